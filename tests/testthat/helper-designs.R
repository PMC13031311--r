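# small helper: random design with area-by-month FE structure
sim_design_frame <- function(n = 300, n_areas = 4, n_months = 6, seed = 1,
                             alpha = 0.5, noise = 1) {
  set.seed(seed)
  area <- sample(sprintf("A%d", 1:n_areas), n, replace = TRUE)
  month <- sample(sprintf("%02d", 1:n_months), n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  byear <- sample(1940:1944, n, replace = TRUE)
  ayear <- sample(2006:2008, n, replace = TRUE)
  x <- rnorm(n)
  fe <- rnorm(n_areas * n_months)[as.integer(factor(paste(area, month)))]
  y <- 2 + fe + alpha * x + 0.3 * (sex == "male") + 0.1 * (byear - 1942) +
    if (noise > 0) rnorm(n, 0, noise) else 0
  birth_date <- as.Date(sprintf("%d-%s-15", byear, month))
  cohort <- data.frame(participant_id = sprintf("P%04d", 1:n),
                       birth_date = birth_date, area_id = area, sex = sex,
                       assess_year = ayear, y = y)
  expo <- data.frame(participant_id = cohort$participant_id,
                     window = "DOC", exposure = x, coverage = 1)
  list(cohort = cohort, expo = expo)
}

dummy_ols_alpha <- function(d) {
  # brute-force dummy-variable OLS oracle
  df <- data.frame(y = d$y, x = d$x, cell = d$cell, d$Z, check.names = TRUE)
  fit <- lm(y ~ ., data = df)
  list(fit = fit, alpha = unname(coef(fit)["x"]))
}
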
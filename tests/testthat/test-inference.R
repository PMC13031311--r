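test_that("binarization applies >= thresholds with sex-specific waist cutoffs", {
  df <- data.frame(
    bmi = c(25.0, 24.999, NA), wc = c(93.9, 80.0, 94.0),
    sex = c("male", "female", "male"),
    hba1c = c(38.999, 39, 50), tg = c(1.7, 1.69, NA), chol = c(5.2, 5.19, 5.3)
  )
  fl <- binarize_outcomes(df)
  expect_equal(fl$overweight, c(TRUE, FALSE, NA))
  expect_equal(fl$high_wc, c(FALSE, TRUE, TRUE))
  expect_equal(fl$high_hba1c, c(FALSE, TRUE, TRUE))
  expect_equal(fl$high_tg, c(TRUE, FALSE, NA))
  expect_equal(fl$high_chol, c(TRUE, FALSE, TRUE))
  expect_error(binarize_outcomes(data.frame(wc = 90)), "sex")
})

test_that("within-transformation equals dummy-variable OLS to 1e-8", {
  for (seed in 1:3) {
    sd_ <- sim_design_frame(n = 300, seed = seed)
    d <- build_design(sd_$cohort, sd_$expo, "y", "DOC")
    mine <- fit_linear_fe(d)
    oracle <- dummy_ols_alpha(d)
    expect_equal(mine$alpha, oracle$alpha, tolerance = 1e-8)
    # within-transform residuals equal the dummy-OLS residuals (FE algebra)
    expect_equal(unname(mine$residuals), unname(residuals(oracle$fit)),
                 tolerance = 1e-8)
  }
})

test_that("noiseless design recovers the true coefficient exactly", {
  sd_ <- sim_design_frame(n = 400, seed = 9, alpha = 0.5, noise = 0)
  d <- build_design(sd_$cohort, sd_$expo, "y", "DOC")
  f <- fit_linear_fe(d)
  expect_equal(f$alpha, 0.5, tolerance = 1e-8)
})

test_that("row order does not affect the estimate or its standard error", {
  sd_ <- sim_design_frame(n = 250, seed = 4)
  d1 <- build_design(sd_$cohort, sd_$expo, "y", "DOC")
  perm <- sample(nrow(sd_$cohort))
  d2 <- build_design(sd_$cohort[perm, ], sd_$expo, "y", "DOC")
  f1 <- fit_linear_fe(d1); f2 <- fit_linear_fe(d2)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("constant-within-cell exposure raises an identification error", {
  sd_ <- sim_design_frame(n = 120, seed = 2)
  cell_x <- ave(seq_len(120), paste(sd_$cohort$area_id,
                                    format(sd_$cohort$birth_date, "%m")),
                FUN = function(i) rnorm(1))
  sd_$expo$exposure <- cell_x
  d <- build_design(sd_$cohort, sd_$expo, "y", "DOC")
  expect_error(fit_linear_fe(d), "not identified")
})

test_that("cluster-robust CR1 sandwich matches a hand/brute-force computation", {
  # 6 observations, 2 clusters, simple design
  X <- cbind(1, c(0.2, -1.1, 0.5, 1.4, -0.3, 0.9))
  y <- c(1.1, -0.4, 0.8, 2.6, 0.3, 1.9)
  cl <- c("g1", "g1", "g1", "g2", "g2", "g2")
  beta <- solve(crossprod(X), crossprod(X, y))
  e <- drop(y - X %*% beta)
  # brute force: explicit sum over clusters
  bread <- solve(crossprod(X))
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    sg <- t(X[cl == g, , drop = FALSE]) %*% e[cl == g]
    meat <- meat + sg %*% t(sg)
  }
  scale <- (2 / 1) * (5 / (6 - 2))
  V_hand <- scale * bread %*% meat %*% bread
  cr <- cluster_robust_se(X, e, cl)
  expect_equal(cr$vcov, V_hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cr$se, sqrt(diag(V_hand)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("one observation per cluster reduces CR1 to HC1, and matches sandwich::vcovCL", {
  set.seed(12)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.2)) + rnorm(n)
  fit <- lm(y ~ X[, 2] + X[, 3])
  e <- residuals(fit)
  # degenerate clustering: every row its own cluster -> the CR1 scale
  # G/(G-1)*(N-1)/(N-K) collapses to N/(N-K), i.e. exactly HC1
  cr <- cluster_robust_se(X, e, seq_len(n))
  hc1 <- sandwich::vcovHC(fit, type = "HC1")
  expect_equal(unname(diag(cr$vcov)), unname(diag(hc1)), tolerance = 1e-10)
  # grouped clustering matches vcovCL's HC1-scaled cluster covariance
  cl <- rep(1:8, each = 5)
  cr2 <- cluster_robust_se(X, e, cl)
  vcl <- sandwich::vcovCL(fit, cluster = cl, type = "HC1", cadjust = TRUE)
  expect_equal(unname(cr2$se), unname(sqrt(diag(vcl))), tolerance = 1e-10)
  expect_error(cluster_robust_se(X, e, rep(1, n)), "2 clusters")
})

test_that("duplicating rows within clusters rescales the CR1 SE as the formula predicts", {
  set.seed(3)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 1)) + rnorm(n)
  cl <- rep(1:6, each = 5)
  beta <- solve(crossprod(X), crossprod(X, y))
  e <- drop(y - X %*% beta)
  cr1 <- cluster_robust_se(X, e, cl)
  X2 <- rbind(X, X); y2 <- c(y, y); cl2 <- c(cl, cl)
  e2 <- drop(y2 - X2 %*% solve(crossprod(X2), crossprod(X2, y2)))
  cr2 <- cluster_robust_se(X2, e2, cl2)
  # brute-force oracle on the duplicated data
  bread <- solve(crossprod(X2)); meat <- matrix(0, 2, 2)
  for (g in unique(cl2)) {
    sg <- t(X2[cl2 == g, , drop = FALSE]) %*% e2[cl2 == g]
    meat <- meat + sg %*% t(sg)
  }
  V <- (6 / 5) * (59 / 58) * bread %*% meat %*% bread
  expect_equal(cr2$vcov, V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Holm correction reproduces the hand-computed step-down", {
  expect_equal(holm_correct(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               c(0.05, 0.08, 0.09, 0.09, 0.09))
  expect_equal(holm_correct(0.2), 0.2)
  expect_equal(holm_correct(c(0.5, 0.5)), c(1, 1))
  # order, bounds, Bonferroni at the smallest p
  set.seed(8)
  p <- runif(5)
  h <- holm_correct(p)
  expect_true(all(h >= p))
  expect_true(all(h <= 1))
  expect_equal(min(h), min(1, 5 * min(p)))
  expect_equal(order(h[order(p)]), 1:5)  # monotone in raw-p rank
})

test_that("logistic FE on a single 2x2 cell reduces to the contingency-table log odds ratio", {
  tab <- expand.grid(x = c(0, 1), y = c(0, 1))
  counts <- c(40, 26, 20, 36)  # x=0/y=0, x=1/y=0, x=0/y=1, x=1/y=1
  df <- tab[rep(1:4, counts), ]
  n <- nrow(df)
  # two FE cells with identical 2x2 tables: by symmetry the FE logit slope
  # equals the pooled contingency-table log odds ratio
  area <- unlist(lapply(counts, function(k) rep(c("A1", "A2"), k / 2)))
  cohort <- data.frame(participant_id = sprintf("P%03d", 1:n),
                       birth_date = as.Date("1950-06-15"),
                       area_id = area,
                       sex = "female", assess_year = 2006, flag = df$y)
  expo <- data.frame(participant_id = cohort$participant_id, window = "DOC",
                     exposure = df$x, coverage = 1)
  d <- build_design(cohort, expo, "flag", "DOC")
  f <- suppressWarnings(fit_logistic_fe(d))
  or_hand <- log((36 * 40) / (26 * 20))
  expect_equal(f$alpha, or_hand, tolerance = 1e-6)
})

test_that("logistic FE drops outcome-constant cells and estimates a null effect as null", {
  set.seed(15)
  n <- 1200
  area <- sample(c("A1", "A2", "A3"), n, replace = TRUE)
  month <- sample(sprintf("%02d", 1:4), n, replace = TRUE)
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.4)
  y[area == "A3" & month == "01"] <- 0  # a degenerate cell
  cohort <- data.frame(participant_id = sprintf("P%04d", 1:n),
                       birth_date = as.Date(sprintf("1950-%s-10", month)),
                       area_id = area, sex = sample(c("f", "m"), n, TRUE),
                       assess_year = 2007, flag = y)
  expo <- data.frame(participant_id = cohort$participant_id, window = "DOC",
                     exposure = x, coverage = 1)
  d <- build_design(cohort, expo, "flag", "DOC")
  f <- suppressWarnings(fit_logistic_fe(d))
  expect_gt(f$n_cell_dropped, 0)
  expect_lt(abs(f$alpha), 3 * f$se)
  expect_true(is.finite(f$se))
})

test_that("the analysis suite returns a tidy table with Holm applied per window family", {
  tw <- tiny_world()
  w <- tw$world
  expo <- build_exposure_table(w$cohort, w$network$stations, tw$deviations)
  res <- run_analysis_suite(w$cohort, expo, windows = c("DOC", "-5w;+3w"),
                            binary = FALSE, negative_controls = TRUE, seed = 5)
  expect_true(all(c("outcome", "window", "family", "stratum", "alpha", "se",
                    "raw_p", "holm_p", "n", "clusters") %in% names(res)))
  main <- res[res$stratum == "all" & res$window == "DOC", ]
  expect_equal(nrow(main), 5L)
  expect_equal(main$holm_p, holm_correct(main$raw_p))
  expect_true(all(main$holm_p >= main$raw_p - 1e-12))
  nc <- res[res$stratum == "negative_control", ]
  expect_equal(sort(unique(nc$outcome)), c("placebo_iid", "placebo_structured"))
  # different windows carry different exposures, hence different estimates
  a_doc <- main$alpha
  a_wide <- res[res$stratum == "all" & res$window == "-5w;+3w", ]$alpha
  expect_false(any(abs(a_doc - a_wide) < 1e-12))
})
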
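#' Binary metabolic-risk cutoffs
#'
#' Established cut-off points for elevated metabolic risk: overweight
#' (BMI >= 25 kg/m2), high waist circumference (>= 94 cm men, >= 80 cm
#' women), high HbA1c (>= 39 mmol/mol), high triglycerides (>= 1.7 mmol/l),
#' high total cholesterol (>= 5.2 mmol/l).  All thresholds apply with `>=`.
#'
#' @return named list of thresholds.
#' @export
binary_cutoffs <- function() {
  list(bmi = 25, wc_male = 94, wc_female = 80, hba1c = 39, tg = 1.7, chol = 5.2)
}

#' Binarize continuous metabolic outcomes
#'
#' @param data data.frame with (any of) `bmi`, `wc`, `hba1c`, `tg`, `chol`
#'   and, when `wc` is present, `sex` (`"male"`/`"female"`).
#' @param cutoffs thresholds from [binary_cutoffs()].
#' @return data.frame of logical flags `overweight`, `high_wc`,
#'   `high_hba1c`, `high_tg`, `high_chol` (missing values stay missing).
#' @export
binarize_outcomes <- function(data, cutoffs = binary_cutoffs()) {
  out <- data.frame(row.names = seq_len(nrow(data)))
  if (!is.null(data$bmi)) out$overweight <- data$bmi >= cutoffs$bmi
  if (!is.null(data$wc)) {
    if (is.null(data$sex)) stop("sex is required to binarize waist circumference")
    thr <- ifelse(data$sex == "male", cutoffs$wc_male, cutoffs$wc_female)
    out$high_wc <- data$wc >= thr
  }
  if (!is.null(data$hba1c)) out$high_hba1c <- data$hba1c >= cutoffs$hba1c
  if (!is.null(data$tg)) out$high_tg <- data$tg >= cutoffs$tg
  if (!is.null(data$chol)) out$high_chol <- data$chol >= cutoffs$chol
  out
}

#' Build a regression design for one outcome and window
#'
#' Joins the cohort to the exposure table for one window, encodes the
#' area-by-birth-month fixed-effect cells (or, with `alt_fe = TRUE`,
#' birth-month-by-birth-year cells with area dummies as covariates), and the
#' covariates (sex, year-of-birth and year-of-assessment as categorical
#' dummies with one reference level each).  Rows with a missing outcome or
#' exposure are dropped and counted.
#'
#' @param cohort cohort table.
#' @param exposure_table long exposure table from [build_exposure_table()].
#' @param outcome outcome column name in `cohort`.
#' @param window exposure window label.
#' @param alt_fe use the alternative fixed-effect scheme.
#' @return list: `y`, `x` (exposure), `Z` (covariate dummy matrix),
#'   `cell` (FE cell factor), `cluster` (area factor), `n_dropped`.
#' @export
build_design <- function(cohort, exposure_table, outcome, window, alt_fe = FALSE) {
  # plain-data.frame subset: `window` is both an argument and a column name,
  # so data.table's scoped evaluation must not see this expression
  expo <- as.data.frame(exposure_table)
  expo <- expo[expo[["window"]] == window, ]
  m <- match(cohort$participant_id, expo$participant_id)
  x <- expo$exposure[m]
  y <- cohort[[outcome]]
  if (is.null(y)) stop(sprintf("outcome '%s' not found in cohort", outcome))
  if (is.logical(y)) y <- as.numeric(y)
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no usable rows after dropping missing exposure/outcome")
  ch <- cohort[keep, ]
  x <- x[keep]; y <- y[keep]
  bmonth <- format(as.Date(ch$birth_date), "%m")
  byear <- format(as.Date(ch$birth_date), "%Y")
  # one dummy block per categorical covariate, skipping constants
  dummy_block <- function(v, name) {
    f <- factor(v)
    if (nlevels(f) < 2) return(NULL)
    m <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(name, levels(f)[-1])
    m
  }
  if (alt_fe) {
    cell <- factor(paste(bmonth, byear, sep = ":"))
    blocks <- list(dummy_block(ch$sex, "sex"),
                   dummy_block(ch$assess_year, "assess"),
                   dummy_block(ch$area_id, "area"))
  } else {
    cell <- factor(paste(ch$area_id, bmonth, sep = ":"))
    blocks <- list(dummy_block(ch$sex, "sex"),
                   dummy_block(byear, "byear"),
                   dummy_block(ch$assess_year, "assess"))
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  Z <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = nrow(ch), ncol = 0)
  list(y = y, x = x, Z = Z, cell = droplevels(cell),
       cluster = factor(ch$area_id), n_dropped = n_dropped,
       outcome = outcome, window = window)
}

# internal: subtract FE-cell means from each column of m (within transform)
.demean_by <- function(m, cell) {
  m <- as.matrix(m)
  means <- rowsum(m, cell) / as.vector(table(cell))
  m - means[as.integer(cell), , drop = FALSE]
}

#' Cluster-robust (CR1) covariance for a linear design
#'
#' Sandwich estimator `(X'X)^-1 [sum_g X_g'e_g e_g'X_g] (X'X)^-1` with the
#' CR1 small-sample scale `G/(G-1) * (N-1)/(N-K)`, where `K` counts all
#' estimated parameters (including any absorbed fixed effects, passed via
#' `n_absorbed`).  Matches Stata's default and `sandwich::vcovCL(type =
#' "HC1")` on an explicit-dummy design.
#'
#' @param X numeric design matrix (post-absorption).
#' @param residuals fitted residuals.
#' @param cluster cluster ids (one per row).
#' @param n_absorbed number of absorbed parameters not in `X` (FE cells).
#' @return list `vcov` (matrix) and `se` (vector).
#' @export
cluster_robust_se <- function(X, residuals, cluster, n_absorbed = 0L) {
  X <- as.matrix(X)
  cluster <- as.factor(cluster)
  G <- nlevels(droplevels(cluster))
  if (G < 2) stop("cluster-robust SEs need >= 2 clusters; use a heteroskedasticity-robust SE instead")
  N <- nrow(X)
  K <- ncol(X) + n_absorbed
  bread <- solve(crossprod(X))
  scores <- rowsum(X * residuals, cluster)
  meat <- crossprod(scores)
  scale <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- scale * bread %*% meat %*% bread
  list(vcov = V, se = sqrt(diag(V)), n_clusters = G)
}

#' Linear fixed-effects regression of an outcome on exposure
#'
#' Estimates the exposure coefficient by OLS with the area-by-birth-month
#' fixed effects absorbed via the within transformation (numerically equal
#' to full dummy-variable OLS), with CR1 area-clustered standard errors and
#' p-values from a t distribution on (clusters - 1) degrees of freedom.
#' Covariate columns that become collinear after absorption are dropped.
#' Singleton FE cells are retained (they self-absorb and contribute nothing
#' to identification).
#'
#' @param design from [build_design()].
#' @return a `periclim_fit`: `alpha` (outcome units per degC), `se`,
#'   `raw_p`, `ci` (95%), `n_obs`, `n_clusters`, `family`, `outcome`,
#'   `window`, `n_dropped`.
#' @export
fit_linear_fe <- function(design) {
  cell <- design$cell
  Xall <- cbind(exposure = design$x, design$Z)
  Xd <- .demean_by(Xall, cell)
  yd <- .demean_by(matrix(design$y, ncol = 1), cell)[, 1]
  if (sd(Xd[, 1]) < 1e-12) {
    stop("exposure is constant within every fixed-effect cell: coefficient not identified")
  }
  # drop covariates absorbed by the FE (zero within-cell variance)
  keep <- c(TRUE, apply(Xd[, -1, drop = FALSE], 2, function(v) sd(v) > 1e-10))
  Xd <- Xd[, keep, drop = FALSE]
  fit <- lm.fit(Xd, yd)
  if (any(is.na(fit$coefficients))) {
    ok <- !is.na(fit$coefficients)
    Xd <- Xd[, ok, drop = FALSE]
    fit <- lm.fit(Xd, yd)
  }
  res <- fit$residuals
  # K in the CR1 correction counts the absorbed FE cells: within-transform
  # residuals are deflated by the absorbed parameters, and (N-1)/(N-K)
  # restores their scale on average
  cr <- cluster_robust_se(Xd, res, design$cluster, n_absorbed = nlevels(cell))
  alpha <- unname(fit$coefficients[1])
  se <- cr$se[1]
  df <- cr$n_clusters - 1
  tstat <- alpha / se
  p <- 2 * pt(-abs(tstat), df)
  ci <- alpha + qt(c(0.025, 0.975), df) * se
  structure(list(alpha = alpha, se = se, raw_p = p, ci = ci, df = df,
                 n_obs = length(yd), n_clusters = cr$n_clusters,
                 family = "linear", outcome = design$outcome,
                 window = design$window, n_dropped = design$n_dropped,
                 coefficients = fit$coefficients, vcov = cr$vcov,
                 residuals = res),
            class = "periclim_fit")
}

#' Logistic fixed-effects regression of a binary outcome on exposure
#'
#' Maximum-likelihood logit with the fixed-effect cells entered as dummy
#' columns (as the model is written), after dropping cells whose outcome
#' does not vary (they carry no likelihood information; their row count is
#' reported).  Cluster-robust sandwich standard errors via
#' [sandwich::vcovCL()]; p-values on (clusters - 1) degrees of freedom.  A
#' warning is issued when the average cell size is below 20 (incidental-
#' parameter territory).
#'
#' @param design from [build_design()] on a binary (0/1 or logical) outcome.
#' @return a `periclim_fit` with `alpha` in log-odds per degC.
#' @export
fit_logistic_fe <- function(design) {
  y <- design$y
  if (!all(y %in% c(0, 1))) stop("fit_logistic_fe needs a binary outcome")
  cell <- design$cell
  var_tab <- tapply(y, cell, function(v) length(unique(v)) > 1)
  keep_cells <- names(var_tab)[var_tab]
  if (!length(keep_cells)) stop("no fixed-effect cell with outcome variation")
  keep <- as.character(cell) %in% keep_cells
  n_cell_dropped <- sum(!keep)
  y <- y[keep]
  dat <- data.frame(y = y, x = design$x[keep],
                    design$Z[keep, , drop = FALSE], check.names = FALSE)
  cellk <- droplevels(cell[keep])
  if (mean(table(cellk)) < 20) {
    warning("average fixed-effect cell size < 20: incidental-parameter bias possible in logistic FE")
  }
  dat$cell <- cellk
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
  cl <- droplevels(design$cluster[keep])
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC1")
  alpha <- unname(coef(fit)["x"])
  se <- sqrt(V["x", "x"])
  G <- nlevels(cl)
  df <- G - 1
  p <- 2 * pt(-abs(alpha / se), df)
  ci <- alpha + qt(c(0.025, 0.975), df) * se
  structure(list(alpha = alpha, se = se, raw_p = p, ci = ci, df = df,
                 n_obs = length(y), n_clusters = G, family = "logistic",
                 outcome = design$outcome, window = design$window,
                 n_dropped = design$n_dropped, n_cell_dropped = n_cell_dropped),
            class = "periclim_fit")
}

#' @export
print.periclim_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ exposure(%s)\n  alpha = %.5f (cluster SE %.5f), p = %.4g, n = %d, clusters = %d\n",
              x$family, x$outcome, x$window, x$alpha, x$se, x$raw_p, x$n_obs, x$n_clusters))
  invisible(x)
}

#' Holm (Bonferroni-Holm) step-down correction
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "holm"`; the family
#' in this pipeline is the set of outcomes tested within one exposure
#' window.
#'
#' @param p_values raw p-values in \[0,1\].
#' @return corrected p-values in the input order.
#' @examples
#' holm_correct(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
holm_correct <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "holm")
}

# internal: one linear or logistic fit, errors captured as NA rows
.safe_fit <- function(cohort, exposure_table, outcome, window, family, alt_fe = FALSE) {
  out <- try({
    d <- build_design(cohort, exposure_table, outcome, window, alt_fe = alt_fe)
    if (family == "linear") fit_linear_fe(d) else fit_logistic_fe(d)
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    return(data.table::data.table(outcome = outcome, window = window, family = family,
                                  alpha = NA_real_, se = NA_real_, raw_p = NA_real_,
                                  n = NA_integer_, clusters = NA_integer_,
                                  error = as.character(attr(out, "condition")$message %||% out)))
  }
  data.table::data.table(outcome = outcome, window = window, family = family,
                         alpha = out$alpha, se = out$se, raw_p = out$raw_p,
                         n = out$n_obs, clusters = out$n_clusters, error = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis suite
#'
#' Fits every exposure window against the five continuous outcomes
#' (linear) and, optionally, the five binarized outcomes (logistic), plus
#' optional strata (sex-specific; winter conceptions Oct-Mar; Oct-Dec vs
#' Jan-Mar), generated placebo (negative-control) outcomes, and the
#' alternative fixed-effect scheme.  Holm correction is applied across the
#' outcome family within each window, family and stratum.  Failures in
#' individual models are reported in the `error` column; the suite
#' continues.
#'
#' @param cohort cohort table with continuous outcomes.
#' @param exposure_table from [build_exposure_table()].
#' @param windows window labels to fit.
#' @param outcomes continuous outcome columns.
#' @param binary also fit logistic models on the binarized outcomes.
#' @param strata character subset of `c("sex", "winter", "winter_split")`.
#' @param negative_controls add placebo outcomes (iid noise and a seasonal
#'   + area structured variable, both generated independent of exposure).
#' @param alt_fe also fit the alternative FE scheme (birth-month-by-year
#'   cells + area dummies) for the continuous outcomes.
#' @param seed seed for the placebo generators.
#' @return tidy data.table: `outcome`, `window`, `family`, `stratum`,
#'   `alpha`, `se`, `raw_p`, `holm_p`, `n`, `clusters`, `error`.
#' @export
run_analysis_suite <- function(cohort, exposure_table,
                               windows = names(exposure_windows()),
                               outcomes = c("bmi", "wc", "hba1c", "tg", "chol"),
                               binary = TRUE,
                               strata = character(0),
                               negative_controls = FALSE,
                               alt_fe = FALSE,
                               seed = 1L) {
  cohort <- data.table::as.data.table(cohort)
  outcomes <- intersect(outcomes, names(cohort))
  res <- list()
  add <- function(tab, stratum) {
    tab$stratum <- stratum
    res[[length(res) + 1L]] <<- tab
  }
  run_family <- function(ch, expo, fam, outs, stratum, alt = FALSE) {
    tab <- data.table::rbindlist(lapply(windows, function(w) {
      one <- data.table::rbindlist(lapply(outs, function(o) {
        .safe_fit(ch, expo, o, w, fam, alt_fe = alt)
      }))
      one$holm_p <- holm_correct(one$raw_p)
      one
    }))
    add(tab, stratum)
  }

  run_family(cohort, exposure_table, "linear", outcomes, "all")
  if (binary) {
    flags <- binarize_outcomes(cohort)
    chb <- cbind(cohort, flags)
    run_family(chb, exposure_table, "logistic", names(flags), "all")
  }
  if ("sex" %in% strata) {
    for (s in c("female", "male")) {
      run_family(cohort[cohort$sex == s, ], exposure_table, "linear", outcomes, s)
    }
  }
  doc_month <- as.integer(format(estimate_doc(cohort$birth_date), "%m"))
  if ("winter" %in% strata) {
    run_family(cohort[doc_month %in% c(10:12, 1:3), ], exposure_table,
               "linear", outcomes, "winter")
  }
  if ("winter_split" %in% strata) {
    run_family(cohort[doc_month %in% 10:12, ], exposure_table, "linear", outcomes, "oct_dec")
    run_family(cohort[doc_month %in% 1:3, ], exposure_table, "linear", outcomes, "jan_mar")
  }
  if (negative_controls) {
    set.seed(stage_seed(seed, "placebo"))
    chp <- data.table::copy(cohort)
    chp$placebo_iid <- rnorm(nrow(chp))
    month_fx <- rnorm(12, 0, 0.5)
    area_fx <- rnorm(length(unique(chp$area_id)), 0, 0.5)
    af <- setNames(area_fx, sort(unique(chp$area_id)))
    chp$placebo_structured <- month_fx[as.integer(format(as.Date(chp$birth_date), "%m"))] +
      af[chp$area_id] + rnorm(nrow(chp))
    run_family(chp, exposure_table, "linear",
               c("placebo_iid", "placebo_structured"), "negative_control")
  }
  if (alt_fe) {
    tab <- data.table::rbindlist(lapply(windows, function(w) {
      one <- data.table::rbindlist(lapply(outcomes, function(o) {
        .safe_fit(cohort, exposure_table, o, w, "linear", alt_fe = TRUE)
      }))
      one$holm_p <- holm_correct(one$raw_p)
      one
    }))
    add(tab, "alt_fe")
  }
  out <- data.table::rbindlist(res, fill = TRUE)
  data.table::setcolorder(out, c("outcome", "window", "family", "stratum",
                                 "alpha", "se", "raw_p", "holm_p", "n", "clusters", "error"))
  out[]
}
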
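#' Express a coefficient as a percentage of the outcome's SD
#'
#' @param coef effect in outcome units per degC.
#' @param sd outcome standard deviation (same units), > 0.
#' @param digits decimals for half-up display rounding (default 2);
#'   `NULL` returns the raw value.
#' @return percent of one SD per degC.
#' @examples
#' percent_of_sd(0.043, 13.512)  # 0.32
#' @export
percent_of_sd <- function(coef, sd, digits = 2) {
  stopifnot(sd > 0)
  x <- 100 * coef / sd
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Translate a BMI coefficient into body-weight grams
#'
#' BMI = weight / height^2, so a BMI change of `bmi_coef * delta_t`
#' corresponds to `bmi_coef * delta_t * height_m^2` kilograms.
#'
#' @param bmi_coef kg/m2 per degC.
#' @param delta_t temperature change in degC.
#' @param height_m body height in metres, > 0.
#' @return weight change in grams (raw, unrounded).
#' @examples
#' weight_change_grams(0.019, 2, 1.80)  # 123.12 g
#' @export
weight_change_grams <- function(bmi_coef, delta_t, height_m) {
  stopifnot(height_m > 0)
  bmi_coef * delta_t * height_m^2 * 1000
}

#' Scale an effect from the 2 degC reference scenario
#'
#' Effects are linear in the temperature change, so an effect quoted for a
#' 2 degC rise scales by `delta_t / 2`.  Confidence-interval endpoints
#' scale the same way.
#'
#' @param effect_at_2c effect under the 2 degC scenario (any unit).
#' @param delta_t target temperature change in degC.
#' @return effect in the same unit.
#' @examples
#' scale_scenario(2.29, 6.5)  # 7.4425
#' @export
scale_scenario <- function(effect_at_2c, delta_t) {
  effect_at_2c * delta_t / 2
}

#' Round half away from zero
#'
#' Display rounding matching printed-table conventions (R's `round()` uses
#' round-half-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Scenario table from a results table
#'
#' Builds the back-of-envelope translations for a set of fitted linear
#' coefficients: percent-of-SD per degC, and the effect under given
#' temperature-rise scenarios (linear scaling), with the BMI coefficient
#' additionally translated into body-weight grams for a reference height.
#'
#' @param results tidy results table (linear rows) with `outcome`, `window`,
#'   `alpha`.
#' @param outcome_sds named vector of outcome SDs.
#' @param delta_ts temperature scenarios in degC (default `c(2, 6.5)`).
#' @param height_m reference height for the weight translation.
#' @return data.table with one row per coefficient and scenario.
#' @export
scenario_table <- function(results, outcome_sds, delta_ts = c(2, 6.5), height_m = 1.80) {
  res <- data.table::as.data.table(results)
  res <- res[res$family == "linear" & !is.na(res$alpha) & res$outcome %in% names(outcome_sds), ]
  rows <- list()
  for (i in seq_len(nrow(res))) {
    o <- res$outcome[i]; a <- res$alpha[i]
    pct <- percent_of_sd(a, outcome_sds[[o]], digits = NULL)
    for (dt in delta_ts) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        outcome = o, window = res$window[i], delta_t = dt,
        effect = a * dt,
        pct_sd = scale_scenario(pct * 2, dt),  # pct is per 1 degC; reference is 2 degC
        weight_g = if (o == "bmi") weight_change_grams(a, dt, height_m) else NA_real_
      )
    }
  }
  data.table::rbindlist(rows)
}
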
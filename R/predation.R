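#' Z-score a variable within groups
#'
#' Replaces `value_col` by its within-group z-score. Groups with zero
#' variance (or a single record) get the value 0 with a warning.
#'
#' @param records data.frame.
#' @param value_col column to scale.
#' @param group_cols character vector of grouping columns (empty =
#'   global z-score).
#' @return `records` with `value_col` replaced by its z-score.
#' @export
zscore_within <- function(records, value_col, group_cols = character()) {
  g <- if (length(group_cols))
    interaction(records[group_cols], drop = TRUE)
  else factor(rep(1, nrow(records)))
  x <- records[[value_col]]
  out <- numeric(length(x))
  warned <- FALSE
  for (lev in levels(g)) {
    i <- g == lev
    s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) {
      out[i] <- 0
      warned <- TRUE
    } else out[i] <- (x[i] - mean(x[i])) / s
  }
  if (warned)
    warning("zero-variance group(s): z-scores set to 0")
  records[[value_col]] <- out
  records
}

#' Fit the predation-probability model
#'
#' Binomial smooth model of largemouth bass predation outcomes from
#' tethered-prey deployments: a k = 7 smooth of the predator's metabolic
#' index (or of temperature), a parametric term for deployment duration
#' z-scored within method and site, and by-method and by-site random
#' intercepts. Optional covariates (e.g. `time_to_night_min`,
#' `distance_to_shore_m`) are added as smooths after within-group
#' z-scoring.
#'
#' @param deployments data.frame with `predated_by_bass`, `method`,
#'   `site_id`, `duration_min`, `temp_C`, and `po2_kPa` (or `do_mgL`
#'   plus optional `salinity`).
#' @param bass_traits a [trait_set()] for the predator.
#' @param driver "phi" (default) or "temperature".
#' @param optional_terms character vector of extra smooth covariates.
#' @param k smooth basis dimension, default 7.
#' @return a `binsmooth` fit; the model data include the computed
#'   `phi` and `duration_z` columns.
#' @export
fit_predation_model <- function(deployments, bass_traits,
                                driver = c("phi", "temperature"),
                                optional_terms = character(), k = 7) {
  driver <- match.arg(driver)
  d <- deployments
  if (is.null(d$po2_kPa)) {
    sal <- if (is.null(d$salinity)) 0 else d$salinity
    d$po2_kPa <- po2_from_do(d$do_mgL, d$temp_C, sal)
  }
  d$phi <- phi(d$po2_kPa, d$temp_C, bass_traits)
  d$duration_z <- d$duration_min
  d <- zscore_within(d, "duration_z", c("method", "site_id"))
  for (v in optional_terms) d <- zscore_within(d, v, c("method", "site_id"))
  driver_col <- if (driver == "phi") "phi" else "temp_C"
  smooths <- stats::setNames(
    rep(list(list(k = k)), 1 + length(optional_terms)),
    c(driver_col, optional_terms))
  spec <- smooth_model_spec(outcome = "predated_by_bass",
                            smooths = smooths,
                            parametric = "duration_z",
                            random = c("method", "site_id"))
  fit_binomial_smooth(d, spec)
}

#' Seasonal alignment of predation pressure and prey fitness
#'
#' Pairs two seasonal curves on a common day grid and summarizes their
#' opposition: the rank (Spearman) correlation, and the day windows where
#' predation sits above its mean while prey fitness sits below its own.
#'
#' @param prey_curve,predation_curve data.frames with columns `day` and
#'   `value` on identical day grids.
#' @return list with `paired` (day, prey, predation), `rank_correlation`,
#'   and `risk_days` (days of above-mean predation with below-mean prey
#'   fitness).
#' @export
predation_alignment <- function(prey_curve, predation_curve) {
  if (nrow(prey_curve) != nrow(predation_curve) ||
      !all(prey_curve$day == predation_curve$day))
    stop("curves are not on a common day grid")
  rho <- stats::cor(prey_curve$value, predation_curve$value,
                    method = "spearman")
  risk <- predation_curve$value > mean(predation_curve$value) &
    prey_curve$value < mean(prey_curve$value)
  list(paired = data.frame(day = prey_curve$day, prey = prey_curve$value,
                           predation = predation_curve$value),
       rank_correlation = rho,
       risk_days = prey_curve$day[risk])
}
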
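#' Critical oxygen tension at a given temperature
#'
#' Evaluates the Arrhenius model \eqn{O_2crit(T) = \exp(A - E/(k_B T))}
#' for a trait set.
#'
#' @param traits a [trait_set()] (or list with `A`, `E`).
#' @param temp_C temperature(s) in C.
#' @return O2crit in kPa.
#' @examples
#' o2crit_at_temperature(trait_set(14.81, 0.33), 16.6) # ~4.92
#' @export
o2crit_at_temperature <- function(traits, temp_C) {
  tr <- .as_traits(traits)
  exp(tr$A - tr$E * inverse_temperature(temp_C))
}

#' The metabolic index
#'
#' Ratio of environmental O2 supply to the temperature-dependent O2
#' requirement of standard metabolism:
#' \deqn{\Phi = pO_2 / O_2crit(T).}
#' Numerically equal to the factorial aerobic scope realized at the
#' ambient pO2; \eqn{\Phi = 1} marks the limit where only maintenance
#' metabolism is possible.
#'
#' @param po2_kPa O2 partial pressure in kPa (>= 0).
#' @param temp_C temperature in C.
#' @param traits a [trait_set()].
#' @return unitless metabolic-index value(s).
#' @examples
#' phi(21, 16.6, trait_set(14.81, 0.33)) # ~4.27
#' @export
phi <- function(po2_kPa, temp_C, traits) {
  if (any(po2_kPa < 0)) stop("po2_kPa must be >= 0")
  po2_kPa / o2crit_at_temperature(traits, temp_C)
}

#' Factorial aerobic scope at air saturation
#'
#' The metabolic index evaluated at the reference pressure (21 kPa):
#' the FAS an organism can express when O2 is not limiting. By the
#' MMR/SMR ratio identity, `fas_at_saturation(tr, t) *
#' o2crit_at_temperature(tr, t) == 21` exactly.
#'
#' @param traits a [trait_set()].
#' @param temp_C temperature in C.
#' @param p_ref_kPa reference pressure; default 21.
#' @return unitless FAS.
#' @export
fas_at_saturation <- function(traits, temp_C, p_ref_kPa = 21) {
  phi(p_ref_kPa, temp_C, traits)
}

#' Daily metabolic-index series from environmental records
#'
#' Element-wise metabolic index over dated environmental records. If
#' `po2_kPa` is absent it is derived from dissolved oxygen via
#' [po2_from_do()]. Records missing temperature or pO2 are dropped with a
#' message.
#'
#' @param env data.frame with `site_id`, `date`, `temp_C`, and `po2_kPa`
#'   (or `do_mgL` plus optional `salinity`).
#' @param traits a [trait_set()].
#' @return a `phi_series` data.frame (`site_id`, `date`, `temp_C`,
#'   `po2_kPa`, `phi`) with attribute `label`.
#' @export
phi_series <- function(env, traits) {
  tr <- .as_traits(traits)
  if (nrow(env) == 0) {
    warning("empty environmental input; returning empty series")
    out <- data.frame(site_id = character(), date = as.Date(character()),
                      temp_C = numeric(), po2_kPa = numeric(),
                      phi = numeric())
    return(structure(out, label = tr$label, class = c("phi_series",
                                                      "data.frame")))
  }
  if (is.null(env$po2_kPa)) {
    sal <- if (is.null(env$salinity)) 0 else env$salinity
    env$po2_kPa <- po2_from_do(env$do_mgL, env$temp_C, sal)
  }
  ok <- is.finite(env$temp_C) & is.finite(env$po2_kPa)
  if (any(!ok))
    message(sum(!ok), " record(s) missing temperature or pO2 were dropped")
  env <- env[ok, , drop = FALSE]
  out <- data.frame(site_id = env$site_id, date = as.Date(env$date),
                    temp_C = env$temp_C, po2_kPa = env$po2_kPa,
                    phi = phi(env$po2_kPa, env$temp_C, tr))
  structure(out, label = tr$label, class = c("phi_series", "data.frame"))
}

#' Robust seasonal smooth of a metabolic-index series
#'
#' Penalized cyclic spline on day of water year with by-site random
#' intercepts and Student-t observation error (scaled-t family), the
#' desk-scale stand-in for a full spatiotemporal smooth: spatial
#' variation enters only through site intercepts. Day 366 wraps to day 1
#' at the cyclic boundary.
#'
#' @param series a `phi_series` (or data.frame with `phi`, `date`,
#'   `site_id`).
#' @param basis_dim cyclic basis dimension, default 9.
#' @param t_dof Student-t degrees of freedom. Used as a starting value and
#'   estimated unless `t_scale` is also given, in which case
#'   `(t_dof, t_scale)` are held fixed.
#' @param t_scale optional fixed scale parameter of the scaled-t family.
#' @param gaussian fit with Gaussian error instead (for robustness
#'   contrasts); default FALSE.
#' @return object of class `seasonal_phi_fit`: list with `grid`
#'   (data.frame `wyday`, `fit`, `lo`, `hi`), `model`, `site_sd`, `nu`.
#' @export
seasonal_phi_smooth <- function(series, basis_dim = 9, t_dof = 5,
                                t_scale = NULL, gaussian = FALSE) {
  d <- data.frame(phi = series$phi,
                  wyday = water_year_day(series$date),
                  site_id = factor(series$site_id))
  if (length(unique(d$site_id)) < 2)
    stop("need >= 2 sites for site random intercepts")
  if (diff(range(d$wyday)) < 300)
    stop("need at least one full seasonal cycle of data")
  fam <- if (gaussian) stats::gaussian() else
    if (is.null(t_scale)) mgcv::scat(theta = c(-abs(t_dof), -1)) else
      mgcv::scat(theta = c(t_dof, t_scale))
  m <- mgcv::gam(phi ~ s(wyday, bs = "cc", k = basis_dim) +
                   s(site_id, bs = "re"),
                 family = fam, data = d, method = "REML",
                 knots = list(wyday = c(0.5, 366.5)))
  grid <- data.frame(wyday = 1:366, site_id = d$site_id[1])
  p <- mgcv::predict.gam(m, newdata = grid, se.fit = TRUE,
                         exclude = "s(site_id)", newdata.guaranteed = TRUE)
  vc <- NULL
  utils::capture.output(vc <- mgcv::gam.vcomp(m))
  site_sd <- tryCatch(unname(vc["s(site_id)", "std.dev"]),
                      error = function(e) NA_real_)
  nu <- if (gaussian) Inf else m$family$getTheta(TRUE)[1]
  structure(list(grid = data.frame(wyday = grid$wyday, fit = as.numeric(p$fit),
                                   lo = as.numeric(p$fit - 1.96 * p$se.fit),
                                   hi = as.numeric(p$fit + 1.96 * p$se.fit)),
                 model = m, site_sd = site_sd, nu = nu),
            class = "seasonal_phi_fit")
}

#' Classify a metabolic-index value against ecological thresholds
#'
#' Partitions the positive axis into `below_crit` (phi < crit), `between`
#' (crit <= phi <= stable; the interval is closed at both ends), and
#' `above_stable` (phi > stable).
#'
#' @param phi_value metabolic-index value(s).
#' @param thresholds list or named vector with `crit` < `stable`.
#' @return factor with levels `below_crit`, `between`, `above_stable`.
#' @export
classify_phi <- function(phi_value, thresholds) {
  crit <- thresholds[["crit"]]
  stable <- thresholds[["stable"]]
  if (crit >= stable) stop("thresholds must satisfy crit < stable")
  out <- ifelse(phi_value < crit, "below_crit",
                ifelse(phi_value <= stable, "between", "above_stable"))
  factor(out, levels = c("below_crit", "between", "above_stable"))
}

#' Presence-weighted exposure fractions
#'
#' Fractions of the days an organism-group was present that fall in each
#' threshold category of the metabolic-index series.
#'
#' @param series a `phi_series`.
#' @param presence_dates dates of presence (must be a subset of the
#'   series dates).
#' @param thresholds list with `crit` and `stable`.
#' @return object of class `exposure_fractions`: list with
#'   `frac_below_crit`, `frac_between`, `frac_above_stable`, `n_days`.
#' @export
presence_weighted_fractions <- function(series, presence_dates,
                                        thresholds) {
  presence_dates <- as.Date(presence_dates)
  if (length(presence_dates) == 0) stop("empty presence set")
  if (!all(presence_dates %in% series$date))
    stop("presence dates must be a subset of the series dates")
  sel <- series[series$date %in% presence_dates, , drop = FALSE]
  cls <- classify_phi(sel$phi, thresholds)
  tab <- table(cls) / length(cls)
  structure(list(frac_below_crit = unname(tab["below_crit"]),
                 frac_between = unname(tab["between"]),
                 frac_above_stable = unname(tab["above_stable"]),
                 n_days = nrow(sel)),
            class = "exposure_fractions")
}

#' @export
print.exposure_fractions <- function(x, ...) {
  cat(sprintf(
    "Presence-weighted fractions over %d days: %.1f%% below crit, %.1f%% between, %.1f%% above stable\n",
    x$n_days, 100 * x$frac_below_crit, 100 * x$frac_between,
    100 * x$frac_above_stable))
  invisible(x)
}

#' Predator metabolic-index surplus over prey
#'
#' Per-day percent surplus `100 * (phi_pred - phi_prey) / phi_prey` over
#' the aligned dates of two series, and its mean.
#'
#' @param pred_series,prey_series `phi_series` objects on identical
#'   site/date alignments.
#' @return list with `series` (data.frame `date`, `site_id`,
#'   `percent_surplus`) and `mean_percent`.
#' @export
predator_surplus <- function(pred_series, prey_series) {
  if (nrow(pred_series) != nrow(prey_series) ||
      !all(pred_series$date == prey_series$date) ||
      !all(pred_series$site_id == prey_series$site_id))
    stop("series are not aligned on the same sites/dates")
  pct <- 100 * (pred_series$phi - prey_series$phi) / prey_series$phi
  list(series = data.frame(date = pred_series$date,
                           site_id = pred_series$site_id,
                           percent_surplus = pct),
       mean_percent = mean(pct))
}
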
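## Boltzmann constant, eV K^-1
.kB <- 8.617333e-5

#' Inverse temperature in Boltzmann-Arrhenius units
#'
#' Converts a Celsius temperature to inverse thermal energy
#' \eqn{1 / (k_B T)} with \eqn{T} in Kelvin and \eqn{k_B} Boltzmann's
#' constant in eV/K, the abscissa of all Arrhenius fits in this package.
#'
#' @param temp_C temperature in degrees Celsius; must exceed -273.15.
#' @return inverse temperature in 1/eV.
#' @examples
#' inverse_temperature(16.6) # ~40.05
#' @export
inverse_temperature <- function(temp_C) {
  if (any(!is.finite(temp_C)) || any(temp_C <= -273.15))
    stop("temp_C must be finite and above absolute zero (-273.15 C)")
  1 / (.kB * (temp_C + 273.15))
}

#' Saturation water vapor pressure (kPa)
#'
#' Buck (1981) approximation over liquid water.
#'
#' @param temp_C temperature in degrees Celsius.
#' @return vapor pressure in kPa.
#' @export
water_vapor_kPa <- function(temp_C) {
  0.61121 * exp((18.678 - temp_C / 234.5) * temp_C / (257.14 + temp_C))
}

#' Oxygen solubility (air-saturation concentration) in mg/L
#'
#' Benson & Krause solubility as parameterized by the Garcia & Gordon (1992)
#' coefficient fit, with salinity correction, converted from mL/L to mg/L
#' (x 1.42905) and rescaled from standard to ambient pressure through the
#' dry-air fraction (patm - pv)/(101.325 - pv).
#'
#' @param temp_C water temperature, 0-40 C (formula validity range).
#' @param salinity practical salinity (>= 0).
#' @param patm_kPa barometric pressure in kPa (default 101.325).
#' @return saturation concentration of dissolved O2 in mg/L.
#' @export
o2_sat_mgL <- function(temp_C, salinity = 0, patm_kPa = 101.325) {
  if (any(temp_C < 0 | temp_C > 40))
    stop("temp_C outside solubility-formula validity range [0, 40] C")
  if (any(salinity < 0)) stop("salinity must be >= 0")
  ts <- log((298.15 - temp_C) / (273.15 + temp_C))
  a <- c(2.00907, 3.22014, 4.05010, 4.94457, -0.256847, 3.88767)
  b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
  c0 <- -4.88682e-7
  lnC <- a[1] + a[2] * ts + a[3] * ts^2 + a[4] * ts^3 + a[5] * ts^4 +
    a[6] * ts^5 +
    salinity * (b[1] + b[2] * ts + b[3] * ts^2 + b[4] * ts^3) +
    c0 * salinity^2
  mgL_std <- exp(lnC) * 1.42905
  pv <- water_vapor_kPa(temp_C)
  mgL_std * (patm_kPa - pv) / (101.325 - pv)
}

#' Convert dissolved oxygen concentration to O2 partial pressure
#'
#' pO2 (kPa) is the fraction of air saturation times the partial pressure
#' of O2 in water-saturated air:
#' \deqn{pO_2 = \frac{DO}{C_{sat}(T, S, P)} \times 0.2095 (P - p_v(T))}
#' Linear in DO; at 100% air saturation and sea-level pressure this is
#' ~20.9 kPa at 15 C.
#'
#' @param do_mgL dissolved O2 concentration in mg/L (>= 0).
#' @param temp_C water temperature in C (0-40).
#' @param salinity practical salinity (default 0).
#' @param patm_kPa barometric pressure in kPa (default 101.325).
#' @return O2 partial pressure in kPa.
#' @examples
#' po2_from_do(10.08, 15, 0) # ~20.9 kPa (air saturation)
#' @export
po2_from_do <- function(do_mgL, temp_C, salinity = 0, patm_kPa = 101.325) {
  if (any(do_mgL < 0)) stop("do_mgL must be >= 0")
  sat <- o2_sat_mgL(temp_C, salinity, patm_kPa)
  (do_mgL / sat) * 0.2095 * (patm_kPa - water_vapor_kPa(temp_C))
}

#' Day of water year
#'
#' 1-based day index in the hydrological year beginning 1 October
#' (California convention): 1 Oct -> 1, 1 Jan -> 93, 30 Sep -> 365/366.
#'
#' @param date a `Date` (or coercible) vector.
#' @return integer day-of-water-year.
#' @export
water_year_day <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  start_yr <- ifelse(as.integer(format(date, "%m")) >= 10, yr, yr - 1L)
  as.integer(date - as.Date(sprintf("%d-10-01", start_yr))) + 1L
}

#' Quantile-based quality-control trim
#'
#' Removes records in which any named variable lies strictly outside its
#' empirical `[q, 1-q]` quantiles, with quantiles computed once on the
#' input set (so the operation is idempotent at those bounds).
#'
#' @param records a data.frame.
#' @param variables character vector of column names to screen.
#' @param q tail probability in (0, 0.5); default 0.005.
#' @return the trimmed data.frame, with attribute `"qc_dropped"` giving the
#'   number of removed records.
#' @export
qc_trim <- function(records, variables, q = 0.005) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars))
    stop("variables not present: ", paste(missing_vars, collapse = ", "))
  keep <- rep(TRUE, nrow(records))
  for (v in variables) {
    x <- records[[v]]
    qs <- stats::quantile(x, c(q, 1 - q), na.rm = TRUE, names = FALSE)
    keep <- keep & x >= qs[1] & x <= qs[2]
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "qc_dropped") <- sum(!keep)
  out
}

#' Retain sites by fry-occupancy frequency
#'
#' Keeps sites where the fraction of survey events with `fry_present == 1`
#' is at least `min_frequency` (boundary inclusive: a site at exactly the
#' threshold is retained; sites with "fewer than" the threshold are
#' dropped).
#'
#' @param events data.frame with columns `site_id` and `fry_present`.
#' @param min_frequency minimum positive-event fraction in \[0, 1\]
#'   (default 0.05).
#' @return character vector of retained site ids.
#' @export
filter_sites_by_occupancy <- function(events, min_frequency = 0.05) {
  if (min_frequency < 0 || min_frequency > 1)
    stop("min_frequency must be in [0, 1]")
  frac <- tapply(events$fry_present, events$site_id, mean)
  names(frac)[frac >= min_frequency]
}

#' Classify wild fry
#'
#' A fish is a wild fry iff it is unmarked and shorter than the length
#' cutoff. The cutoff is either supplied directly (default 6.7 cm) or
#' computed as the 0.05 quantile of the lengths of marked hatchery fish.
#'
#' @param length_cm fork length(s) in cm (> 0).
#' @param marked logical (or 0/1) hatchery-mark status.
#' @param length_cutoff_cm cutoff length in cm; default 6.7.
#' @param marked_lengths optional vector of marked-fish lengths from which
#'   the cutoff is computed as the 0.05 quantile (overrides
#'   `length_cutoff_cm`).
#' @return logical vector.
#' @export
classify_wild_fry <- function(length_cm, marked, length_cutoff_cm = 6.7,
                              marked_lengths = NULL) {
  if (any(length_cm <= 0)) stop("length_cm must be > 0")
  if (!is.null(marked_lengths))
    length_cutoff_cm <- stats::quantile(marked_lengths, 0.05, names = FALSE)
  !as.logical(marked) & length_cm < length_cutoff_cm
}

## resolve a travel rate by the fallback hierarchy:
## release_group x route -> route -> overall
.lookup_rate <- function(rates, release_group, route) {
  hit <- function(g, r) {
    gm <- if (is.na(g)) is.na(rates$release_group) else
      !is.na(rates$release_group) & rates$release_group == g
    rm <- if (is.na(r)) is.na(rates$route) else
      !is.na(rates$route) & rates$route == r
    w <- which(gm & rm)
    if (length(w)) rates$rate_km_day[w[1]] else NA_real_
  }
  for (cand in list(c(release_group, route), c(NA, route), c(NA, NA))) {
    rate <- hit(cand[1], cand[2])
    if (!is.na(rate)) return(rate)
  }
  stop("no usable travel rate at any hierarchy level for group '",
       release_group, "', route '", route, "'")
}

#' Construct a transit (exposure) window from telemetry detections
#'
#' Entry/exit times at the reach boundaries are taken from detections when
#' a detection occurred at the boundary position; otherwise they are
#' imputed from the temporally closest detection as
#' time +/- distance / travel rate, with the travel rate resolved by the
#' fallback hierarchy release-group-by-route, then route, then overall
#' average. Positions are river kilometers increasing downstream;
#' `entry_km <= exit_km`.
#'
#' @param detections data.frame with columns `time` (numeric days or Date)
#'   and `river_km`, ordered by time.
#' @param entry_km,exit_km boundary positions (river km).
#' @param rates data.frame with columns `release_group`, `route`
#'   (either may be `NA` for aggregated levels) and `rate_km_day`.
#' @param release_group,route identifiers of this fish used for the rate
#'   lookup.
#' @param tag_id optional identifier carried through.
#' @param position_tol tolerance (km) for treating a detection as "at" a
#'   boundary; default 1e-6.
#' @return an object of class `exposure_window`: list with `tag_id`,
#'   `entry_time`, `exit_time`, `interpolated_entry`, `interpolated_exit`.
#' @export
transit_window <- function(detections, entry_km, exit_km, rates = NULL,
                           release_group = NA, route = NA, tag_id = NA,
                           position_tol = 1e-6) {
  if (nrow(detections) < 1) stop("need at least one detection")
  if (is.unsorted(as.numeric(detections$time)))
    stop("detection timestamps must be increasing")
  add_days <- function(t, d) {
    if (inherits(t, "Date")) t + d
    else if (inherits(t, "POSIXct")) t + d * 86400
    else t + d
  }
  at_entry <- which(abs(detections$river_km - entry_km) <= position_tol)
  at_exit <- which(abs(detections$river_km - exit_km) <= position_tol)
  if (length(at_entry)) {
    entry_time <- detections$time[at_entry[1]]
    interp_entry <- FALSE
  } else {
    i <- which.min(detections$river_km) # closest to upstream boundary
    rate <- .lookup_rate(rates, release_group, route)
    entry_time <- add_days(detections$time[i],
                           -(detections$river_km[i] - entry_km) / rate)
    interp_entry <- TRUE
  }
  if (length(at_exit)) {
    exit_time <- detections$time[utils::tail(at_exit, 1)]
    interp_exit <- FALSE
  } else {
    i <- which.max(detections$river_km) # closest to downstream boundary
    rate <- .lookup_rate(rates, release_group, route)
    exit_time <- add_days(detections$time[i],
                          (exit_km - detections$river_km[i]) / rate)
    interp_exit <- TRUE
  }
  if (as.numeric(exit_time) < as.numeric(entry_time))
    stop("exit_time precedes entry_time")
  structure(list(tag_id = tag_id, entry_time = entry_time,
                 exit_time = exit_time,
                 interpolated_entry = interp_entry,
                 interpolated_exit = interp_exit),
            class = "exposure_window")
}

#' Mean environmental exposure over a transit window
#'
#' Arithmetic means of temperature, O2 partial pressure and flow over the
#' daily environmental records whose dates intersect
#' `[entry_time, exit_time]`. Days with missing values are excluded from
#' the corresponding mean (the monitoring-gap rule); a window with zero
#' overlapping records is an error.
#'
#' @param window an `exposure_window` (or list with `entry_time`,
#'   `exit_time`).
#' @param env data.frame with `date` and any of `temp_C`, `po2_kPa`,
#'   `flow`.
#' @return list with `mean_temp_C`, `mean_po2_kPa`, `mean_flow`, `n_days`.
#' @export
exposure_summary <- function(window, env) {
  to_day <- function(t) {
    if (inherits(t, "Date")) as.numeric(t)
    else if (inherits(t, "POSIXct")) as.numeric(as.Date(t))
    else as.numeric(t)
  }
  d <- to_day(as.Date(env$date))
  lo <- floor(to_day(window$entry_time))
  hi <- ceiling(to_day(window$exit_time))
  sel <- env[d >= lo & d <= hi, , drop = FALSE]
  if (nrow(sel) == 0) stop("window does not overlap the environmental series")
  m <- function(col) if (col %in% names(sel))
    mean(sel[[col]], na.rm = TRUE) else NA_real_
  list(mean_temp_C = m("temp_C"), mean_po2_kPa = m("po2_kPa"),
       mean_flow = m("flow"), n_days = nrow(sel))
}
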
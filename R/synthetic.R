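#' Configuration for the synthetic-data generators
#'
#' Returns the default "stated world" of the synthetic datasets: trait
#' truths, sample sizes and mass ranges matching the motivating study's
#' respirometry design, seasonal environmental cycles with AR(1) daily
#' noise, three-segment piecewise log-odds fitness truths anchored at the
#' published threshold estimates, and a smooth predation-probability
#' truth. Any default can be overridden by name.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param ... named overrides of any default element.
#' @return object of class `synth_config` (a list).
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ## trait truths (lifestage-level, population-averaged)
    traits = list(fry = list(A = 7.98, E = 0.16),
                  smolt = list(A = 14.81, E = 0.33),
                  bass = list(A = 21.3, E = 0.50)),
    populations = list(fry = c("fall", "late_fall", "winter"),
                       smolt = c("fall", "spring", "winter")),
    population_sd = 0.08,  # between-population SD of A (ln kPa)
    noise_cv = 0.10,       # lognormal CV of O2crit
    n = c(fry = 117L, smolt = 523L),
    mass_range_kg = list(fry = c(0.0009, 0.0070),
                         smolt = c(0.0132, 0.0409)),
    temp_range_C = c(8, 25),
    alpha = -1.12,         # mass-specific ln-ln slope; pressure ~ m^(1+alpha)
    ref_mass_kg = 0.02, ref_temp_C = 16.6,
    bass = list(n = 35L, mass_range_kg = c(0.12, 0.45),
                alpha = -0.54, ref_mass_kg = 0.23),
    ## seasonal environment (daily, multiple sites)
    env = list(n_sites = 4L, n_years = 3L, start = "2018-10-01",
               temp_mean = 16, temp_amp = 6, temp_peak_doy = 213,
               temp_noise_sd = 0.8, site_temp_sd = 0.3,
               do_sat_mean = 0.92, do_sat_amp = 0.05, do_noise_sd = 0.02,
               salinity = 0.2,
               lflow_mean = log(300), lflow_amp = 0.8,
               flow_peak_doy = 135, flow_noise_sd = 0.25,
               ar1 = 0.8),
    ## fitness truths: three-segment piecewise log-odds in phi
    thresholds = list(rearing = c(crit = 2.82, stable = 3.81),
                      migration = c(crit = 3.72, stable = 4.33)),
    segment_slopes = c(0, 2.5, 0),
    logodds_low = c(rearing = -2, migration = -2),
    flow_effect = 0.3,       # additive log-odds per SD of centered log flow
    site_intercept_sd = 0.5, # rearing only
    n_outcomes = 5000L,
    n_sites_rearing = 15L,
    phi_range = list(rearing = c(2.0, 6.5), migration = c(3.0, 6.5)),
    ## predation truth: rising in bass phi up to a cap, cold-suppressed
    ## cold suppression is strong enough to outweigh the predator's high
    ## winter phi, giving the near-zero winter event rate and warm-season
    ## predation peak the deployment record shows
    predation = list(n_deploy = 2277L, b0 = -6.5, slope = 0.8, cap = 6,
                     cold_temp_C = 12, cold_scale = 1.5, cold_depress = 5,
                     method_sd = 0.3, site_sd = 0.3,
                     dur_mean = 44, dur_sd = 33, dur_effect = 0.3,
                     methods = c(PER = 1567, sPER = 158, pPER = 552))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[nm], dots[nm])[[nm]]
  }
  stopifnot(cfg$noise_cv >= 0, all(cfg$n >= 1),
            all(vapply(cfg$thresholds, function(th)
              th[["crit"]] < th[["stable"]], logical(1))))
  structure(cfg, class = "synth_config")
}

## run code with a deterministic RNG stream derived from (seed, offset),
## restoring the caller's RNG state afterwards (generators are pure)
.with_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate synthetic respirometry records
#'
#' Draws masses uniformly on the lifestage range and test temperatures
#' uniformly on the configured range, computes true O2crit from the
#' Arrhenius traits with population offsets on `A`
#' (Normal(0, population_sd)), applies the mass-scaling law (pressure
#' exponent `1 + alpha`) and multiplicative lognormal noise (mean-zero on
#' the log scale), then inverts the FAS identity to emit SMR/MMR pairs
#' (`MMR = 21 * SMR / O2crit`). SMR itself is a lognormal nuisance
#' variable: only the MMR/SMR ratio is informative.
#'
#' @param config a [synth_config()].
#' @param species "chinook" (fry + smolt) or "largemouth_bass".
#' @return data.frame of respirometry records (with the generating truth
#'   in column `o2crit_true`).
#' @export
gen_respirometry <- function(config, species = c("chinook",
                                                 "largemouth_bass")) {
  species <- match.arg(species)
  .with_seed(config$seed, 101L, {
    if (species == "largemouth_bass") {
      b <- config$bass
      n <- b$n
      mass <- stats::runif(n, b$mass_range_kg[1], b$mass_range_kg[2])
      temp <- stats::runif(n, config$temp_range_C[1],
                           config$temp_range_C[2])
      tr <- config$traits$bass
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      o2c <- exp(tr$A - tr$E * inverse_temperature(temp)) *
        (mass / b$ref_mass_kg)^(1 + b$alpha) *
        exp(stats::rnorm(n, 0, sdlog))
      smr <- exp(stats::rnorm(n, log(120), 0.2))
      out <- data.frame(fish_id = sprintf("bass_%03d", seq_len(n)),
                        lifestage = "adult", population = "delta",
                        species = species, mass_kg = mass,
                        test_temp_C = temp, smr = smr,
                        mmr = 21 * smr / o2c, mmr_method = "swim",
                        o2crit_true = o2c)
    } else {
      rows <- lapply(names(config$n), function(ls) {
        n <- config$n[[ls]]
        pops <- config$populations[[ls]]
        pop_off <- stats::setNames(
          stats::rnorm(length(pops), 0, config$population_sd), pops)
        pop <- sample(pops, n, replace = TRUE)
        mass <- stats::runif(n, config$mass_range_kg[[ls]][1],
                             config$mass_range_kg[[ls]][2])
        temp <- stats::runif(n, config$temp_range_C[1],
                             config$temp_range_C[2])
        tr <- config$traits[[ls]]
        sdlog <- sqrt(log(1 + config$noise_cv^2))
        o2c <- exp(tr$A + pop_off[pop] - tr$E * inverse_temperature(temp)) *
          (mass / config$ref_mass_kg)^(1 + config$alpha) *
          exp(stats::rnorm(n, 0, sdlog))
        smr <- exp(stats::rnorm(n, log(200) - 0.2 * log(mass / 0.02), 0.2))
        data.frame(fish_id = sprintf("%s_%04d", ls, seq_len(n)),
                   lifestage = ls, population = pop, species = species,
                   mass_kg = mass, test_temp_C = temp, smr = smr,
                   mmr = 21 * smr / o2c,
                   mmr_method = sample(c("swim", "chase"), n, TRUE,
                                       prob = c(0.9, 0.1)),
                   o2crit_true = o2c, row.names = NULL)
      })
      out <- do.call(rbind, rows)
    }
    stopifnot(all(out$mmr >= out$smr), all(out$o2crit_true > 0),
              all(out$o2crit_true <= 21))
    out
  })
}

.seasonal <- function(doy, amp, peak_doy) {
  amp * cos(2 * pi * (doy - peak_doy) / 365.25)
}

.ar1 <- function(n, rho, sd) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  stats::filter(e, rho, method = "recursive")[seq_len(n)]
}

#' Generate a synthetic daily environmental series
#'
#' Daily temperature, dissolved oxygen, salinity and flow for several
#' monitoring sites sharing one seasonal signal with site offsets:
#' temperature is a summer-peaked sinusoid with AR(1) noise; DO is an
#' air-saturation fraction in anti-phase with temperature (warm water is
#' both less soluble and further from saturation); flow is log-normal
#' with a winter/spring peak. The resulting smolt metabolic index peaks
#' in winter and troughs in summer.
#'
#' @param config a [synth_config()].
#' @return an `EnvRecord`-schema data.frame (`site_id`, `date`, `temp_C`,
#'   `do_mgL`, `salinity`, `flow`).
#' @export
gen_environment <- function(config) {
  e <- config$env
  .with_seed(config$seed, 202L, {
    dates <- seq(as.Date(e$start), by = "day",
                 length.out = ceiling(365.25 * e$n_years))
    doy <- as.integer(format(dates, "%j"))
    n <- length(dates)
    site_off <- stats::rnorm(e$n_sites, 0, e$site_temp_sd)
    rows <- lapply(seq_len(e$n_sites), function(s) {
      temp <- e$temp_mean + site_off[s] +
        .seasonal(doy, e$temp_amp, e$temp_peak_doy) +
        .ar1(n, e$ar1, e$temp_noise_sd)
      temp <- pmin(pmax(temp, 1), 35)
      satfrac <- e$do_sat_mean -
        .seasonal(doy, e$do_sat_amp, e$temp_peak_doy) +
        .ar1(n, e$ar1, e$do_noise_sd)
      satfrac <- pmin(pmax(satfrac, 0.5), 1.1)
      sal <- pmax(e$salinity + stats::rnorm(n, 0, 0.02), 0)
      flow <- exp(e$lflow_mean + .seasonal(doy, e$lflow_amp,
                                           e$flow_peak_doy) +
                    .ar1(n, e$ar1, e$flow_noise_sd))
      data.frame(site_id = sprintf("site_%02d", s), date = dates,
                 temp_C = temp,
                 do_mgL = satfrac * o2_sat_mgL(pmin(pmax(temp, 0), 40),
                                               sal),
                 salinity = sal, flow = flow, row.names = NULL)
    })
    do.call(rbind, rows)
  })
}

## three-segment piecewise-linear log-odds in phi:
## flat (slope s1) below crit, rising (s2) between, flat (s3) above
.piecewise_logodds <- function(phi_val, crit, stable, slopes, lo_low) {
  s1 <- slopes[1]; s2 <- slopes[2]; s3 <- slopes[3]
  ifelse(phi_val < crit,
         lo_low + s1 * (phi_val - crit),
         ifelse(phi_val <= stable,
                lo_low + s2 * (phi_val - crit),
                lo_low + s2 * (stable - crit) + s3 * (phi_val - stable)))
}

#' Generate synthetic binary fitness outcomes
#'
#' Bernoulli rearing (fry presence) or migration (smolt success) outcomes
#' whose log-odds follow a three-segment piecewise-linear function of the
#' metabolic index (breakpoints at the configured true thresholds) plus
#' an additive flow effect, site intercepts for rearing, and (for
#' migration) fish length and release distance with null true effects.
#' With `env = NULL` (the calibration mode used by the acceptance tests)
#' the metabolic index is sampled uniformly on the configured range;
#' otherwise records are sampled from the metabolic-index series implied
#' by `env` and `traits`.
#'
#' @param config a [synth_config()].
#' @param behavior "rearing" or "migration".
#' @param env optional environmental table from [gen_environment()].
#' @param traits trait set used when `env` is supplied.
#' @return data.frame with `phi`, `flow_c` (centered/scaled log flow),
#'   outcome column (`fry_present` or `success`), `true_log_odds`, and
#'   behavior-specific covariates.
#' @export
gen_fitness_outcomes <- function(config, behavior = c("rearing",
                                                      "migration"),
                                 env = NULL, traits = NULL) {
  behavior <- match.arg(behavior)
  th <- config$thresholds[[behavior]]
  lo_low <- config$logodds_low[[behavior]]
  .with_seed(config$seed, if (behavior == "rearing") 303L else 404L, {
    n <- config$n_outcomes
    if (is.null(env)) {
      rng <- config$phi_range[[behavior]]
      phi_val <- stats::runif(n, rng[1], rng[2])
      flow_c <- stats::rnorm(n)
      date <- as.Date("2019-10-01") + sample.int(365, n, replace = TRUE) - 1
      site <- sprintf("site_%02d", sample.int(config$n_sites_rearing, n,
                                              replace = TRUE))
      ## temperature consistent with phi being temperature-driven, plus
      ## measurement scatter: phi (not temperature) carries the signal
      temp_C <- 24 - 2.2 * phi_val + stats::rnorm(n, 0, 0.8)
    } else {
      ps <- phi_series(env, traits)
      i <- sample.int(nrow(ps), n, replace = TRUE)
      phi_val <- ps$phi[i]
      lflow <- log(env$flow[i])
      flow_c <- (lflow - mean(log(env$flow))) / stats::sd(log(env$flow))
      date <- ps$date[i]
      site <- ps$site_id[i]
      temp_C <- ps$temp_C[i]
    }
    lo <- .piecewise_logodds(phi_val, th[["crit"]], th[["stable"]],
                             config$segment_slopes, lo_low) +
      config$flow_effect * flow_c
    if (behavior == "rearing") {
      sites <- sort(unique(site))
      s_off <- stats::setNames(
        stats::rnorm(length(sites), 0, config$site_intercept_sd), sites)
      lo <- lo + s_off[site]
      y <- stats::rbinom(n, 1, stats::plogis(lo))
      data.frame(site_id = site, date = date, phi = phi_val,
                 temp_C = temp_C, flow_c = flow_c, fry_present = y,
                 true_log_odds = lo, row.names = NULL)
    } else {
      len <- stats::rnorm(n, 14, 1.5)
      rel_km <- stats::runif(n, 50, 300)
      y <- stats::rbinom(n, 1, stats::plogis(lo))
      data.frame(tag_id = sprintf("tag_%05d", seq_len(n)), date = date,
                 phi = phi_val, temp_C = temp_C, flow_c = flow_c,
                 fish_length_cm = len, release_distance_km = rel_km,
                 success = y, true_log_odds = lo, row.names = NULL)
    }
  })
}

#' Generate synthetic tethered-prey (PER) deployments
#'
#' Samples deployment sites/dates from the environmental series, assigns
#' methods in the study's observed proportions, draws truncated-normal
#' durations (44 +/- 33 min), and draws Bernoulli predation outcomes
#' whose log-odds rise with the predator's metabolic index up to a cap,
#' are suppressed at the coldest temperatures, and include method/site
#' intercepts and a duration effect.
#'
#' @param config a [synth_config()].
#' @param env environmental table from [gen_environment()].
#' @param bass_traits predator [trait_set()]; defaults to the configured
#'   bass truth.
#' @return a `PERDeployment`-schema data.frame (plus `true_log_odds`).
#' @export
gen_predation <- function(config, env,
                          bass_traits = trait_set(config$traits$bass$A,
                                                  config$traits$bass$E,
                                                  label = "bass")) {
  p <- config$predation
  .with_seed(config$seed, 505L, {
    n <- p$n_deploy
    i <- sample.int(nrow(env), n, replace = TRUE)
    method <- sample(names(p$methods), n, replace = TRUE,
                     prob = p$methods / sum(p$methods))
    dur <- pmax(stats::rnorm(n, p$dur_mean, p$dur_sd), 5)
    temp <- env$temp_C[i] + stats::rnorm(n, 0, 0.3)
    temp <- pmin(pmax(temp, 1), 35)
    do_mgL <- pmax(env$do_mgL[i] + stats::rnorm(n, 0, 0.2), 0.5)
    sal <- env$salinity[i]
    po2 <- po2_from_do(do_mgL, pmin(pmax(temp, 0), 40), sal)
    phi_bass <- phi(po2, temp, bass_traits)
    meths <- names(p$methods)
    m_off <- stats::setNames(stats::rnorm(length(meths), 0, p$method_sd),
                             meths)
    sites <- sort(unique(env$site_id))
    s_off <- stats::setNames(stats::rnorm(length(sites), 0, p$site_sd),
                             sites)
    dur_z <- (dur - mean(dur)) / stats::sd(dur)
    lo <- p$b0 + p$slope * pmin(phi_bass, p$cap) -
      p$cold_depress / (1 + exp((temp - p$cold_temp_C) / p$cold_scale)) +
      m_off[method] + s_off[env$site_id[i]] + p$dur_effect * dur_z
    data.frame(deployment_id = sprintf("dep_%05d", seq_len(n)),
               method = method, site_id = env$site_id[i],
               start_time = env$date[i], duration_min = dur,
               temp_C = temp, do_mgL = do_mgL, salinity = sal,
               predated_by_bass = stats::rbinom(n, 1, stats::plogis(lo)),
               true_log_odds = lo, row.names = NULL)
  })
}
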
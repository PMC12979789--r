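test_that("o2crit_at_temperature evaluates the Arrhenius model", {
  expect_equal(o2crit_at_temperature(smolt_traits, 16.6), 4.92,
               tolerance = 0.001)
  expect_equal(o2crit_at_temperature(fry_traits, 16.6), 4.82,
               tolerance = 0.001)
  tr0 <- trait_set(A = 1.5, E = 0)
  expect_equal(o2crit_at_temperature(tr0, c(5, 15, 25)),
               rep(exp(1.5), 3))
})

test_that("phi has the defining value, monotonicity and equivariance", {
  oc <- o2crit_at_temperature(smolt_traits, 12)
  expect_equal(phi(oc, 12, smolt_traits), 1)
  expect_equal(phi(21, 16.6, smolt_traits), 4.27, tolerance = 0.002)
  ## strictly increasing in pO2, strictly decreasing in temperature
  expect_true(all(diff(phi(seq(1, 21, 1), 15, smolt_traits)) > 0))
  expect_true(all(diff(phi(15, seq(5, 25, 1), smolt_traits)) < 0))
  ## scale equivariance in pO2
  p <- runif(20, 1, 21)
  expect_equal(phi(3 * p, 14, fry_traits), 3 * phi(p, 14, fry_traits))
  expect_error(phi(-1, 15, smolt_traits), "po2")
})

test_that("FAS x O2crit = 21 exactly for any traits and temperature", {
  set.seed(3)
  for (i in 1:20) {
    tr <- trait_set(runif(1, 5, 25), runif(1, 0, 0.6))
    tC <- runif(1, 0, 30)
    expect_equal(fas_at_saturation(tr, tC) * o2crit_at_temperature(tr, tC),
                 21, tolerance = 1e-12)
  }
  expect_equal(fas_at_saturation(bass_traits, 16.6), 5.87,
               tolerance = 0.005)
  expect_true(all(diff(fas_at_saturation(bass_traits, seq(5, 25, 1))) < 0))
})

test_that("phi_series maps environmental records element-wise", {
  env <- data.frame(site_id = "s1", date = as.Date("2020-01-01") + 0:1,
                    temp_C = c(12, 20), po2_kPa = c(21, 15))
  ps <- phi_series(env, smolt_traits)
  expect_equal(nrow(ps), 2)
  expect_gt(ps$phi[1], ps$phi[2])
  expect_equal(ps$phi,
               c(21, 15) / o2crit_at_temperature(smolt_traits, c(12, 20)))
  ## constant env -> constant series
  envc <- data.frame(site_id = "s1", date = as.Date("2020-01-01") + 0:9,
                     temp_C = 15, po2_kPa = 18)
  expect_equal(length(unique(phi_series(envc, smolt_traits)$phi)), 1)
  ## pO2 derived from DO when absent
  envd <- data.frame(site_id = "s1", date = as.Date("2020-01-01"),
                     temp_C = 15, do_mgL = o2_sat_mgL(15, 0))
  expect_equal(phi_series(envd, smolt_traits)$po2_kPa, 20.87,
               tolerance = 0.001)
  ## missing records dropped with a message; empty input warns
  envm <- rbind(env, data.frame(site_id = "s1",
                                date = as.Date("2020-01-03"),
                                temp_C = NA, po2_kPa = 20))
  expect_message(psm <- phi_series(envm, smolt_traits), "dropped")
  expect_equal(nrow(psm), 2)
  expect_warning(phi_series(env[0, ], smolt_traits), "empty")
})

test_that("classify_phi partitions the positive axis with closed middle", {
  th <- list(crit = 2.82, stable = 3.81)
  expect_equal(as.character(classify_phi(2.5, th)), "below_crit")
  expect_equal(as.character(classify_phi(2.82, th)), "between")
  expect_equal(as.character(classify_phi(3.81, th)), "between")
  expect_equal(as.character(classify_phi(5.0, list(crit = 3.72,
                                                   stable = 4.33))),
               "above_stable")
  ## partition: every value maps to exactly one category
  set.seed(8)
  v <- c(runif(200, 0, 8), 2.82, 3.81)
  expect_false(anyNA(classify_phi(v, th)))
  expect_error(classify_phi(3, list(crit = 4, stable = 4)), "crit < stable")
})

test_that("presence-weighted fractions count categories and sum to one", {
  series <- data.frame(site_id = "s", date = as.Date("2020-01-01") + 0:9,
                       phi = c(2.0, 2.5, 3.0, 3.2, 3.5, 4.0, 4.2, 4.5,
                               5.0, 5.5))
  th <- list(crit = 2.82, stable = 3.81)
  fr <- presence_weighted_fractions(series, series$date, th)
  expect_equal(fr$frac_below_crit, 0.2)
  expect_equal(fr$frac_between, 0.3)
  expect_equal(fr$frac_above_stable, 0.5)
  expect_equal(fr$frac_below_crit + fr$frac_between + fr$frac_above_stable,
               1, tolerance = 1e-9)
  ## all presence days above stable
  hi <- presence_weighted_fractions(series, series$date[series$phi > 3.81],
                                    th)
  expect_equal(c(hi$frac_below_crit, hi$frac_between,
                 hi$frac_above_stable), c(0, 0, 1))
  expect_error(presence_weighted_fractions(series, as.Date(character()),
                                           th), "empty")
  expect_error(presence_weighted_fractions(series,
                                           as.Date("2030-01-01"), th),
               "subset")
})

test_that("predator surplus is the per-day percent excess", {
  d <- data.frame(site_id = "s", date = as.Date("2020-01-01") + 0:4)
  pred <- cbind(d, phi = rep(6, 5)); prey <- cbind(d, phi = rep(4, 5))
  expect_equal(predator_surplus(pred, prey)$mean_percent, 50)
  expect_equal(predator_surplus(prey, prey)$mean_percent, 0)
  ## single-condition bass vs fry value (16.6 C, 21 kPa)
  s <- 100 * (phi(21, 16.6, bass_traits) - phi(21, 16.6, fry_traits)) /
    phi(21, 16.6, fry_traits)
  expect_equal(s, 35, tolerance = 0.5)
  prey2 <- prey; prey2$date <- prey2$date + 1
  expect_error(predator_surplus(pred, prey2), "aligned")
})

test_that("bass phi dominates prey phi up to the Arrhenius crossover", {
  ## the bass and fry Arrhenius lines cross at
  ## invT = (21.3 - 7.98)/(0.50 - 0.16) = 39.18, i.e. ~23.0 C; below
  ## that temperature the predator's O2crit is lower, so its phi is
  ## higher at any shared pO2. Versus smolts the crossover sits at
  ## ~30.8 C, outside the habitable range.
  cross_fry <- 1 / (8.617333e-5 * (21.3 - 7.98) / (0.50 - 0.16)) - 273.15
  expect_equal(cross_fry, 23.0, tolerance = 0.005)
  tC <- seq(5, cross_fry - 0.05, by = 0.05)
  expect_true(all(phi(15, tC, bass_traits) > phi(15, tC, fry_traits)))
  expect_false(all(phi(15, seq(5, 25, 0.1), bass_traits) >
                     phi(15, seq(5, 25, 0.1), fry_traits)))
  expect_true(all(phi(15, seq(5, 25, 0.1), bass_traits) >
                    phi(15, seq(5, 25, 0.1), smolt_traits)))
})

test_that("seasonal smooth recovers a sinusoid and resists outliers", {
  set.seed(14)
  n_day <- 500
  mkdat <- function(noise) {
    dates <- rep(as.Date("2019-10-01") + 0:(n_day - 1), 2)
    wy <- water_year_day(dates)
    truth <- 4 + 1.2 * cos(2 * pi * (wy - 120) / 365.25)
    data.frame(site_id = rep(c("a", "b"), each = n_day),
               date = dates, phi = truth + noise, truth = truth)
  }
  cover <- vapply(1:3, function(i) {
    di <- mkdat(0.15 * rt(2 * n_day, df = 5))
    fit <- seasonal_phi_smooth(di)
    truth_grid <- 4 + 1.2 * cos(2 * pi * (fit$grid$wyday - 120) / 365.25)
    mean(truth_grid >= fit$grid$lo & truth_grid <= fit$grid$hi)
  }, numeric(1))
  expect_gte(mean(cover), 0.9)
  d <- mkdat(0.15 * rt(2 * n_day, df = 5))
  ## zero-noise constant input -> flat prediction at the constant
  dc <- mkdat(0); dc$phi <- 3.3
  fc <- seasonal_phi_smooth(dc, t_dof = 5, t_scale = 0.01)
  expect_equal(fc$grid$fit, rep(3.3, 366), tolerance = 1e-3)
  ## heavy outliers move the robust fit less than a Gaussian-loss fit
  do <- mkdat(0.15 * rnorm(2 * n_day))
  out_idx <- sample(nrow(do), round(0.01 * nrow(do)))
  do$phi[out_idx] <- do$phi[out_idx] + 12
  fr <- seasonal_phi_smooth(do)
  fg <- seasonal_phi_smooth(do, gaussian = TRUE)
  tg <- 4 + 1.2 * cos(2 * pi * (fr$grid$wyday - 120) / 365.25)
  expect_lt(max(abs(fr$grid$fit - tg)), max(abs(fg$grid$fit - tg)))
  expect_error(seasonal_phi_smooth(d[d$site_id == "a", ]), "2 sites")
  expect_error(seasonal_phi_smooth(d[water_year_day(d$date) < 100, ]),
               "seasonal cycle")
})

test_that("scaled-t smooth reduces to penalized least squares as nu grows", {
  set.seed(5)
  d <- data.frame(phi = sin(2 * pi * (1:1000) / 366) + rnorm(1000, 0, 0.1),
                  date = as.Date("2019-10-01") + rep(0:499, 2),
                  site_id = rep(c("a", "b"), each = 500))
  g <- seasonal_phi_smooth(d, gaussian = TRUE)
  s <- seasonal_phi_smooth(d, t_dof = 1e6, t_scale = sqrt(g$model$sig2))
  expect_lt(max(abs(g$grid$fit - s$grid$fit)), 1e-6)
})
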
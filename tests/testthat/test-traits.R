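test_that("o2crit_from_fas implements the FAS identity", {
  expect_equal(o2crit_from_fas(2, 8), 5.25)
  expect_equal(o2crit_from_fas(3, 3), 21)
  expect_equal(o2crit_from_fas(3, 12.6), 5.0)
  ## pipeline identity: o2crit * (mmr/smr) = 21 exactly
  set.seed(2)
  smr <- runif(50, 50, 300); fas <- runif(50, 1, 6)
  expect_equal(o2crit_from_fas(smr, smr * fas) * fas, rep(21, 50))
  expect_error(o2crit_from_fas(5, 4), "unphysical")
  expect_error(o2crit_from_fas(-1, 4), "> 0")
})

test_that("temperature standardization removes a known Arrhenius slope", {
  ## constant mass so the pooled slope is exactly -E
  r <- make_resp(n = 30, alpha = -1, mass = rep(0.02, 30))
  r$o2crit_kPa <- o2crit_from_fas(r$smr, r$mmr)
  rs <- suppressWarnings(standardize_temperature(r, ref_temp_C = 16.6))
  ## noiseless: every standardized value equals the curve at 16.6 C
  expect_equal(rs$o2crit_Tstd,
               rep(exp(14.81 - 0.33 * inverse_temperature(16.6)), 30),
               tolerance = 1e-10)
  expect_equal(attr(rs, "fit")$b, -0.33, tolerance = 1e-10)
  ## slope-zero data: standardization is the identity
  r0 <- make_resp(n = 10, A = log(5), E = 0, alpha = -1,
                  mass = rep(0.02, 10))
  r0$o2crit_kPa <- o2crit_from_fas(r0$smr, r0$mmr)
  rs0 <- suppressWarnings(standardize_temperature(r0))
  expect_equal(rs0$o2crit_Tstd, rs0$o2crit_kPa, tolerance = 1e-12)
  ## two-point fit reproduces the secant slope (closed form)
  r2 <- data.frame(o2crit_kPa = c(4, 6), test_temp_C = c(10, 20),
                   mass_kg = c(0.02, 0.02))
  r2 <- rbind(r2, r2[1, ]) # >= 3 records, two distinct temperatures
  rs2 <- suppressWarnings(standardize_temperature(r2))
  secant <- (log(6) - log(4)) /
    (inverse_temperature(20) - inverse_temperature(10))
  expect_equal(attr(rs2, "fit")$b, secant, tolerance = 1e-9)
  expect_error(standardize_temperature(
    data.frame(o2crit_kPa = 1:5, test_temp_C = 10, mass_kg = 0.02)),
    "single temperature")
})

test_that("mass-scaling fit recovers a known power law exactly", {
  ## noiseless mass-specific law: ln(q) = 1.16 - 1.12 ln m at one temp
  m <- seq(0.001, 0.04, length.out = 25)
  d <- data.frame(mass_kg = m, o2crit_Tstd = exp(1.16) * m^(-1.12) * m)
  sc <- suppressWarnings(fit_mass_scaling(d)) # lm warns on perfect fits
  expect_equal(sc$alpha, -1.12, tolerance = 1e-10)
  expect_equal(sc$beta, 1.16, tolerance = 1e-10)
  ## mass-independent mass-specific values -> alpha ~ 0
  d0 <- data.frame(mass_kg = m, o2crit_Tstd = 5 * m)
  expect_equal(suppressWarnings(fit_mass_scaling(d0))$alpha, 0,
               tolerance = 1e-10)
  ## doubling every mass: alpha unchanged, beta shifts by -(1+alpha)ln2
  d2 <- d; d2$mass_kg <- 2 * d2$mass_kg
  sc2 <- suppressWarnings(fit_mass_scaling(d2))
  expect_equal(sc2$alpha, sc$alpha, tolerance = 1e-9)
  expect_equal(sc2$beta - sc$beta, -(1 + sc$alpha) * log(2),
               tolerance = 1e-9)
  expect_error(fit_mass_scaling(
    data.frame(mass_kg = rep(0.02, 5), o2crit_Tstd = 1:5)),
    "single mass")
})

test_that("mass standardization applies the pressure exponent 1 + alpha", {
  d <- data.frame(o2crit_kPa = c(5, 5, 5), mass_kg = c(0.02, 0.04, 0.01))
  ## alpha = -1: pressure is mass-independent, identity
  s1 <- standardize_mass(d, list(alpha = -1, ref_mass_kg = 0.02))
  expect_equal(s1$o2crit_std, d$o2crit_kPa)
  ## mass = ref: identity regardless of alpha
  s2 <- standardize_mass(d[1, ], list(alpha = -1.12, ref_mass_kg = 0.02))
  expect_equal(s2$o2crit_std, 5)
  ## alpha = -1.12, mass = 2 x ref: factor (1/2)^(-0.12) = 2^0.12
  s3 <- standardize_mass(d[2, ], list(alpha = -1.12, ref_mass_kg = 0.02))
  expect_equal(s3$o2crit_std, 5 * 2^0.12, tolerance = 1e-12)
})

test_that("fixed-effects Arrhenius fit recovers noiseless truths", {
  cfg <- synth_config(seed = 7, noise_cv = 0, population_sd = 0)
  est <- estimate_traits(gen_respirometry(cfg), model = "mr")
  tr <- est$fit$traits
  ## recovery is limited only by the pooled temperature-standardization
  ## step (two lifestages with different E); tolerances reflect that
  expect_equal(est$scaling$alpha, -1.12, tolerance = 0.01)
  expect_equal(tr$A[tr$lifestage == "smolt"][1], 14.81, tolerance = 0.02)
  expect_equal(tr$E[tr$lifestage == "smolt"][1], 0.33, tolerance = 1e-3)
  expect_equal(tr$A[tr$lifestage == "fry"][1], 7.98, tolerance = 0.02)
  expect_equal(tr$E[tr$lifestage == "fry"][1], 0.16, tolerance = 0.01)
  ## no population offsets -> population coefficients ~ 0
  pops <- coef(est$fit$model)[grep("population", names(coef(est$fit$model)))]
  expect_lt(max(abs(pops)), 1e-3)
  ## CIs bracket the point estimates
  expect_true(all(tr$A_lo <= tr$A & tr$A <= tr$A_hi))
  expect_true(all(tr$E_lo <= tr$E & tr$E <= tr$E_hi))
})

test_that("fixed-effects fit equals hand-rolled normal equations", {
  cfg <- synth_config(seed = 4, n = c(fry = 14L, smolt = 16L))
  est <- estimate_traits(gen_respirometry(cfg), model = "mr")
  d <- est$records
  X <- stats::model.matrix(
    ~ inverse_temperature(test_temp_C) * factor(lifestage) +
      factor(population), data = d)
  beta <- solve(crossprod(X), crossprod(X, log(d$o2crit_std)))
  fitted_coef <- coef(est$fit$model)
  expect_equal(unname(drop(beta)), unname(fitted_coef), tolerance = 1e-10)
})

test_that("fixed-effects fit names aliased terms on rank deficiency", {
  r <- make_resp(n = 30)
  r2 <- make_resp(n = 30, A = 7.98, E = 0.16, lifestage = "fry",
                  population = "winter")
  d <- rbind(r, r2) # lifestage and population perfectly confounded
  d$smr <- 100
  d$o2crit_kPa <- o2crit_from_fas(d$smr, d$mmr)
  d <- standardize_temperature(d)
  d <- standardize_mass(d, list(alpha = -1.12, ref_mass_kg = 0.02))
  expect_error(fit_arrhenius_fixed(d), "aliased")
})

test_that("mixed fit degenerates to the fixed fit and falls back cleanly", {
  cfg <- synth_config(seed = 11, population_sd = 0)
  est_mr <- estimate_traits(gen_respirometry(cfg), model = "mr")
  est_lmer <- estimate_traits(gen_respirometry(cfg), model = "lmer")
  tf <- est_mr$fit$traits; tm <- est_lmer$fit$traits
  for (s in c("fry", "smolt")) {
    expect_equal(tm$A[tm$lifestage == s],
                 mean(tf$A[tf$lifestage == s]), tolerance = 0.02)
    expect_equal(tm$E[tm$lifestage == s],
                 tf$E[tf$lifestage == s][1], tolerance = 0.02)
  }
  ## single population -> warning + fixed-effects fallback
  r <- gen_respirometry(cfg)
  r <- r[r$population == "fall" & r$lifestage == "smolt", ]
  r$o2crit_kPa <- o2crit_from_fas(r$smr, r$mmr)
  r <- standardize_temperature(r)
  r <- standardize_mass(r, list(alpha = -1.12, ref_mass_kg = 0.02))
  expect_warning(fit_arrhenius_mixed(r), "single population")
})

test_that("bootstrap CI width shrinks with sample size", {
  mk <- function(n, seed) {
    cfg <- synth_config(seed = seed,
                        n = c(fry = as.integer(n / 4), smolt = as.integer(n)))
    estimate_traits(gen_respirometry(cfg), model = "lmer", n_boot = 60,
                    seed = seed)
  }
  small <- mk(150, 21)$fit$traits
  big <- mk(1200, 21)$fit$traits
  w <- function(t) t$E_hi[t$lifestage == "smolt"] -
    t$E_lo[t$lifestage == "smolt"]
  expect_lt(w(big), w(small))
})

test_that("sign convention holds: negative slope, E reported positive", {
  for (s in 1:5) {
    est <- estimate_traits(gen_respirometry(synth_config(seed = s)),
                           model = "lmer")
    expect_true(all(est$fit$traits$E >= 0))
    expect_lt(lme4::fixef(est$fit$model)[["invT"]], 0)
  }
})

test_that("smolt temperature sensitivity is recovered precisely", {
  ## spec-style parameter recovery, scaled to 10 seeds for suite speed
  err <- vapply(1:10, function(s) {
    est <- estimate_traits(gen_respirometry(synth_config(seed = s)),
                           model = "lmer")
    abs(est$fit$traits$E[est$fit$traits$lifestage == "smolt"] - 0.33)
  }, numeric(1))
  expect_lt(median(err), 0.02)
})
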
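## shared trait sets (published point estimates, used as fixture truths)
smolt_traits <- trait_set(A = 14.81, E = 0.33, label = "smolt")
fry_traits <- trait_set(A = 7.98, E = 0.16, label = "fry")
bass_traits <- trait_set(A = 21.3, E = 0.50, label = "largemouth_bass")

## noiseless three-segment piecewise log-odds curve
piecewise3 <- function(x, crit, stable, lo_low, s2, s1 = 0, s3 = 0) {
  ifelse(x < crit, lo_low + s1 * (x - crit),
         ifelse(x <= stable, lo_low + s2 * (x - crit),
                lo_low + s2 * (stable - crit) + s3 * (x - stable)))
}

## noiseless respirometry table from an exact Arrhenius + mass-scaling law
## (single lifestage, single population unless given)
make_resp <- function(n = 40, A = 14.81, E = 0.33, alpha = -1.12,
                      ref_mass = 0.02, mass = NULL, temp = NULL,
                      lifestage = "smolt", population = "fall") {
  if (is.null(mass)) mass <- seq(0.013, 0.041, length.out = n)
  if (is.null(temp)) temp <- seq(8, 25, length.out = n)
  o2c <- exp(A - E * inverse_temperature(temp)) *
    (mass / ref_mass)^(1 + alpha)
  smr <- rep(100, n)
  data.frame(fish_id = seq_len(n), lifestage = lifestage,
             population = population, mass_kg = mass, test_temp_C = temp,
             smr = smr, mmr = 21 * smr / o2c)
}

## small rearing pipeline: generate -> fit -> thresholds (used by several
## test files); n kept modest for test-suite speed
fit_rearing <- function(seed, n_outcomes = 5000L) {
  cfg <- synth_config(seed = seed, n_outcomes = as.integer(n_outcomes))
  dat <- gen_fitness_outcomes(cfg, "rearing")
  spec <- smooth_model_spec("fry_present",
                            smooths = list(phi = list(k = 7),
                                           flow_c = list(k = 7)),
                            interactions = list(c("phi", "flow_c")),
                            random = "site_id")
  fit_binomial_smooth(dat, spec)
}

fit_migration <- function(seed, n_outcomes = 5000L) {
  cfg <- synth_config(seed = seed, n_outcomes = as.integer(n_outcomes))
  dat <- gen_fitness_outcomes(cfg, "migration")
  spec <- smooth_model_spec("success",
                            smooths = list(phi = list(k = 7),
                                           flow_c = list(k = 7),
                                           fish_length_cm = list(k = 7),
                                           release_distance_km = list(k = 7)),
                            interactions = list(c("phi", "flow_c")))
  fit_binomial_smooth(dat, spec)
}
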
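test_that("the TPC shape is unimodal, left-skewed and zero beyond the maximum", {
  s <- tpc_shape(r_max = 1.4, t_opt = 25, t_max = 33, sigma_rise = 5)
  expect_equal(tpc_value(s, 25), 1.4) # optimum
  expect_equal(tpc_value(s, 33), 0) # critical maximum
  expect_equal(tpc_value(s, 40), 0)
  expect_lt(tpc_value(s, 26), 1.4)
  expect_lt(tpc_value(s, 33 - 1e-6), 1e-3)
  # negatively skewed: fall is steeper than rise at the same offset
  expect_lt(tpc_value(s, 25 + 4), tpc_value(s, 25 - 4))
  # continuous at the optimum
  expect_equal(tpc_value(s, 25 - 1e-9), tpc_value(s, 25 + 1e-9), tolerance = 1e-6)
  expect_error(tpc_shape(t_opt = 30, t_max = 25), "exceed")
  expect_error(tpc_shape(r_max = -1), "positive")
})

test_that("scenario validation rejects malformed settings", {
  expect_error(sim_scenario("shift", assay_temps = c(0, -2, 4)), "increasing")
  expect_error(sim_scenario("shift", noise_sd = 0), "positive")
  expect_error(sim_scenario("shift", height_gain = -1.5), "-1")
  expect_error(sim_scenario("sideways"), "arg")
})

test_that("simulation is byte-identical under a fixed seed and leaves the RNG
           state alone", {
  scn <- sim_scenario("shift", n_species = 3, seed = 123)
  set.seed(1)
  a <- simulate_experiment(scn)
  before <- runif(1)
  b <- simulate_experiment(scn)
  expect_identical(a, b)
  set.seed(1)
  expect_identical(runif(1), before) # generator restored the RNG state
})

test_that("simulated tables satisfy the tpcmeta-v1 schema and hierarchy", {
  sim <- simulate_experiment(sim_scenario("hotter_is_wider", seed = 5))
  expect_identical(names(sim), assay_schema())
  expect_silent(validate_assay_table(sim))
  # every TPC sits in exactly one study, every study in one species
  map <- dplyr::distinct(sim, tpc_id, study_id, species_id)
  expect_equal(nrow(map), dplyr::n_distinct(sim$tpc_id))
  expect_true(all(table(dplyr::distinct(map, study_id, species_id)$study_id) == 1))
  # the selection temperature itself is always assayed
  at_sel <- dplyr::summarise(dplyr::group_by(sim, tpc_id),
    has0 = any(abs(assay_temp - selection_temp) < 1e-9)
  )
  expect_true(all(at_sel$has0))
})

test_that("null scenario effects scatter around zero", {
  scn <- sim_scenario("null", n_species = 12, seed = 31)
  eff <- apply_exclusions(
    compute_effects(normalize_dispersion(simulate_experiment(scn)))
  )$kept
  expect_gte(dplyr::n_distinct(eff$tpc_id), 20)
  mc_se <- sd(eff$rel_fitness) / sqrt(nrow(eff))
  expect_lt(abs(mean(eff$rel_fitness)), 2 * mc_se + 0.01)
})

test_that("scenario fingerprints: shift trades off below the selection
           temperature, hotter-is-better raises the maximum", {
  shift <- apply_exclusions(compute_effects(normalize_dispersion(
    simulate_experiment(sim_scenario("shift", n_species = 12, seed = 42))
  )))$kept
  below <- shift$rel_fitness[shift$rel_assay_temp < -1]
  at_above <- shift$rel_fitness[shift$rel_assay_temp >= 0]
  expect_lt(mean(below), 0)
  expect_gt(mean(at_above), 0)

  hb_assays <- normalize_dispersion(
    simulate_experiment(sim_scenario("hotter_is_better", n_species = 16, seed = 43))
  )
  hib <- hotter_is_better_effects(hb_assays)
  expect_gte(nrow(hib), 20)
  expect_gt(mean(hib$rel_fitness), 0)

  # under the null the max-vs-max effect is centred at zero
  null_assays <- normalize_dispersion(
    simulate_experiment(sim_scenario("null", n_species = 16, seed = 43))
  )
  hib0 <- hotter_is_better_effects(null_assays)
  expect_lt(
    abs(mean(hib0$rel_fitness)),
    2 * sd(hib0$rel_fitness) / sqrt(nrow(hib0)) + 0.02
  )
})

test_that("direct effect simulation obeys its stated moments", {
  # all variances zero, constant SE: CLT sanity for the sample mean
  eff <- simulate_effects_direct(
    mu = 0.3, sigma_species = 0, sigma_study = 0,
    n_species = 5, n_studies_per_species = 4, n_effects_per_study = 10,
    se = c(0.1, 0.1000001), seed = 77
  )
  expect_equal(nrow(eff), 200)
  expect_lt(abs(mean(eff$rel_fitness) - 0.3), 3 * 0.1 / sqrt(200))
  expect_identical(
    eff,
    simulate_effects_direct(
      mu = 0.3, sigma_species = 0, sigma_study = 0,
      n_species = 5, n_studies_per_species = 4, n_effects_per_study = 10,
      se = c(0.1, 0.1000001), seed = 77
    )
  )
  # truth bookkeeping for recovery studies
  expect_equal(attr(eff, "truth")$mu, 0.3)
  expect_true(all(eff$rel_fitness_se > 0))
})

test_that("cubic truth produces a cubic mean structure", {
  eff <- simulate_effects_direct(
    mu = 0, beta = c(dt3 = 0.002),
    sigma_species = 0.05, sigma_study = 0.05,
    n_species = 10, n_studies_per_species = 3, n_effects_per_study = 10,
    seed = 13
  )
  fit_lm <- lm(rel_fitness ~ poly(rel_assay_temp, 3, raw = TRUE), data = eff)
  expect_equal(unname(coef(fit_lm)[4]), 0.002, tolerance = 0.25)
})
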
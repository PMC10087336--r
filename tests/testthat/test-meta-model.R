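# Internal reconstruction of per-draw linear predictors, independent of the
# vectorised implementation in the package (used as a brute-force oracle).
theta_draws_loop <- function(fit) {
  n <- length(fit$design$y)
  out <- matrix(NA_real_, fit$n_draws, n)
  for (d in seq_len(fit$n_draws)) {
    for (i in seq_len(n)) {
      mu <- sum(fit$design$X[i, ] * fit$beta[d, ])
      for (lev in fit$spec$random) {
        mu <- mu + fit$u[[lev]][d, fit$design$levels[[lev]][i]]
      }
      out[d, i] <- mu
    }
  }
  out
}

test_that("build_design produces the documented fixed-effect columns", {
  eff <- toy_effects(rnorm(10), rep(0.1, 10))
  d0 <- build_design(eff, test_spec())
  expect_equal(colnames(d0$X), "(Intercept)")
  expect_equal(length(unique(d0$levels$species)), 10)
  expect_equal(length(unique(d0$levels$study)), 10)

  eff$rel_assay_temp <- seq(-5, 4, 1)
  d3 <- build_design(eff, test_spec(poly_degree = 3))
  expect_equal(colnames(d3$X), c("(Intercept)", "dt", "dt2", "dt3"))
  expect_equal(d3$X[, "dt3"], eff$rel_assay_temp^3)

  dv <- build_design(eff, test_spec(fixed = "var", abs_dt = TRUE))
  expect_equal(colnames(dv$X), c("(Intercept)", "abs_dt", "var_de_novo"))
  expect_equal(dv$X[, "abs_dt"], abs(eff$rel_assay_temp))
})

test_that("requesting the generations moderator with missing values errors", {
  eff <- toy_effects(rnorm(6), rep(0.1, 6))
  eff$generations[3] <- NA
  expect_error(build_design(eff, test_spec(fixed = "gen")), "reduced")
  expect_error(
    build_design(dplyr::mutate(eff, rel_fitness_se = 0), test_spec()),
    "positive"
  )
})

test_that("with level variances forced to zero the posterior mean is the
           inverse-variance-weighted mean", {
  y <- c(0.1, 0.3, -0.2, 0.5, 0.0)
  se <- c(0.05, 0.1, 0.2, 0.1, 0.05)
  eff <- toy_effects(y, se, study = rep("st1", 5), species = rep("sp1", 5))
  spec <- meta_model_spec(
    random = "study",
    priors = list(beta_sd = 10, sigma_rate = 1e6),
    iterations = 4000, warmup = 500, chains = 2
  )
  fit <- fit_meta(eff, spec = spec, seed = 42)
  ivw <- sum(y / se^2) / sum(1 / se^2)
  mu_draws <- fit$beta[, 1]
  mcse <- sd(mu_draws) / sqrt(fit$ess["(Intercept)"])
  expect_lt(abs(mean(mu_draws) - ivw), 2 * mcse + 1e-4)
  # independent frequentist oracle for the same quantity
  skip_if_not_installed("metafor")
  fe <- metafor::rma(yi = y, sei = se, method = "FE")
  expect_equal(ivw, as.numeric(fe$beta), tolerance = 1e-10)
})

test_that("an uninformative likelihood returns the coefficient prior", {
  eff <- toy_effects(rnorm(10), rep(1e3, 10), study = rep("st1", 10))
  spec <- meta_model_spec(
    random = "study", priors = list(beta_sd = 1, sigma_rate = 1e6),
    iterations = 6000, warmup = 500, chains = 2
  )
  fit <- fit_meta(eff, spec = spec, seed = 5)
  expect_lt(abs(mean(fit$beta[, 1])), 0.1)
  expect_equal(sd(fit$beta[, 1]), 1, tolerance = 0.1)
})

test_that("fits are reproducible given a seed and draw counts are honoured", {
  eff <- simulate_effects_direct(n_species = 4, n_studies_per_species = 2,
    n_effects_per_study = 3, seed = 8
  )
  f1 <- fit_meta(eff, spec = test_spec(), seed = 99)
  f2 <- fit_meta(eff, spec = test_spec(), seed = 99)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma, f2$sigma)
  expect_equal(f1$n_draws, 2 * (2000 - 500))
  expect_true(all(f1$sigma >= 0))
})

test_that("pointwise log-likelihood equals brute-force normal densities", {
  eff <- simulate_effects_direct(
    n_species = 3, n_studies_per_species = 2,
    n_effects_per_study = 2, seed = 31
  )
  fit <- fit_meta(eff, spec = meta_model_spec(
    iterations = 700, warmup = 500, chains = 1
  ), seed = 3)
  ll <- pointwise_loglik(fit)
  theta <- theta_draws_loop(fit)
  brute <- matrix(NA_real_, nrow(theta), ncol(theta))
  for (d in seq_len(nrow(theta))) {
    for (i in seq_len(ncol(theta))) {
      brute[d, i] <- dnorm(fit$design$y[i], theta[d, i], fit$design$se[i], log = TRUE)
    }
  }
  expect_equal(unname(ll), brute, tolerance = 1e-12)
  expect_true(all(is.finite(ll)))
})

test_that("waic matches direct formula evaluation", {
  # constant matrix: lppd = n * c, p_waic = 0
  const <- matrix(-1.3, nrow = 50, ncol = 4)
  w <- waic(const)
  expect_equal(w$lppd, 4 * -1.3)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * 4 * -1.3)

  m <- matrix(c(-1, -2, -1.5, -2.5, -0.5, -1.5), nrow = 3, byrow = TRUE)
  w2 <- waic(m)
  lppd <- sum(log(colMeans(exp(m))))
  p <- sum(apply(m, 2, var))
  expect_equal(w2$lppd, lppd, tolerance = 1e-12)
  expect_equal(w2$p_waic, p, tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (lppd - p), tolerance = 1e-12)

  # invariant to effect (column) ordering
  expect_equal(waic(m)$waic, waic(m[, 2:1])$waic)
})

test_that("model ranking applies Akaike-style weights and guards subsets", {
  eff <- simulate_effects_direct(
    n_species = 4, n_studies_per_species = 2,
    n_effects_per_study = 2, seed = 77
  )
  spec <- test_spec()
  f <- fit_meta(eff, spec = spec, seed = 1)
  r1 <- rank_models(list(only = f))
  expect_equal(r1$weight, 1)

  # closed-form weights from synthetic WAIC values 100 and 102
  d <- c(0, 2)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(round(w, 3), c(0.731, 0.269))

  f2 <- fit_meta(eff[1:10, ], spec = spec, seed = 1)
  expect_error(rank_models(list(a = f, b = f2)), "different")
})

test_that("posterior true effects shrink observations toward the population mean", {
  set.seed(14)
  eff <- toy_effects(rnorm(12, 0.3, 0.6), rep(0.25, 12),
    study = rep("st1", 12), species = rep("sp1", 12)
  )
  eff$tpc_id <- sprintf("tpc%02d", 1:12) # one latent effect per record
  spec <- meta_model_spec(
    random = c("study", "tpc"),
    iterations = 4000, warmup = 500, chains = 2
  )
  fit <- fit_meta(eff, spec = spec, seed = 6)
  theta_hat <- colMeans(theta_draws_loop(fit))
  pop <- mean(fit$beta[, 1]) + colMeans(fit$u$study)[1]
  tol <- 0.03
  for (i in seq_len(12)) {
    lo <- min(eff$rel_fitness[i], pop) - tol
    hi <- max(eff$rel_fitness[i], pop) + tol
    expect_gte(theta_hat[i], lo)
    expect_lte(theta_hat[i], hi)
  }
})

test_that("duplicating every effect tightens the posterior for the mean", {
  # in the vanishing-heterogeneity limit the posterior for the mean is
  # driven by measurement information alone, so doubling the data shrinks
  # its SD by roughly sqrt(2)
  eff <- simulate_effects_direct(
    sigma_species = 0, sigma_study = 0, se = c(0.3, 0.5),
    n_species = 5, n_studies_per_species = 2,
    n_effects_per_study = 3, seed = 55
  )
  dup <- dplyr::bind_rows(eff, dplyr::mutate(eff,
    effect_id = paste0(effect_id, "b"), tpc_id = paste0(tpc_id, "b")
  ))
  spec <- meta_model_spec(
    priors = list(sigma_rate = 1e6),
    iterations = 4000, warmup = 500, chains = 2
  )
  f1 <- fit_meta(eff, spec = spec, seed = 2)
  f2 <- fit_meta(dup, spec = spec, seed = 2)
  expect_lt(sd(f2$beta[, 1]), sd(f1$beta[, 1]))
})

test_that("predict_curve is flat for an intercept model and flags extrapolation", {
  eff <- simulate_effects_direct(
    n_species = 4, n_studies_per_species = 2,
    n_effects_per_study = 2, beta = c(dt = 0.001), seed = 9
  )
  fit <- fit_meta(eff, spec = test_spec(), seed = 9)
  pred <- predict_curve(fit, grid = c(-5, 0, 5))
  expect_equal(pred$estimate, rep(median(fit$beta[, 1]), 3))
  expect_false(any(pred$extrapolated))
  expect_warning(
    pred2 <- predict_curve(fit, grid = c(-100, 0)),
    "extrapolation"
  )
  expect_true(pred2$extrapolated[1])
  expect_true(all(pred$conf.low <= pred$estimate & pred$estimate <= pred$conf.high))
})

test_that("the variation-source moderator moves predictions by its coefficient", {
  eff <- simulate_effects_direct(
    n_species = 6, n_studies_per_species = 2,
    n_effects_per_study = 3, seed = 12
  )
  fit <- fit_meta(eff, spec = test_spec(fixed = "var"), seed = 12)
  p_std <- predict_curve(fit, grid = 0, moderators = list(var = "standing"))
  p_dn <- predict_curve(fit, grid = 0, moderators = list(var = "de_novo"))
  # per-draw the two settings differ exactly by the var coefficient
  expect_equal(
    p_dn$estimate - p_std$estimate,
    median(fit$beta[, "(Intercept)"] + fit$beta[, "var_de_novo"]) -
      median(fit$beta[, "(Intercept)"]),
    tolerance = 1e-12
  )
})

test_that("hotter-is-better effects use curve maxima with tie-break to cooler", {
  base <- toy_assays(1)
  tpc <- dplyr::bind_rows(lapply(c(20, 25, 30, 35), function(t) {
    dplyr::mutate(base,
      tpc_id = "T1", reproduction_mode = "discrete", assay_temp = t
    )
  }))
  tpc$f_sel_mean <- c(0.8, 1.0, 1.5, 0.9)
  tpc$f_anc_mean <- c(0.9, 1.2, 1.0, 0.4)
  tpc$disp_sel <- c(0.2, 0.2, 0.1, 0.2)
  tpc$disp_anc <- c(0.2, 0.1, 0.2, 0.2)
  hib <- hotter_is_better_effects(tpc)
  expect_equal(nrow(hib), 1)
  expect_equal(hib$rel_fitness, 1.5 / 1.2 - 1)
  expect_equal(
    hib$rel_fitness_se,
    (1.5 / 1.2) * sqrt((0.1 / 1.5)^2 + (0.1 / 1.2)^2),
    tolerance = 1e-12
  )
  expect_equal(hib$rel_assay_temp, 30 - 25)

  # identical curves: zero effect
  tpc2 <- dplyr::mutate(tpc, f_sel_mean = f_anc_mean, tpc_id = "T2")
  expect_equal(hotter_is_better_effects(tpc2)$rel_fitness, 0)

  # tie in the maximum resolves to the lower temperature's dispersion
  tpc3 <- dplyr::mutate(tpc, tpc_id = "T3")
  tpc3$f_anc_mean <- c(1.2, 1.0, 1.2, 0.4)
  tpc3$disp_anc <- c(0.05, 0.1, 0.3, 0.2)
  hib3 <- hotter_is_better_effects(tpc3)
  expect_equal(
    hib3$rel_fitness_se,
    (1.5 / 1.2) * sqrt((0.1 / 1.5)^2 + (0.05 / 1.2)^2),
    tolerance = 1e-12
  )

  # TPCs with too few temperatures are dropped
  expect_equal(nrow(hotter_is_better_effects(tpc[1:3, ])), 0)
})
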
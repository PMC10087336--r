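## Synthetic TPC selection experiments. The generator emulates the
## statistical structure of an extracted assay table: a species -> study ->
## TPC -> assay-point hierarchy, unimodal left-skewed thermal performance
## curves, heteroscedastic replicate-based sampling error, and the
## moderators used in the meta-regression (variation source, reproduction,
## comparison type, generations, relative selection temperature).

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Thermal performance curve shape
#'
#' A unimodal, negatively skewed performance curve: a Gaussian rise up to
#' the thermal optimum and a steeper quadratic fall between the optimum and
#' the critical maximum, beyond which performance is zero. This is the
#' standard qualitative ectotherm shape; the analyses make no use of any
#' particular parametric family, so the form is a simulator choice.
#'
#' @param r_max Performance at the optimum (> 0).
#' @param t_opt Thermal optimum, degrees Celsius.
#' @param t_max Critical thermal maximum, degrees Celsius (> `t_opt`).
#' @param sigma_rise Width of the Gaussian rising limb, degrees Celsius.
#' @return Object of class `tpc_shape`.
#' @export
tpc_shape <- function(r_max = 1, t_opt = 25, t_max = 33, sigma_rise = 5) {
  if (r_max <= 0) cli::cli_abort("{.arg r_max} must be positive.")
  if (t_max <= t_opt) cli::cli_abort("{.arg t_max} must exceed {.arg t_opt}.")
  if (sigma_rise <= 0) cli::cli_abort("{.arg sigma_rise} must be positive.")
  structure(
    list(r_max = r_max, t_opt = t_opt, t_max = t_max, sigma_rise = sigma_rise),
    class = "tpc_shape"
  )
}

#' Evaluate a thermal performance curve
#'
#' @param shape A [tpc_shape()].
#' @param temp Temperature(s), degrees Celsius.
#' @return Performance value(s): `r_max * exp(-((T - t_opt) / (2 sigma_rise))^2)`
#'   below the optimum, `r_max * (1 - ((T - t_opt)/(t_opt - t_max))^2)`
#'   between optimum and critical maximum, 0 beyond; continuous at the
#'   optimum.
#' @export
#' @examples
#' s <- tpc_shape(r_max = 1, t_opt = 25, t_max = 33)
#' tpc_value(s, c(15, 25, 33))
tpc_value <- function(shape, temp) {
  stopifnot(inherits(shape, "tpc_shape"))
  rise <- shape$r_max * exp(-((temp - shape$t_opt) / (2 * shape$sigma_rise))^2)
  fall <- shape$r_max *
    (1 - ((temp - shape$t_opt) / (shape$t_opt - shape$t_max))^2)
  out <- ifelse(temp <= shape$t_opt, rise, pmax(fall, 0))
  ifelse(temp >= shape$t_max, 0, out)
}

#' Define a synthetic TPC selection-experiment scenario
#'
#' Scenarios encode the classical hypotheses for TPC evolution as
#' transformations of the ancestor curve into the derived (selected) one:
#' \describe{
#'   \item{`"null"`}{no evolution; derived curve identical to the ancestor;}
#'   \item{`"shift"`}{the optimum moves to the selection temperature
#'     (niche shift: fitness gained near the selection temperature, lost
#'     below it);}
#'   \item{`"hotter_is_better"`}{optimum shift plus a height gain — warm
#'     adaptation raises maximal performance;}
#'   \item{`"generalist_specialist"`}{curve widens at the cost of height
#'     (or narrows and gains, for negative `width_change`);}
#'   \item{`"hotter_is_wider"`}{optimum shift and widening with maximal
#'     performance preserved.}
#' }
#'
#' @param scenario One of `"null"`, `"shift"`, `"hotter_is_better"`,
#'   `"generalist_specialist"`, `"hotter_is_wider"`.
#' @param n_species,n_studies_per_species,n_tpcs_per_study Hierarchy sizes.
#'   Defaults (10 x 2 x 2) give a table of the same order as a systematic
#'   extraction (a few hundred assay points across tens of studies).
#' @param assay_temps Candidate assay temperatures as offsets from the
#'   selection temperature, degrees Celsius, strictly increasing; 0 (the
#'   selection temperature itself) is always assayed.
#' @param selection_shift Selection temperature minus the ancestor optimum,
#'   degrees Celsius. Default +3 (warm selection).
#' @param height_gain Fractional change in `r_max` for
#'   `hotter_is_better`. Default 0.1.
#' @param width_change Fractional widening for the width-based scenarios.
#'   Default 0.2.
#' @param noise_sd Replicate-level measurement noise, in fitness units
#'   (curve height is around 1). Default 0.05.
#' @param replicate_count Replicates per line x temperature. Default 5.
#' @param mode_mix Named sampling weights over reproduction modes.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(scenario = c(
                           "null", "shift", "hotter_is_better",
                           "generalist_specialist", "hotter_is_wider"
                         ),
                         n_species = 10, n_studies_per_species = 2,
                         n_tpcs_per_study = 2,
                         assay_temps = seq(-8, 4, by = 2),
                         selection_shift = 3, height_gain = 0.1,
                         width_change = 0.2, noise_sd = 0.05,
                         replicate_count = 5,
                         mode_mix = c(discrete = 0.4, continuous = 0.3, fission = 0.3),
                         seed = 1) {
  scenario <- match.arg(scenario)
  if (is.unsorted(assay_temps, strictly = TRUE)) {
    cli::cli_abort("{.arg assay_temps} must be strictly increasing.")
  }
  if (noise_sd <= 0) cli::cli_abort("{.arg noise_sd} must be positive.")
  if (height_gain <= -1 || width_change <= -1) {
    cli::cli_abort("Fractional changes must exceed -1.")
  }
  structure(
    list(
      scenario = scenario, n_species = n_species,
      n_studies_per_species = n_studies_per_species,
      n_tpcs_per_study = n_tpcs_per_study, assay_temps = assay_temps,
      selection_shift = selection_shift, height_gain = height_gain,
      width_change = width_change, noise_sd = noise_sd,
      replicate_count = replicate_count,
      mode_mix = mode_mix / sum(mode_mix), seed = seed
    ),
    class = "sim_scenario"
  )
}

.derive_shape <- function(anc, scn) {
  d <- unclass(anc)
  sh <- scn$selection_shift
  switch(scn$scenario,
    null = {},
    shift = {
      d$t_opt <- d$t_opt + sh
      d$t_max <- d$t_max + sh
    },
    hotter_is_better = {
      d$t_opt <- d$t_opt + sh
      d$t_max <- d$t_max + sh
      d$r_max <- d$r_max * (1 + scn$height_gain)
    },
    generalist_specialist = {
      d$sigma_rise <- d$sigma_rise * (1 + scn$width_change)
      d$t_max <- d$t_opt + (d$t_max - d$t_opt) * (1 + scn$width_change)
      d$r_max <- d$r_max * (1 - 0.5 * scn$width_change) # generalist trade-off
    },
    hotter_is_wider = {
      d$t_opt <- d$t_opt + sh
      d$t_max <- d$t_max + sh + (d$t_max - d$t_opt) * scn$width_change
      d$sigma_rise <- d$sigma_rise * (1 + scn$width_change)
    }
  )
  do.call(tpc_shape, d[c("r_max", "t_opt", "t_max", "sigma_rise")])
}

#' Simulate a thermal selection experiment table
#'
#' Draws a full synthetic assay table in `tpcmeta-v1` layout. Ancestor
#' curve parameters carry species- and study-level random perturbations;
#' the derived curve applies the scenario transformation plus a small
#' TPC-level performance perturbation (so the three hierarchy levels all
#' contribute true-effect heterogeneity). Each study is randomly assigned
#' a reproduction mode, moderators that co-vary the way they do in the
#' experimental-evolution literature (unicellular systems: binary fission
#' or continuous growth, de novo variation, ancestor comparisons;
#' multicellular sexual systems: discrete generations, standing variation,
#' control comparisons), an assay design (selection temperature only, two
#' temperatures, or a multi-temperature TPC), and a dispersion reporting
#' convention (sd, se or 95% CI half-width). Replicate fitness values are
#' Normal(curve value, `noise_sd`); reported means and dispersions are
#' computed over `replicate_count` replicates.
#'
#' @param scn A [sim_scenario()].
#' @return Assay tibble in `tpcmeta-v1` layout (validated); deterministic
#'   given `scn$seed`.
#' @export
simulate_experiment <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  .with_seed(scn$seed, {
    rows <- list()
    study_n <- 0
    for (sp in seq_len(scn$n_species)) {
      sp_id <- sprintf("sp%02d", sp)
      t_opt_sp <- rnorm(1, 26, 1.5)
      r_max_sp <- exp(rnorm(1, 0, 0.15))
      unicellular <- runif(1) < sum(scn$mode_mix[c("continuous", "fission")])
      var_sp <- if (runif(1) < 0.95) {
        if (unicellular) "de_novo" else "standing"
      } else {
        if (unicellular) "standing" else "de_novo"
      }
      for (st in seq_len(scn$n_studies_per_species)) {
        study_n <- study_n + 1
        st_id <- sprintf("st%03d", study_n)
        mode <- if (unicellular) {
          w <- scn$mode_mix[c("continuous", "fission")]
          sample(names(w), 1, prob = w)
        } else {
          "discrete"
        }
        sexual <- mode == "discrete"
        comparison <- if (runif(1) < 0.9) {
          if (unicellular) "ancestor" else "control"
        } else {
          if (unicellular) "control" else "ancestor"
        }
        generations <- if (runif(1) < 0.12) {
          NA_real_ # some studies do not report duration
        } else if (mode == "discrete") {
          round(exp(rnorm(1, log(20), 0.5)))
        } else {
          round(exp(rnorm(1, log(150), 0.6)))
        }
        generation_time <- if (mode == "continuous") runif(1, 0.5, 3) else NA_real_
        disp_type <- sample(c("sd", "se", "ci95_halfwidth"), 1,
          prob = c(0.6, 0.3, 0.1)
        )
        design <- sample(c("one", "two", "multi"), 1, prob = c(0.17, 0.38, 0.45))
        anc <- tpc_shape(
          r_max = r_max_sp * exp(rnorm(1, 0, 0.1)),
          t_opt = t_opt_sp + rnorm(1, 0, 0.8),
          t_max = t_opt_sp + rnorm(1, 8, 0.8),
          sigma_rise = 5 * exp(rnorm(1, 0, 0.1))
        )
        sel_temp <- anc$t_opt + scn$selection_shift
        ctrl_temp <- anc$t_opt
        derived <- .derive_shape(anc, scn)
        offsets <- switch(design,
          one = 0,
          two = c(0, sample(setdiff(scn$assay_temps, 0), 1)),
          multi = sort(c(0, sample(
            setdiff(scn$assay_temps, 0),
            min(3 + rbinom(1, 2, 0.5), length(setdiff(scn$assay_temps, 0)))
          )))
        )
        for (tp in seq_len(scn$n_tpcs_per_study)) {
          tp_id <- sprintf("%s_tpc%02d", st_id, tp)
          tpc_gain <- exp(rnorm(1, 0, 0.05)) # TPC-level heterogeneity
          for (off in offsets) {
            temp <- sel_temp + off
            m_sel <- tpc_value(derived, temp) * tpc_gain
            m_anc <- tpc_value(anc, temp)
            reps_sel <- rnorm(scn$replicate_count, m_sel, scn$noise_sd)
            reps_anc <- rnorm(scn$replicate_count, m_anc, scn$noise_sd)
            sd_sel <- sd(reps_sel)
            sd_anc <- sd(reps_anc)
            disp <- switch(disp_type,
              sd = c(sd_sel, sd_anc),
              se = c(sd_sel, sd_anc) / sqrt(scn$replicate_count),
              ci95_halfwidth = 1.96 * c(sd_sel, sd_anc) / sqrt(scn$replicate_count)
            )
            rows[[length(rows) + 1]] <- tibble::tibble(
              study_id = st_id, species_id = sp_id, tpc_id = tp_id,
              reproduction_mode = mode, variation_source = var_sp,
              comparison = comparison, sexual = sexual,
              generations = generations, generation_time = generation_time,
              selection_temp = sel_temp, control_temp = ctrl_temp,
              assay_temp = temp,
              f_sel_mean = abs(mean(reps_sel)), # fitness correlates are non-negative
              f_anc_mean = abs(mean(reps_anc)),
              disp_sel = disp[1], disp_anc = disp[2],
              disp_type = disp_type,
              n_replicates = as.integer(scn$replicate_count)
            )
          }
        }
      }
    }
    validate_assay_table(dplyr::bind_rows(rows))
  })
}

#' Simulate effect records directly from the meta-analytic model
#'
#' The generative twin of [fit_meta()]: draws random effects at each
#' hierarchy level, composes true effects from the fixed part and the
#' random effects, then observes each with known heteroscedastic sampling
#' error. Used for parameter-recovery and model-selection checks, where
#' the data-generating truth must be exactly the fitted model.
#'
#' @param mu Fixed intercept (overall mean effect).
#' @param beta Optional named vector of polynomial coefficients over the
#'   relative assay temperature, names among `dt`, `dt2`, `dt3`; when
#'   supplied, each effect receives a `rel_assay_temp` drawn uniformly
#'   over `dt_range`.
#' @param sigma_species,sigma_study,sigma_tpc Random-effect SDs (>= 0);
#'   `sigma_tpc` adds one latent effect per record (each record is its own
#'   TPC).
#' @param n_species,n_studies_per_species,n_effects_per_study Hierarchy
#'   sizes; total records = product.
#' @param se Range of the uniform distribution of sampling standard
#'   errors. Default `c(0.02, 0.2)`.
#' @param dt_range Range of relative assay temperatures when `beta` is
#'   supplied. Default `c(-15, 15)`.
#' @param seed Integer seed.
#' @return Effect tibble (as from [compute_effects()]) with attribute
#'   `truth` (list of the generating parameters) and column `theta_true`.
#' @export
simulate_effects_direct <- function(mu = 0.18, beta = NULL,
                                    sigma_species = 0.22, sigma_study = 0.17,
                                    sigma_tpc = 0,
                                    n_species = 10, n_studies_per_species = 4,
                                    n_effects_per_study = 5,
                                    se = c(0.02, 0.2), dt_range = c(-15, 15),
                                    seed = 1) {
  stopifnot(
    sigma_species >= 0, sigma_study >= 0, sigma_tpc >= 0,
    all(se > 0), length(se) == 2
  )
  .with_seed(seed, {
    n <- n_species * n_studies_per_species * n_effects_per_study
    species <- rep(seq_len(n_species), each = n_studies_per_species * n_effects_per_study)
    study <- rep(seq_len(n_species * n_studies_per_species), each = n_effects_per_study)
    u_sp <- rnorm(n_species, 0, sigma_species)
    u_st <- rnorm(n_species * n_studies_per_species, 0, sigma_study)
    u_tp <- rnorm(n, 0, sigma_tpc)
    dt <- if (is.null(beta)) rep(0, n) else runif(n, dt_range[1], dt_range[2])
    fixed <- mu
    if (!is.null(beta)) {
      pow <- c(dt = 1, dt2 = 2, dt3 = 3)[names(beta)]
      fixed <- mu + drop(outer(dt, pow, `^`) %*% beta)
    }
    theta <- fixed + u_sp[species] + u_st[study] + u_tp
    s <- runif(n, se[1], se[2])
    y <- rnorm(n, theta, s)
    var_sp <- sample(c("de_novo", "standing"), n_species, replace = TRUE)
    out <- tibble::tibble(
      effect_id = sprintf("e%04d", seq_len(n)),
      study_id = sprintf("st%03d", study),
      species_id = sprintf("sp%02d", species),
      tpc_id = sprintf("tpc%04d", seq_len(n)),
      rel_fitness = y,
      rel_fitness_se = s,
      rel_assay_temp = dt,
      sign = "higher",
      variation_source = var_sp[species],
      reproduction_mode = "discrete",
      comparison = "control",
      sexual = TRUE,
      generations = round(exp(rnorm(n, log(30), 0.4))),
      n_assay_temps_in_tpc = 1L,
      theta_true = theta
    )
    attr(out, "truth") <- list(
      mu = mu, beta = beta, sigma_species = sigma_species,
      sigma_study = sigma_study, sigma_tpc = sigma_tpc
    )
    out
  })
}
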
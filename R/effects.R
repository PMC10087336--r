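## Relative-fitness effect sizes per reproduction mode, following Chevin's
## selection-coefficient formulations, plus first-order (delta-method) error
## propagation assuming uncorrelated errors in the two fitness means.

#' Relative fitness for discrete, non-overlapping generations
#'
#' The selection-coefficient style effect size `f_sel / f_anc - 1`: the
#' proportional fitness advantage of the derived (selected) line over its
#' ancestor or control at a common assay temperature.
#'
#' @param f_sel,f_anc Fitness means of the selected and ancestor/control
#'   lines, in the same (study-specific) units. `f_anc` must be non-zero.
#' @return Dimensionless relative fitness; vectorised over inputs.
#' @seealso [relfit_continuous()], [relfit_fission()], [propagate_se()]
#' @export
relfit_discrete <- function(f_sel, f_anc) {
  if (any(f_anc == 0, na.rm = TRUE)) {
    cli::cli_abort("Ancestor fitness of zero: the ratio f_sel / f_anc is undefined.")
  }
  f_sel / f_anc - 1
}

#' Relative fitness for continuously growing populations
#'
#' For organisms measured as growth rates, the rate difference is multiplied
#' by the generation time `G` so that studies on different time scales
#' become comparable: `(f_sel - f_anc) * G`, a per-generation selection
#' differential.
#'
#' @param f_sel,f_anc Growth rates in the same units (e.g. per day).
#' @param G Generation time in the reciprocal time unit; must be positive.
#' @return Dimensionless relative fitness; vectorised.
#' @export
relfit_continuous <- function(f_sel, f_anc, G) {
  if (any(is.na(G)) || any(G <= 0)) {
    cli::cli_abort("Generation time {.arg G} must be present and positive.")
  }
  (f_sel - f_anc) * G
}

#' Relative fitness for binary fission
#'
#' The discrete-generation ratio scaled by `ln 2`, the standard
#' approximation for organisms doubling by binary fission:
#' `(f_sel / f_anc - 1) * ln(2)`.
#'
#' @inheritParams relfit_discrete
#' @return Dimensionless relative fitness; vectorised.
#' @export
relfit_fission <- function(f_sel, f_anc) {
  relfit_discrete(f_sel, f_anc) * log(2)
}

#' Propagate fitness-mean standard errors to the effect-size scale
#'
#' First-order propagation assuming uncorrelated errors in the two fitness
#' means. For the ratio-based modes (discrete, fission) the relative-error
#' form is used, `|f_sel/f_anc| * sqrt((se_sel/f_sel)^2 + (se_anc/f_anc)^2)`,
#' multiplied by `ln 2` for fission; for continuous growth the propagated
#' error is `sqrt(se_sel^2 + se_anc^2) * G`.
#'
#' @inheritParams relfit_discrete
#' @param se_sel,se_anc Standard errors of the two fitness means (>= 0).
#' @param mode One of `"discrete"`, `"continuous"`, `"fission"`; vectorised.
#' @param G Generation time, required where `mode == "continuous"`.
#' @return Non-negative standard error of the relative fitness; vectorised.
#' @export
#' @examples
#' propagate_se(2, 1, 0.2, 0.1, "discrete") # ~0.283
propagate_se <- function(f_sel, f_anc, se_sel, se_anc, mode, G = NA_real_) {
  n <- max(length(f_sel), length(f_anc), length(mode))
  f_sel <- rep_len(f_sel, n)
  f_anc <- rep_len(f_anc, n)
  se_sel <- rep_len(se_sel, n)
  se_anc <- rep_len(se_anc, n)
  mode <- rep_len(mode, n)
  G <- rep_len(G, n)
  if (any(se_sel < 0 | se_anc < 0, na.rm = TRUE)) {
    cli::cli_abort("Standard errors must be non-negative.")
  }
  ratio <- mode %in% c("discrete", "fission")
  if (any(ratio & (f_sel == 0 | f_anc == 0))) {
    cli::cli_abort(
      "Zero fitness mean in a ratio-based mode: relative-error propagation
       is undefined."
    )
  }
  if (any(mode == "continuous" & (is.na(G) | G <= 0))) {
    cli::cli_abort("Continuous mode requires a positive generation time.")
  }
  out <- numeric(n)
  r <- ratio
  out[r] <- abs(f_sel[r] / f_anc[r]) *
    sqrt((se_sel[r] / f_sel[r])^2 + (se_anc[r] / f_anc[r])^2)
  out[mode == "fission"] <- out[mode == "fission"] * log(2)
  cont <- mode == "continuous"
  out[cont] <- sqrt(se_sel[cont]^2 + se_anc[cont]^2) * G[cont]
  out
}

#' Compute relative-fitness effect records from an assay table
#'
#' Turns one assay row (a line-pair measured at one temperature) into one
#' effect record: relative fitness dispatched on the reproduction mode, its
#' propagated standard error, the relative assay temperature
#' (assay minus selection temperature), and the moderators carried along
#' for meta-regression (variation source, reproduction, comparison type,
#' generations, and the sign of the selection temperature relative to the
#' control regime).
#'
#' @param assays Assay tibble with dispersion already normalised to
#'   standard errors (see [normalize_dispersion()]); rows still carrying
#'   `sd` or `ci95_halfwidth` dispersions are an error.
#' @param temp_tol Temperature-equality tolerance in degrees Celsius used
#'   for the `sign` moderator and for classifying at-selection assays;
#'   digitised temperatures can carry rounding, so exact ties are not
#'   required. Default 0.25.
#' @return Tibble of effect records, one per assay row, with columns
#'   `effect_id`, hierarchy IDs, `rel_fitness`, `rel_fitness_se`,
#'   `rel_assay_temp`, `sign`, moderators, `mode_used`, and
#'   `n_assay_temps_in_tpc` (distinct assay temperatures in the parent TPC).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_scenario("shift", n_species = 2, seed = 42))
#' effects <- compute_effects(normalize_dispersion(sim))
#' head(effects)
compute_effects <- function(assays, temp_tol = 0.25) {
  assays <- tibble::as_tibble(assays)
  if (nrow(assays) > 0 && any(assays$disp_type != "se")) {
    cli::cli_abort(
      "Dispersion must be normalised to standard errors first; see
       {.fun normalize_dispersion}."
    )
  }
  neg <- assays$reproduction_mode %in% c("discrete", "fission") &
    (assays$f_sel_mean < 0 | assays$f_anc_mean < 0)
  if (any(neg)) {
    cli::cli_abort(
      "Row {which(neg)[1]}: negative fitness means are not meaningful in
       ratio-based reproduction modes."
    )
  }
  rel <- numeric(nrow(assays))
  for (i in seq_len(nrow(assays))) {
    rel[i] <- switch(assays$reproduction_mode[i],
      discrete = relfit_discrete(assays$f_sel_mean[i], assays$f_anc_mean[i]),
      continuous = relfit_continuous(
        assays$f_sel_mean[i], assays$f_anc_mean[i], assays$generation_time[i]
      ),
      fission = relfit_fission(assays$f_sel_mean[i], assays$f_anc_mean[i])
    )
  }
  se <- if (nrow(assays) == 0) {
    numeric(0)
  } else {
    propagate_se(
      assays$f_sel_mean, assays$f_anc_mean,
      assays$disp_sel, assays$disp_anc,
      assays$reproduction_mode, assays$generation_time
    )
  }
  dtemp <- assays$selection_temp - assays$control_temp
  out <- tibble::tibble(
    effect_id = sprintf("e%04d", seq_len(nrow(assays))),
    study_id = assays$study_id,
    species_id = assays$species_id,
    tpc_id = assays$tpc_id,
    rel_fitness = rel,
    rel_fitness_se = se,
    rel_assay_temp = assays$assay_temp - assays$selection_temp,
    sign = dplyr::case_when(
      abs(dtemp) <= temp_tol ~ "equal",
      dtemp > 0 ~ "higher",
      TRUE ~ "lower"
    ),
    variation_source = assays$variation_source,
    reproduction_mode = assays$reproduction_mode,
    comparison = assays$comparison,
    sexual = assays$sexual,
    generations = assays$generations
  )
  dplyr::mutate(
    dplyr::group_by(out, .data$tpc_id),
    n_assay_temps_in_tpc = dplyr::n_distinct(.data$rel_assay_temp),
    .after = "generations"
  ) |> dplyr::ungroup()
}
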
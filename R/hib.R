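#' Maximal-fitness effects for the Hotter-is-better comparison
#'
#' For TPCs assayed densely enough (more than three assay temperatures for
#' both lines), compares the curves at their respective maxima: relative
#' fitness of `max_T f_sel(T)` versus `max_T f_anc(T)`, computed with the
#' TPC's reproduction mode, with the standard error propagated from the
#' dispersions at the two argmax temperatures. Under Hotter-is-better,
#' warm-evolved lines should achieve a higher maximum, making this effect
#' positive. Ties in the maximum are resolved toward the lower temperature.
#'
#' @param assays Assay tibble with dispersion normalised to standard
#'   errors ([normalize_dispersion()]).
#' @param min_temps Minimum number of distinct assay temperatures per TPC;
#'   TPCs below it are dropped. Default 4.
#' @param temp_tol Tolerance passed to the `sign` moderator computation.
#' @return Effect tibble with one row per qualifying TPC. `rel_assay_temp`
#'   records the temperature gap between the two maxima (selected argmax
#'   minus ancestor argmax); `n_assay_temps_in_tpc` the TPC's assay count.
#' @export
hotter_is_better_effects <- function(assays, min_temps = 4, temp_tol = 0.25) {
  assays <- tibble::as_tibble(assays)
  if (nrow(assays) > 0 && any(assays$disp_type != "se")) {
    cli::cli_abort("Normalise dispersion to standard errors first.")
  }
  per_tpc <- dplyr::group_split(dplyr::group_by(assays, .data$tpc_id))
  rows <- purrr::map(per_tpc, function(g) {
    if (dplyr::n_distinct(g$assay_temp) < min_temps) {
      return(NULL)
    }
    g <- dplyr::arrange(g, .data$assay_temp) # ties in max -> lowest temperature
    i_sel <- which.max(g$f_sel_mean)
    i_anc <- which.max(g$f_anc_mean)
    mode <- g$reproduction_mode[1]
    G <- g$generation_time[1]
    rel <- switch(mode,
      discrete = relfit_discrete(g$f_sel_mean[i_sel], g$f_anc_mean[i_anc]),
      continuous = relfit_continuous(g$f_sel_mean[i_sel], g$f_anc_mean[i_anc], G),
      fission = relfit_fission(g$f_sel_mean[i_sel], g$f_anc_mean[i_anc])
    )
    se <- propagate_se(
      g$f_sel_mean[i_sel], g$f_anc_mean[i_anc],
      g$disp_sel[i_sel], g$disp_anc[i_anc], mode, G
    )
    dtemp <- g$selection_temp[1] - g$control_temp[1]
    tibble::tibble(
      study_id = g$study_id[1],
      species_id = g$species_id[1],
      tpc_id = g$tpc_id[1],
      rel_fitness = rel,
      rel_fitness_se = se,
      rel_assay_temp = g$assay_temp[i_sel] - g$assay_temp[i_anc],
      sign = dplyr::case_when(
        abs(dtemp) <= temp_tol ~ "equal",
        dtemp > 0 ~ "higher",
        TRUE ~ "lower"
      ),
      variation_source = g$variation_source[1],
      reproduction_mode = mode,
      comparison = g$comparison[1],
      sexual = g$sexual[1],
      generations = g$generations[1],
      n_assay_temps_in_tpc = dplyr::n_distinct(g$assay_temp)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      study_id = character(), species_id = character(), tpc_id = character(),
      rel_fitness = numeric(), rel_fitness_se = numeric(),
      rel_assay_temp = numeric(), sign = character(),
      variation_source = character(), reproduction_mode = character(),
      comparison = character(), sexual = logical(), generations = numeric(),
      n_assay_temps_in_tpc = integer()
    )
    out$effect_id <- character()
  }
  if (nrow(out) > 0) {
    out <- dplyr::mutate(out,
      effect_id = sprintf("hib%03d", dplyr::row_number()), .before = 1
    )
  }
  out
}
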
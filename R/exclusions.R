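#' Apply the meta-analysis exclusion rules to an effect table
#'
#' Three cleaning rules precede model fitting: implausibly large relative
#' fitness values (outliers above `outlier_threshold`, default 20, against
#' an overall mean near 0.1) are removed; effects whose propagated standard
#' error is exactly zero cannot enter a measurement-error likelihood and
#' are removed; effects with no error measurement at all (missing standard
#' error) are removed. Each removal is logged with its reason.
#'
#' @param effects Effect tibble from [compute_effects()].
#' @param outlier_threshold Relative-fitness value above which an effect is
#'   treated as an extraction outlier. Default 20.
#' @return A list with components `kept` (the cleaned effect tibble) and
#'   `log` (tibble of `effect_id`, `rel_fitness`, `reason` for every removed
#'   row; zero rows when nothing was excluded).
#' @export
#' @examples
#' eff <- tibble::tibble(
#'   effect_id = paste0("e", 1:3), rel_fitness = c(0.2, 25, 0.1),
#'   rel_fitness_se = c(0.1, 0.1, 0)
#' )
#' apply_exclusions(eff)$log
apply_exclusions <- function(effects, outlier_threshold = 20) {
  effects <- tibble::as_tibble(effects)
  reason <- dplyr::case_when(
    !is.na(effects$rel_fitness) &
      effects$rel_fitness > outlier_threshold ~ "outlier_rel_fitness",
    is.na(effects$rel_fitness_se) ~ "missing_se",
    effects$rel_fitness_se == 0 ~ "zero_se",
    TRUE ~ NA_character_
  )
  drop <- !is.na(reason)
  log <- tibble::tibble(
    effect_id = effects$effect_id[drop],
    rel_fitness = effects$rel_fitness[drop],
    reason = reason[drop]
  )
  list(kept = effects[!drop, , drop = FALSE], log = log)
}

#' Split cleaned effects into the four analysis subsets
#'
#' The analyses operate on different slices of the effect table:
#' \describe{
#'   \item{`at_selection`}{effects assayed at the selection temperature
#'     (relative assay temperature zero within `temp_tol`), used for the
#'     overall direct-response analysis;}
#'   \item{`two_point`}{effects belonging to TPCs assayed at exactly two
#'     temperatures (linear reaction norms);}
#'   \item{`multipoint`}{effects in TPCs with three or more assay
#'     temperatures (TPC-shape analysis);}
#'   \item{`hib_candidates`}{effects in TPCs with more than three assay
#'     temperatures, the pool for the Hotter-is-better max-vs-max
#'     comparison.}
#' }
#' Two-point and multipoint partition the TPCs with at least two assay
#' temperatures; `at_selection` cuts across that partition.
#'
#' @param effects Cleaned effect tibble (after [apply_exclusions()]).
#' @param temp_tol Temperature tolerance in degrees Celsius for treating a
#'   relative assay temperature as zero. Default 0.25.
#' @return Named list of four effect tibbles.
#' @export
build_subsets <- function(effects, temp_tol = 0.25) {
  effects <- tibble::as_tibble(effects)
  counts <- dplyr::summarise(
    dplyr::group_by(effects, .data$tpc_id),
    n_temps = dplyr::n_distinct(.data$rel_assay_temp),
    .groups = "drop"
  )
  n_of <- setNames(counts$n_temps, counts$tpc_id)[effects$tpc_id]
  list(
    at_selection = effects[abs(effects$rel_assay_temp) <= temp_tol, , drop = FALSE],
    two_point = effects[n_of == 2, , drop = FALSE],
    multipoint = effects[n_of >= 3, , drop = FALSE],
    hib_candidates = effects[n_of > 3, , drop = FALSE]
  )
}
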
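#' Normalise dispersion measures to standard errors
#'
#' Extracted studies report uncertainty heterogeneously: as a standard
#' error, a standard deviation over replicates, or a 95% confidence-interval
#' half-width. Downstream weighting needs a standard error, so standard
#' deviations are divided by the square root of the replicate count and
#' CI half-widths by 1.96. Rows already carrying a standard error pass
#' through unchanged, which makes the operation idempotent.
#'
#' @param assays Assay tibble (`tpcmeta-v1` columns).
#' @return The same tibble with `disp_sel`/`disp_anc` converted to standard
#'   errors and `disp_type` set to `"se"` on every row.
#' @export
#' @examples
#' df <- simulate_experiment(sim_scenario("null", n_species = 1, seed = 1))
#' normalize_dispersion(df)$disp_type[1]
normalize_dispersion <- function(assays) {
  assays <- tibble::as_tibble(assays)
  if (nrow(assays) == 0) {
    return(assays)
  }
  needs_n <- assays$disp_type == "sd" &
    (is.na(assays$n_replicates) | assays$n_replicates < 1)
  if (any(needs_n)) {
    cli::cli_abort(
      "Row {which(needs_n)[1]}: cannot convert a standard deviation without
       {.field n_replicates}."
    )
  }
  factor <- dplyr::case_when(
    assays$disp_type == "sd" ~ 1 / sqrt(assays$n_replicates),
    assays$disp_type == "ci95_halfwidth" ~ 1 / 1.96,
    assays$disp_type == "se" ~ 1,
    TRUE ~ NA_real_
  )
  if (anyNA(factor)) {
    cli::cli_abort(
      "Row {which(is.na(factor))[1]}: unknown {.field disp_type}."
    )
  }
  dplyr::mutate(assays,
    disp_sel = .data$disp_sel * factor,
    disp_anc = .data$disp_anc * factor,
    disp_type = "se"
  )
}
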
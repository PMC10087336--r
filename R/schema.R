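## Flat assay-table schema ("tpcmeta-v1"): one row per study x TPC x assay
## temperature, carrying the fitness means and dispersions of the selected
## and ancestor/control lines plus the moderators used downstream.

.tpcmeta_v1_cols <- c(
  study_id = "character",
  species_id = "character",
  tpc_id = "character",
  reproduction_mode = "character",
  variation_source = "character",
  comparison = "character",
  sexual = "logical",
  generations = "double",
  generation_time = "double",
  selection_temp = "double",
  control_temp = "double",
  assay_temp = "double",
  f_sel_mean = "double",
  f_anc_mean = "double",
  disp_sel = "double",
  disp_anc = "double",
  disp_type = "character",
  n_replicates = "integer"
)

.enum_levels <- list(
  reproduction_mode = c("discrete", "continuous", "fission"),
  variation_source = c("de_novo", "standing"),
  comparison = c("ancestor", "control"),
  disp_type = c("se", "sd", "ci95_halfwidth")
)

#' Column names of the tpcmeta-v1 assay schema
#'
#' @return Character vector of the column names, in canonical order.
#' @export
assay_schema <- function() names(.tpcmeta_v1_cols)

#' Read a flat assay table
#'
#' Reads a CSV of extracted thermal-selection assays (one row per study x
#' TPC x assay temperature) and validates it against the `tpcmeta-v1`
#' schema: column set, enum levels, and per-row invariants (non-negative
#' dispersions, generation time present for continuous reproducers,
#' replicate counts present when dispersion is reported as a standard
#' deviation, non-zero ancestor fitness for ratio-based modes).
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param dialect Schema version tag; only `"tpcmeta-v1"` is defined.
#' @return A tibble of assay records with one row per parsed input row.
#'   Missing optional fields (`generations`, `generation_time`,
#'   `n_replicates`) are `NA`, never zero.
#' @export
read_assay_table <- function(path, dialect = "tpcmeta-v1") {
  if (!identical(dialect, "tpcmeta-v1")) {
    cli::cli_abort("Unknown schema dialect {.val {dialect}}.")
  }
  if (!file.exists(path)) {
    cli::cli_abort("File {.path {path}} does not exist.")
  }
  raw <- readr::read_csv(
    path,
    col_types = do.call(
      readr::cols,
      lapply(.tpcmeta_v1_cols, function(t) {
        switch(t,
          character = readr::col_character(),
          logical = readr::col_logical(),
          double = readr::col_double(),
          integer = readr::col_integer()
        )
      })
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(assay_schema(), names(raw))
  if (length(missing_cols) > 0) {
    cli::cli_abort(c(
      "Header does not match the tpcmeta-v1 schema.",
      x = "Missing column{?s}: {.field {missing_cols}}."
    ))
  }
  validate_assay_table(raw[assay_schema()])
}

#' Validate an in-memory assay table
#'
#' Applies the same checks as [read_assay_table()] to a data frame built in
#' code (for example by [simulate_experiment()]).
#'
#' @param assays Data frame with the `tpcmeta-v1` columns.
#' @return The validated tibble, invisibly identical in content.
#' @export
validate_assay_table <- function(assays) {
  assays <- tibble::as_tibble(assays)
  missing_cols <- setdiff(assay_schema(), names(assays))
  if (length(missing_cols) > 0) {
    cli::cli_abort("Missing column{?s}: {.field {missing_cols}}.")
  }
  if (nrow(assays) == 0) {
    return(assays)
  }
  for (col in names(.enum_levels)) {
    bad <- !is.na(assays[[col]]) & !(assays[[col]] %in% .enum_levels[[col]])
    if (any(bad)) {
      row <- which(bad)[1]
      cli::cli_abort(
        "Row {row}: unknown {.field {col}} value {.val {assays[[col]][row]}}."
      )
    }
    if (anyNA(assays[[col]])) {
      row <- which(is.na(assays[[col]]))[1]
      cli::cli_abort("Row {row}: required field {.field {col}} is missing.")
    }
  }
  .check_rows(assays)
  assays
}

.check_rows <- function(assays) {
  fail <- function(rows, field, what) {
    row <- rows[1]
    cli::cli_abort("Row {row}: {what} ({.field {field}}).")
  }
  with(assays, {
    bad <- which(!is.na(disp_sel) & disp_sel < 0 | !is.na(disp_anc) & disp_anc < 0)
    if (length(bad)) fail(bad, "disp_sel/disp_anc", "dispersion must be non-negative")
    bad <- which(reproduction_mode == "continuous" &
      (is.na(generation_time) | generation_time <= 0))
    if (length(bad)) {
      fail(
        bad, "generation_time",
        "continuous reproduction requires a positive generation time"
      )
    }
    bad <- which(disp_type == "sd" & (is.na(n_replicates) | n_replicates < 1))
    if (length(bad)) {
      fail(
        bad, "n_replicates",
        "dispersion reported as a standard deviation requires the replicate count"
      )
    }
    bad <- which(reproduction_mode %in% c("discrete", "fission") & f_anc_mean == 0)
    if (length(bad)) {
      fail(
        bad, "f_anc_mean",
        "ancestor fitness of zero makes the fitness ratio undefined"
      )
    }
    bad <- which(!is.na(generations) & generations < 0)
    if (length(bad)) fail(bad, "generations", "generations must be non-negative")
  })
  invisible(assays)
}

#' Write an assay or effect table as tpcmeta-v1 CSV
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tpcmeta_csv <- function(x, path) {
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(x)
}
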
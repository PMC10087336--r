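## Design construction: response, sampling SEs, fixed-effect matrix and
## random-effect index maps for the measurement-error model.

.fixed_matrix <- function(df, spec, x_info = NULL) {
  n <- nrow(df)
  cols <- list("(Intercept)" = rep(1, n))
  if (spec$poly_degree > 0) {
    for (d in seq_len(spec$poly_degree)) {
      cols[[paste0("dt", if (d > 1) d else "")]] <- df$rel_assay_temp^d
    }
  }
  if (spec$abs_dt) {
    cols[["abs_dt"]] <- abs(df$rel_assay_temp)
  }
  if ("var" %in% spec$fixed || "var:dt" %in% spec$fixed) {
    var_ind <- as.numeric(df$variation_source == "de_novo")
    if ("var" %in% spec$fixed) cols[["var_de_novo"]] <- var_ind
    if ("var:dt" %in% spec$fixed) {
      for (d in seq_len(spec$poly_degree)) {
        cols[[paste0("var_de_novo:dt", if (d > 1) d else "")]] <-
          var_ind * df$rel_assay_temp^d
      }
    }
  }
  if ("gen" %in% spec$fixed) {
    if (anyNA(df$generations)) {
      cli::cli_abort(c(
        "Moderator {.val gen} requested but some effects lack generation counts.",
        i = "Fit the model on the reduced data set (rows with generations recorded)."
      ))
    }
    if (is.null(x_info)) {
      ctr <- mean(df$generations)
      scl <- sd(df$generations)
      if (!is.finite(scl) || scl == 0) scl <- 1
    } else {
      ctr <- x_info$gen_center
      scl <- x_info$gen_scale
    }
    cols[["gen_z"]] <- (df$generations - ctr) / scl
    gen_info <- list(gen_center = ctr, gen_scale = scl)
  } else {
    gen_info <- list(gen_center = NA_real_, gen_scale = NA_real_)
  }
  if ("sign" %in% spec$fixed) {
    lv <- if (is.null(x_info)) {
      intersect(c("higher", "lower"), unique(df$sign))
    } else {
      x_info$sign_levels
    }
    for (s in lv) cols[[paste0("sign_", s)]] <- as.numeric(df$sign == s)
    gen_info$sign_levels <- lv
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, x_info = gen_info)
}

#' Build the design bundle for a measurement-error meta-analysis
#'
#' Assembles, from cleaned effect records and a model specification, the
#' response (relative fitness), the per-effect sampling standard errors
#' (the measurement-error weights), the indicator-coded fixed-effect
#' matrix and integer index maps for each random-effect level.
#'
#' @param effects Cleaned effect tibble; every `rel_fitness_se` must be
#'   strictly positive.
#' @param spec A [meta_model_spec()].
#' @return An object of class `tpc_design`: list with `y`, `se`, `X`,
#'   `levels` (named list of integer index vectors), `level_labels`,
#'   `effects`, `spec` and `x_info` (centring constants reused for
#'   prediction grids).
#' @export
build_design <- function(effects, spec) {
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) == 0) {
    cli::cli_abort("No effects to model.")
  }
  if (any(is.na(effects$rel_fitness_se)) || any(effects$rel_fitness_se <= 0)) {
    cli::cli_abort(
      "All effects must carry a positive standard error; run
       {.fun apply_exclusions} first."
    )
  }
  fm <- .fixed_matrix(effects, spec)
  id_col <- c(species = "species_id", study = "study_id", tpc = "tpc_id")
  levels <- list()
  level_labels <- list()
  for (lev in spec$random) {
    f <- factor(effects[[id_col[[lev]]]])
    levels[[lev]] <- as.integer(f)
    level_labels[[lev]] <- levels(f)
  }
  structure(
    list(
      y = effects$rel_fitness,
      se = effects$rel_fitness_se,
      X = fm$X,
      levels = levels,
      level_labels = level_labels,
      effects = effects,
      spec = spec,
      x_info = fm$x_info
    ),
    class = "tpc_design"
  )
}
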
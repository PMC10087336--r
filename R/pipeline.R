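## End-to-end orchestration of the four analyses: subset -> candidate
## model set -> WAIC ranking -> best-model summary -> heterogeneity ->
## moderator screening and bias assessment.

.default_model_args <- function(analysis) {
  switch(analysis,
    at_selection = list(
      random = c("species", "study"),
      models = list(
        intercept = list(),
        var = list(fixed = "var")
      )
    ),
    two_point = list(
      random = c("species", "study", "tpc"),
      models = list(
        intercept = list(),
        abs_dt = list(abs_dt = TRUE),
        `abs_dt+var` = list(abs_dt = TRUE, fixed = "var")
      )
    ),
    multipoint = list(
      random = c("species", "study", "tpc"),
      models = list(
        intercept = list(),
        linear = list(poly_degree = 1),
        quadratic = list(poly_degree = 2),
        cubic = list(poly_degree = 3),
        `cubic+var` = list(poly_degree = 3, fixed = "var"),
        `cubic+var+sign` = list(poly_degree = 3, fixed = c("var", "sign"))
      )
    ),
    hotter_is_better = list(
      random = c("species", "study"),
      models = list(
        intercept = list(),
        var = list(fixed = "var")
      )
    )
  )
}

#' Run one of the four meta-analyses end to end
#'
#' Orchestrates the full pipeline on an assay table: dispersion
#' normalisation, effect-size computation, exclusion rules, subsetting,
#' fitting the analysis's candidate model set, WAIC ranking, best-model
#' summaries, heterogeneity decomposition, moderator-collinearity
#' screening and the publication-bias test. When `include_gen = TRUE`
#' every candidate model is additionally refitted with the
#' generation-count moderator on the reduced data set (rows where
#' generations were reported), since not all studies report experiment
#' duration; that ranking is returned separately because WAIC is only
#' comparable within one data subset.
#'
#' @param assays Assay tibble in `tpcmeta-v1` layout, or a path to such a
#'   CSV.
#' @param analysis One of `"at_selection"` (direct response at the
#'   selection temperature), `"two_point"` (linear reaction norms,
#'   absolute relative assay temperature), `"multipoint"` (TPC shape,
#'   signed polynomial) or `"hotter_is_better"` (max-vs-max comparison).
#' @param models Optional named list of argument lists for
#'   [meta_model_spec()] overriding the analysis's default candidate set;
#'   random levels are filled in per analysis (species + study, plus TPC
#'   identity for the two-point and multipoint analyses).
#' @param include_gen Also fit `+gen` variants on the reduced data set.
#' @param outlier_threshold Passed to [apply_exclusions()].
#' @param iterations,warmup,chains MCMC settings applied to every
#'   candidate model. The defaults (6000/1000/2) are sized for
#'   interactive use; headline runs use 30000 iterations with 1000
#'   warmup.
#' @param seed Integer seed governing all fits and the bias test.
#' @param outdir Optional directory; when given, effect tables, the
#'   exclusion log, ranking, best-model summary, heterogeneity table,
#'   moderator correlations, funnel data (CSV), the ranking (JSON) and a
#'   run log are written there.
#' @return Object of class `tpc_analysis`: list with `analysis`,
#'   `effects` (cleaned), `exclusions`, `subset`, `fits`, `ranking`,
#'   `best` (the top-ranked fit), `heterogeneity`, `moderators`, `bias`,
#'   `gen_ranking`/`gen_fits` (when requested), and `config`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_experiment(sim_scenario("shift", seed = 3))
#' res <- run_analysis(sim, "at_selection",
#'   iterations = 2000, warmup = 500, seed = 3
#' )
#' res$ranking
#' }
run_analysis <- function(assays, analysis = c(
                           "at_selection", "two_point",
                           "multipoint", "hotter_is_better"
                         ),
                         models = NULL, include_gen = FALSE,
                         outlier_threshold = 20,
                         iterations = 6000, warmup = 1000, chains = 2,
                         seed = 1, outdir = NULL) {
  analysis <- match.arg(analysis)
  if (is.character(assays) && length(assays) == 1) {
    assays <- read_assay_table(assays)
  }
  assays <- normalize_dispersion(assays)
  defaults <- .default_model_args(analysis)
  if (analysis == "hotter_is_better") {
    raw_effects <- hotter_is_better_effects(assays)
  } else {
    raw_effects <- compute_effects(assays)
  }
  cleaned <- apply_exclusions(raw_effects, outlier_threshold)
  subset <- if (analysis == "hotter_is_better") {
    cleaned$kept
  } else {
    build_subsets(cleaned$kept)[[analysis]]
  }
  if (nrow(subset) == 0) {
    cli::cli_abort("The {.val {analysis}} subset is empty after cleaning.")
  }
  model_args <- models %||% defaults$models
  specs <- lapply(names(model_args), function(nm) {
    do.call(meta_model_spec, c(
      model_args[[nm]],
      list(
        random = defaults$random, iterations = iterations,
        warmup = warmup, chains = chains, label = nm
      )
    ))
  })
  names(specs) <- names(model_args)
  fits <- lapply(specs, function(sp) fit_meta(subset, spec = sp, seed = seed))
  ranking <- rank_models(fits)
  best <- fits[[ranking$model[1]]]
  het <- i2_posterior(best)
  mods <- screen_moderators(cleaned$kept)
  bias <- bias_test(subset,
    random = defaults$random, seed = seed,
    iterations = min(iterations, 4000), warmup = warmup, chains = chains
  )
  gen_fits <- NULL
  gen_ranking <- NULL
  if (include_gen) {
    reduced <- subset[!is.na(subset$generations), , drop = FALSE]
    if (nrow(reduced) > 0) {
      gen_specs <- lapply(names(model_args), function(nm) {
        args <- model_args[[nm]]
        args$fixed <- union(args$fixed %||% character(), "gen")
        do.call(meta_model_spec, c(args, list(
          random = defaults$random, iterations = iterations,
          warmup = warmup, chains = chains, label = paste0(nm, "+gen")
        )))
      })
      names(gen_specs) <- paste0(names(model_args), "+gen")
      gen_fits <- lapply(gen_specs, function(sp) {
        fit_meta(reduced, spec = sp, seed = seed)
      })
      gen_ranking <- rank_models(gen_fits)
    }
  }
  out <- structure(
    list(
      analysis = analysis,
      effects = cleaned$kept,
      exclusions = cleaned$log,
      subset = subset,
      fits = fits,
      ranking = ranking,
      best = best,
      heterogeneity = het,
      moderators = mods,
      bias = bias,
      gen_fits = gen_fits,
      gen_ranking = gen_ranking,
      config = list(
        analysis = analysis, seed = seed, iterations = iterations,
        warmup = warmup, chains = chains,
        outlier_threshold = outlier_threshold,
        models = names(model_args), random = defaults$random
      )
    ),
    class = "tpc_analysis"
  )
  if (!is.null(outdir)) {
    .write_analysis(out, outdir)
  }
  out
}

.write_analysis <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tpcmeta_csv(res$effects, p("effects.csv"))
  write_tpcmeta_csv(res$exclusions, p("exclusion_log.csv"))
  write_tpcmeta_csv(res$subset, p("subset.csv"))
  write_tpcmeta_csv(tidy(res$best), p("best_model_summary.csv"))
  write_tpcmeta_csv(res$heterogeneity$summary, p("heterogeneity.csv"))
  write_tpcmeta_csv(res$moderators$correlations, p("moderator_correlations.csv"))
  write_tpcmeta_csv(res$bias$funnel, p("funnel.csv"))
  jsonlite::write_json(res$ranking, p("ranking.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(
      slope = res$bias$slope, verdict = res$bias$verdict
    ),
    p("bias.json"),
    digits = NA, auto_unbox = TRUE
  )
  log <- c(
    paste("analysis:", res$config$analysis),
    paste("seed:", res$config$seed),
    paste(
      "mcmc:", res$config$chains, "chains x", res$config$iterations,
      "iterations,", res$config$warmup, "warmup"
    ),
    paste("models:", paste(res$config$models, collapse = ", ")),
    paste("random levels:", paste(res$config$random, collapse = ", ")),
    paste("effects (cleaned):", nrow(res$effects)),
    paste("subset size:", nrow(res$subset)),
    paste("excluded:", nrow(res$exclusions)),
    paste("best model:", res$ranking$model[1]),
    paste("converged:", res$best$converged)
  )
  writeLines(log, p("run_log.txt"))
  invisible(res)
}

#' @export
print.tpc_analysis <- function(x, ...) {
  cat(
    "<tpc_analysis>", x$analysis, "|", nrow(x$subset), "effects |",
    length(x$fits), "models\n"
  )
  cat("Model ranking (WAIC):\n")
  print(x$ranking)
  cat("\nBest model:", x$ranking$model[1], "\n")
  print(tidy(x$best))
  invisible(x)
}
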
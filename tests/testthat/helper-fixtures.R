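# Shared fixtures: a minimal well-formed assay table and small model specs
# sized for unit tests (headline analyses use far longer chains).

toy_assays <- function(n = 5) {
  tibble::tibble(
    study_id = paste0("st", rep(1:2, length.out = n)),
    species_id = paste0("sp", rep(1, n)),
    tpc_id = paste0("tpc", seq_len(n)),
    reproduction_mode = rep(c("discrete", "continuous", "fission"), length.out = n),
    variation_source = rep(c("de_novo", "standing"), length.out = n),
    comparison = rep(c("ancestor", "control"), length.out = n),
    sexual = rep(c(TRUE, FALSE), length.out = n),
    generations = seq_len(n) * 10,
    generation_time = ifelse(
      rep(c("discrete", "continuous", "fission"), length.out = n) == "continuous",
      2, NA_real_
    ),
    selection_temp = 28,
    control_temp = 25,
    assay_temp = 28,
    f_sel_mean = 1.2,
    f_anc_mean = 1.0,
    disp_sel = 0.1,
    disp_anc = 0.1,
    disp_type = "se",
    n_replicates = 5L
  )
}

test_spec <- function(...) {
  meta_model_spec(iterations = 2000, warmup = 500, chains = 2, ...)
}

# effect table with explicit values for design/model tests
toy_effects <- function(y, se, study = NULL, species = NULL) {
  n <- length(y)
  tibble::tibble(
    effect_id = sprintf("e%03d", seq_len(n)),
    study_id = study %||% sprintf("st%02d", seq_len(n)),
    species_id = species %||% sprintf("sp%02d", seq_len(n)),
    tpc_id = sprintf("tpc%03d", seq_len(n)),
    rel_fitness = y,
    rel_fitness_se = se,
    rel_assay_temp = 0,
    sign = "higher",
    variation_source = "standing",
    reproduction_mode = "discrete",
    comparison = "control",
    sexual = TRUE,
    generations = 10,
    n_assay_temps_in_tpc = 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
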
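#' Publication-bias assessment: funnel data and Egger-style multilevel test
#'
#' Small or imprecise studies are more likely to be published when their
#' effects are large; in a funnel plot of effect against standard error
#' this shows up as asymmetry, and in an Egger-style meta-regression as a
#' non-zero association between effect size and standard error. This test
#' refits the multilevel measurement-error model with the effect's own
#' standard error added as a fixed moderator (centred), keeping the same
#' random-effect structure as the main analysis, and reports the slope's
#' posterior median and 95% compatibility interval. The verdict is
#' "no consistent bias" exactly when the interval covers zero.
#'
#' With no spread in the standard errors the slope is unidentifiable; the
#' verdict is then "unidentifiable" and no model is fitted.
#'
#' @param effects Cleaned effect tibble (positive `rel_fitness_se`).
#' @param random Random-effect levels, as in [meta_model_spec()].
#' @param iterations,warmup,chains MCMC settings (defaults sized for a
#'   screening diagnostic rather than headline inference).
#' @param seed Integer seed.
#' @return Object of class `tpc_funnel`: list with `funnel` (tibble
#'   `effect`, `se` for plotting), `slope` (tibble `estimate`, `conf.low`,
#'   `conf.high`), `verdict`, and the underlying `fit` (`NULL` when
#'   unidentifiable). Plot with [autoplot()].
#' @export
bias_test <- function(effects, random = c("species", "study"),
                      iterations = 4000, warmup = 1000, chains = 2, seed = 1) {
  effects <- tibble::as_tibble(effects)
  funnel <- tibble::tibble(
    effect = effects$rel_fitness,
    se = effects$rel_fitness_se
  )
  if (nrow(effects) < 3) {
    cli::cli_abort("At least three effects are required for the bias test.")
  }
  if (sd(effects$rel_fitness_se) == 0) {
    cli::cli_warn("All standard errors are equal: the bias slope is unidentifiable.")
    return(structure(
      list(
        funnel = funnel,
        slope = tibble::tibble(
          estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_
        ),
        verdict = "unidentifiable", fit = NULL
      ),
      class = "tpc_funnel"
    ))
  }
  spec <- meta_model_spec(
    random = random, iterations = iterations, warmup = warmup,
    chains = chains, label = "egger"
  )
  design <- build_design(effects, spec)
  design$X <- cbind(design$X, se_centred = design$se - mean(design$se))
  fit <- fit_meta(design, seed = seed)
  sl <- fit$beta[, "se_centred"]
  qs <- quantile(sl, c(0.5, 0.025, 0.975), names = FALSE)
  slope <- tibble::tibble(estimate = qs[1], conf.low = qs[2], conf.high = qs[3])
  verdict <- if (qs[2] <= 0 && qs[3] >= 0) "no consistent bias" else "possible bias"
  structure(
    list(funnel = funnel, slope = slope, verdict = verdict, fit = fit),
    class = "tpc_funnel"
  )
}

#' @export
print.tpc_funnel <- function(x, ...) {
  cat("<tpc_funnel>", nrow(x$funnel), "effects | verdict:", x$verdict, "\n")
  if (!is.na(x$slope$estimate)) {
    cat(sprintf(
      "  SE slope: %.3f [%.3f, %.3f]\n",
      x$slope$estimate, x$slope$conf.low, x$slope$conf.high
    ))
  }
  invisible(x)
}
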
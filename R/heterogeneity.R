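## Multilevel heterogeneity: typical sampling variance and posterior I².

#' Typical sampling variance of a set of effects
#'
#' The Higgins-Thompson summary of within-effect sampling variance used in
#' I² computations: with inverse-variance weights `w_i = 1 / se_i^2`,
#' `s2 = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))`. When all standard
#' errors are equal to `s` this collapses to `s^2`.
#'
#' @param se Vector of at least two positive standard errors.
#' @return The typical sampling variance (positive scalar).
#' @export
#' @examples
#' typical_sampling_variance(c(1, 1, 2)) # 1.5
typical_sampling_variance <- function(se) {
  se <- se[!is.na(se)]
  if (length(se) < 2) {
    cli::cli_abort("At least two standard errors are required.")
  }
  if (any(se <= 0)) {
    cli::cli_abort("All standard errors must be positive.")
  }
  w <- 1 / se^2
  (length(se) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Posterior multilevel I² decomposition
#'
#' Computes, per posterior draw, the share of total variance attributable
#' to true-effect heterogeneity at each random-effect level (once fixed
#' effects are accounted for):
#' `I2_level = sigma2_level / (sum(sigma2) + s2_typical) * 100`, with the
#' total `I2 = sum(sigma2) / (sum(sigma2) + s2_typical) * 100`. Level
#' contributions add up to the total exactly, draw by draw. Summaries
#' report both posterior means and medians with 95% compatibility
#' intervals (conventions differ between effect and heterogeneity
#' reporting, so both are emitted and labelled).
#'
#' @param fit A [fit_meta()] result (its sampling SEs give `s2_typical`),
#'   or a draws x levels matrix of level SDs.
#' @param s2_typical Typical sampling variance; computed from the fit's
#'   design via [typical_sampling_variance()] when omitted.
#' @return An object of class `tpc_heterogeneity`: list with `summary`
#'   (tibble: one row per level plus `total`, columns `sigma2_median`,
#'   `sigma2_lo`, `sigma2_hi`, `I2_mean`, `I2_median`, `I2_lo`, `I2_hi`),
#'   `s2_typical`, and the per-draw `I2_draws` matrix.
#' @export
i2_posterior <- function(fit, s2_typical = NULL) {
  if (inherits(fit, "tpc_meta_fit")) {
    sigma_draws <- fit$sigma
    s2_typical <- s2_typical %||% typical_sampling_variance(fit$design$se)
  } else {
    sigma_draws <- as.matrix(fit)
    if (is.null(s2_typical)) {
      cli::cli_abort("Supply {.arg s2_typical} when passing raw draws.")
    }
  }
  if (s2_typical <= 0) {
    cli::cli_abort("{.arg s2_typical} must be positive.")
  }
  sigma2 <- sigma_draws^2
  total_sigma2 <- rowSums(sigma2)
  denom <- total_sigma2 + s2_typical
  I2 <- cbind(sigma2 / denom, total = total_sigma2 / denom) * 100
  sigma2 <- cbind(sigma2, total = total_sigma2)
  q <- function(m, p) apply(m, 2, quantile, probs = p, names = FALSE)
  summary <- tibble::tibble(
    level = colnames(I2),
    sigma2_median = q(sigma2, 0.5),
    sigma2_lo = q(sigma2, 0.025),
    sigma2_hi = q(sigma2, 0.975),
    I2_mean = colMeans(I2),
    I2_median = q(I2, 0.5),
    I2_lo = q(I2, 0.025),
    I2_hi = q(I2, 0.975)
  )
  structure(
    list(summary = summary, s2_typical = s2_typical, I2_draws = I2),
    class = "tpc_heterogeneity"
  )
}

#' @export
print.tpc_heterogeneity <- function(x, ...) {
  cat(
    "<tpc_heterogeneity> typical sampling variance =",
    signif(x$s2_typical, 4), "\n"
  )
  print(x$summary, ...)
  invisible(x)
}
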
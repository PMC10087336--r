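#' Tidy a measurement-error meta-analytic fit
#'
#' One row per parameter (fixed coefficients and random-effect SDs) with
#' the posterior median, SD, 95% compatibility interval and split-R-hat.
#'
#' @param x A `tpc_meta_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @exportS3Method generics::tidy
tidy.tpc_meta_fit <- function(x, ...) {
  draws <- cbind(x$beta, `colnames<-`(x$sigma, paste0("sd_", colnames(x$sigma))))
  qs <- apply(draws, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = colnames(draws),
    estimate = qs[1, ],
    std.error = apply(draws, 2, sd),
    conf.low = qs[2, ],
    conf.high = qs[3, ],
    rhat = unname(x$rhat[colnames(draws)])
  )
}

#' One-row summary of a meta-analytic fit
#'
#' @param x A `tpc_meta_fit`.
#' @param ... Unused.
#' @return Tibble with `nobs`, `n_draws`, `chains`, `waic`, `p_waic`,
#'   `max_rhat`, `converged`.
#' @exportS3Method generics::glance
glance.tpc_meta_fit <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(
    nobs = length(x$design$y),
    n_draws = x$n_draws,
    chains = x$chains,
    waic = w$waic,
    p_waic = w$p_waic,
    max_rhat = max(x$rhat, na.rm = TRUE),
    converged = x$converged
  )
}
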
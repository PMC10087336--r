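## WAIC machinery: pointwise log-likelihood, WAIC, and model ranking.

.mu_draws <- function(fit, X = NULL, include_random = TRUE) {
  X <- X %||% fit$design$X
  mu <- fit$beta %*% t(X)
  if (include_random) {
    for (lev in fit$spec$random) {
      mu <- mu + fit$u[[lev]][, fit$design$levels[[lev]], drop = FALSE]
    }
  }
  mu
}

#' Pointwise posterior log-likelihood matrix
#'
#' Evaluates, for each posterior draw and each effect, the log density of
#' the observed effect under the measurement-error likelihood with the
#' latent true effect integrated out analytically. Conditioning on the
#' sampled random effects of every level present in the design, the
#' marginal is `y_i ~ Normal(x_i' beta + sum of level effects, se_i^2)`.
#'
#' @param fit A [fit_meta()] result.
#' @return Matrix of dimension draws x effects; required input to [waic()].
#' @export
pointwise_loglik <- function(fit) {
  mu <- .mu_draws(fit)
  y <- fit$design$y
  se <- fit$design$se
  ll <- dnorm(rep(y, each = nrow(mu)), mean = mu,
    sd = rep(se, each = nrow(mu)), log = TRUE
  )
  matrix(ll, nrow = nrow(mu), dimnames = list(NULL, fit$design$effects$effect_id))
}

.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Watanabe-Akaike information criterion
#'
#' Computes WAIC from a pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_d exp(ll_di)` (via log-sum-exp for numerical
#' stability), effective parameter count `p_waic = sum_i var_d(ll_di)`,
#' `waic = -2 (lppd - p_waic)`, with a standard error from the pointwise
#' contributions.
#'
#' @param pointwise Either a draws x effects log-likelihood matrix or a
#'   `tpc_meta_fit` (in which case [pointwise_loglik()] is called).
#' @return A tibble with one row: `waic`, `lppd`, `p_waic`, `se`, `n`.
#' @export
waic <- function(pointwise) {
  if (inherits(pointwise, "tpc_meta_fit")) {
    pointwise <- pointwise_loglik(pointwise)
  }
  if (!all(is.finite(pointwise))) {
    cli::cli_abort("Non-finite pointwise log-likelihood entries.")
  }
  lppd_i <- apply(pointwise, 2, .log_mean_exp)
  p_i <- apply(pointwise, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(pointwise)
  tibble::tibble(
    waic = -2 * sum(elpd_i),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    se = 2 * sqrt(n * var(elpd_i)),
    n = n
  )
}

#' Rank candidate models by WAIC
#'
#' Orders fitted models by ascending WAIC and attaches WAIC differences to
#' the best model and Akaike-style weights `w_m = exp(-delta_m / 2)`
#' (normalised). All fits must be on the same effect subset; ranking models
#' fitted to different data is meaningless and raises an error.
#'
#' @param fits List of `tpc_meta_fit` objects (named list names become
#'   model labels; otherwise the spec labels are used).
#' @return A tibble with columns `model`, `waic`, `p_waic`, `delta_waic`,
#'   `weight`, sorted best-first.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "tpc_meta_fit")) fits <- list(fits)
  ids <- lapply(fits, function(f) f$design$effects$effect_id)
  if (length(unique(lapply(ids, sort))) > 1) {
    cli::cli_abort("Models were fitted to different effect subsets; cannot rank.")
  }
  labels <- names(fits) %||% vapply(fits, function(f) f$spec$label, character(1))
  if (is.null(names(fits))) names(fits) <- labels
  empty <- !nzchar(labels)
  labels[empty] <- vapply(fits[empty], function(f) f$spec$label, character(1))
  w <- dplyr::bind_rows(lapply(fits, function(f) waic(f)[, c("waic", "p_waic")]))
  out <- tibble::tibble(model = labels, w) |>
    dplyr::arrange(.data$waic) |>
    dplyr::mutate(
      delta_waic = .data$waic - .data$waic[1],
      weight = exp(-.data$delta_waic / 2) / sum(exp(-.data$delta_waic / 2))
    )
  out
}
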
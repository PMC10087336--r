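## Measurement-error model fit via JAGS. Observation layer:
##   y_i ~ Normal(theta_i, se_i^2),  se_i known (propagated sampling error)
##   theta_i = x_i' beta + u_species(i) + u_study(i) + u_tpc(i)
## with the finest random level absorbing residual true-effect
## heterogeneity, Normal(0, beta_sd^2) priors on coefficients and
## Exponential(sigma_rate) priors on the level SDs.

.jags_model_string <- function(levels) {
  lev_terms <- paste0("u_", levels, "[idx_", levels, "[i]]", collapse = " + ")
  lev_blocks <- paste(vapply(levels, function(lev) {
    paste0(
      "  for (k in 1:n_", lev, ") { u_", lev,
      "[k] ~ dnorm(0, pow(sd_", lev, ", -2)) }\n",
      "  sd_", lev, " ~ dexp(sigma_rate)\n"
    )
  }, character(1)), collapse = "")
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    mu[i] <- inprod(X[i,], beta) + ", lev_terms, "\n",
    "    y[i] ~ dnorm(mu[i], prec_y[i])\n",
    "  }\n",
    "  for (j in 1:P) { beta[j] ~ dnorm(0, beta_prec) }\n",
    lev_blocks,
    "}\n"
  )
}

.split_rhat <- function(mat, n_chains) {
  # mat: (chains * n) x params, chains stacked; split each chain in half
  n <- nrow(mat) / n_chains
  half <- floor(n / 2)
  if (half < 2) {
    return(setNames(rep(NA_real_, ncol(mat)), colnames(mat)))
  }
  apply(mat, 2, function(x) {
    chains <- split(x, rep(seq_len(n_chains), each = n))
    halves <- unlist(lapply(chains, function(ch) {
      list(ch[seq_len(half)], ch[seq_len(half) + half])
    }), recursive = FALSE)
    m <- vapply(halves, mean, numeric(1))
    v <- vapply(halves, var, numeric(1))
    W <- mean(v)
    B <- half * var(m)
    if (!is.finite(W) || W == 0) {
      return(if (var(x) == 0) 1 else NA_real_)
    }
    sqrt(((half - 1) / half * W + B / half) / W)
  })
}

#' Fit a Bayesian multilevel measurement-error meta-analytic model
#'
#' Samples the posterior of the model specified by a [meta_model_spec()] on
#' a [build_design()] bundle using Gibbs/slice sampling (JAGS). Each
#' observed effect is treated as a noisy measurement, with known standard
#' error, of a true effect composed of fixed moderator terms and random
#' effects for species, study and (optionally) TPC identity — so effects
#' are weighted by their study precision and within-hierarchy pooling is
#' controlled by the sampled level variances.
#'
#' Draws are reproducible given `seed`: chain `c` is initialised with RNG
#' seed `seed + c`. Split-R-hat is computed for every coefficient and
#' level SD; values above 1.05 flag the fit as non-converged (a warning,
#' surfaced in [glance()], never silently dropped).
#'
#' @param design A `tpc_design` from [build_design()], or an effect tibble
#'   (in which case `spec` must be supplied and the design is built here).
#' @param spec Optional [meta_model_spec()] when `design` is an effect
#'   tibble.
#' @param seed Integer seed controlling all chains.
#' @param quiet Suppress the JAGS progress output. Default `TRUE`.
#' @return An object of class `tpc_meta_fit`: posterior draws for the
#'   coefficients (`beta`), level SDs (`sigma`), and random effects (`u`),
#'   plus the design, diagnostics (`rhat`, `ess`) and MCMC metadata.
#'   Methods: [tidy()], [glance()], [predict_curve()], [autoplot()].
#' @export
#' @examples
#' \donttest{
#' eff <- simulate_effects_direct(
#'   mu = 0.2, sigma_species = 0.1, sigma_study = 0.1,
#'   n_species = 8, n_studies_per_species = 3, n_effects_per_study = 3,
#'   seed = 7
#' )
#' fit <- fit_meta(eff,
#'   spec = meta_model_spec(iterations = 2000, warmup = 500, chains = 2),
#'   seed = 7
#' )
#' tidy(fit)
#' }
fit_meta <- function(design, spec = NULL, seed = 1, quiet = TRUE) {
  if (!inherits(design, "tpc_design")) {
    if (is.null(spec)) {
      cli::cli_abort("Supply a {.cls tpc_design} or an effect tibble plus {.arg spec}.")
    }
    design <- build_design(design, spec)
  }
  spec <- design$spec
  data <- list(
    N = length(design$y),
    P = ncol(design$X),
    X = design$X,
    y = design$y,
    prec_y = 1 / design$se^2,
    beta_prec = 1 / spec$priors$beta_sd^2,
    sigma_rate = spec$priors$sigma_rate
  )
  for (lev in spec$random) {
    data[[paste0("idx_", lev)]] <- design$levels[[lev]]
    data[[paste0("n_", lev)]] <- length(design$level_labels[[lev]])
  }
  inits <- lapply(seq_len(spec$chains), function(c) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (seed + c - 1) %% .Machine$integer.max + 1
    )
  })
  run <- function() {
    m <- rjags::jags.model(
      textConnection(.jags_model_string(spec$random)),
      data = data, inits = inits, n.chains = spec$chains,
      n.adapt = spec$warmup, quiet = quiet
    )
    monitors <- c("beta", paste0("sd_", spec$random), paste0("u_", spec$random))
    rjags::coda.samples(
      m, monitors,
      n.iter = spec$iterations - spec$warmup,
      progress.bar = "none"
    )
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  full <- do.call(rbind, lapply(samples, as.matrix))
  vec_cols <- function(stem, k) {
    # coda drops the [1] index for length-1 monitored vectors
    if (k == 1 && stem %in% colnames(full)) stem else paste0(stem, "[", seq_len(k), "]")
  }
  beta <- full[, vec_cols("beta", data$P), drop = FALSE]
  colnames(beta) <- colnames(design$X)
  sigma <- full[, paste0("sd_", spec$random), drop = FALSE]
  colnames(sigma) <- spec$random
  u <- lapply(setNames(spec$random, spec$random), function(lev) {
    nk <- length(design$level_labels[[lev]])
    um <- full[, vec_cols(paste0("u_", lev), nk), drop = FALSE]
    colnames(um) <- design$level_labels[[lev]]
    um
  })
  diag_mat <- cbind(beta, `colnames<-`(sigma, paste0("sd_", spec$random)))
  rhat <- .split_rhat(diag_mat, spec$chains)
  ess <- tryCatch(
    vapply(
      seq_len(ncol(diag_mat)),
      function(j) as.numeric(coda::effectiveSize(diag_mat[, j])),
      numeric(1)
    ),
    error = function(e) rep(NA_real_, ncol(diag_mat))
  )
  names(ess) <- colnames(diag_mat)
  converged <- all(rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    cli::cli_warn(
      "Split-R-hat above 1.05 for {.val {names(rhat)[which(rhat > 1.05)]}};
       treat summaries with caution."
    )
  }
  structure(
    list(
      beta = beta, sigma = sigma, u = u,
      design = design, spec = spec, seed = seed,
      n_draws = nrow(beta), chains = spec$chains,
      rhat = rhat, ess = ess, converged = converged
    ),
    class = "tpc_meta_fit"
  )
}

#' @export
print.tpc_meta_fit <- function(x, ...) {
  cat(
    "<tpc_meta_fit>", x$spec$label, "|", length(x$design$y), "effects |",
    x$n_draws, "draws (", x$chains, "chains )\n"
  )
  if (!x$converged) cat("  WARNING: split-R-hat > 1.05 on some parameters\n")
  print(tidy(x), ...)
  invisible(x)
}
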
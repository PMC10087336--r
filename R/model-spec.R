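#' Specify a multilevel measurement-error meta-analytic model
#'
#' A model specification bundles the fixed-effect design (moderators and a
#' polynomial in relative assay temperature), the random-effect levels, the
#' priors and the MCMC settings. The intercept is always present. Fixed
#' terms are drawn from the moderators carried by effect records:
#' \describe{
#'   \item{`"var"`}{variation source (de novo mutation vs standing genetic
#'     variation), indicator-coded with `standing` as reference;}
#'   \item{`"gen"`}{number of generations the experiment lasted, centred
#'     and scaled; requesting it on effects with missing generations is an
#'     error (use the reduced data set instead);}
#'   \item{`"sign"`}{relative selection temperature (selection above, below
#'     or equal to the control regime), indicator-coded;}
#'   \item{`"var:dt"`}{interaction of the variation-source indicator with
#'     every polynomial temperature term.}
#' }
#' The temperature predictor is either a raw-power polynomial in the signed
#' relative assay temperature (`poly_degree` 1 to 3, centred at the
#' selection temperature by construction since the predictor is
#' assay minus selection temperature) or the absolute relative assay
#' temperature (`abs_dt = TRUE`), as used for two-point reaction norms.
#'
#' Priors are vaguely informative on the effect-size scale, where relative
#' fitness rarely exceeds 2 in magnitude: Normal(0, `beta_sd`) on the
#' intercept and coefficients (default SD 1) and Exponential(`sigma_rate`)
#' on the random-effect standard deviations (default rate 1).
#'
#' @param fixed Character vector of moderator terms, a subset of
#'   `c("var", "gen", "sign", "var:dt")`. Default none (intercept only).
#' @param poly_degree Degree of the polynomial in signed relative assay
#'   temperature, 0 (none) to 3 (cubic). Default 0.
#' @param abs_dt Use `|relative assay temperature|` as a linear predictor
#'   instead of a signed polynomial. Default `FALSE`.
#' @param random Character vector of random-effect levels, a non-empty
#'   subset of `c("species", "study", "tpc")`. Default species and study;
#'   add `"tpc"` for two-point and multipoint analyses so that independent
#'   TPC measurements are not pooled.
#' @param priors Named list with elements `beta_sd` and `sigma_rate`.
#' @param iterations,warmup,chains MCMC settings: total iterations per
#'   chain (default 30000), warmup iterations discarded per chain (default
#'   1000) and number of chains (default 4).
#' @param label Optional model label used in ranking tables; derived from
#'   the terms when omitted.
#' @return An object of class `tpc_model_spec`.
#' @export
#' @examples
#' meta_model_spec(fixed = "var", poly_degree = 3, random = c("species", "study", "tpc"))
meta_model_spec <- function(fixed = character(), poly_degree = 0, abs_dt = FALSE,
                            random = c("species", "study"),
                            priors = list(beta_sd = 1, sigma_rate = 1),
                            iterations = 30000, warmup = 1000, chains = 4,
                            label = NULL) {
  allowed <- c("var", "gen", "sign", "var:dt")
  bad <- setdiff(fixed, allowed)
  if (length(bad)) {
    cli::cli_abort("Unknown fixed term{?s} {.val {bad}}; allowed: {.val {allowed}}.")
  }
  if (!poly_degree %in% 0:3) {
    cli::cli_abort("{.arg poly_degree} must be 0, 1, 2 or 3.")
  }
  if (abs_dt && poly_degree > 0) {
    cli::cli_abort("Use either {.arg abs_dt} or a signed polynomial, not both.")
  }
  if ("var:dt" %in% fixed && poly_degree == 0) {
    cli::cli_abort("{.val var:dt} requires a polynomial temperature term.")
  }
  random <- match.arg(random, c("species", "study", "tpc"), several.ok = TRUE)
  if (length(random) == 0) {
    cli::cli_abort("At least one random-effect level is required.")
  }
  if (warmup >= iterations) {
    cli::cli_abort("{.arg warmup} must be smaller than {.arg iterations}.")
  }
  priors <- utils::modifyList(list(beta_sd = 1, sigma_rate = 1), priors)
  if (is.null(label)) {
    parts <- c(
      "intercept",
      if (poly_degree > 0) paste0("dt^", poly_degree),
      if (abs_dt) "|dt|",
      fixed
    )
    label <- paste(parts, collapse = "+")
  }
  structure(
    list(
      fixed = fixed, poly_degree = poly_degree, abs_dt = abs_dt,
      random = random, priors = priors,
      iterations = iterations, warmup = warmup, chains = chains,
      label = label
    ),
    class = "tpc_model_spec"
  )
}

#' @export
print.tpc_model_spec <- function(x, ...) {
  cat("<tpc_model_spec>", x$label, "\n")
  cat("  random levels:", paste(x$random, collapse = ", "), "\n")
  cat(
    "  priors: beta ~ Normal(0, ", x$priors$beta_sd,
    "), level SD ~ Exponential(", x$priors$sigma_rate, ")\n",
    sep = ""
  )
  cat(
    "  mcmc:", x$chains, "chain(s) x", x$iterations, "iterations (",
    x$warmup, "warmup )\n"
  )
  invisible(x)
}
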
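#' Population-level posterior prediction curve
#'
#' Evaluates the fixed-effect (population-level) prediction of relative
#' fitness over a grid of relative assay temperatures, with random effects
#' set to zero, and summarises the per-draw predictions by their median and
#' 95% compatibility interval. Grid points outside the observed range of
#' relative assay temperatures are allowed but flagged as extrapolation.
#'
#' @param fit A [fit_meta()] result.
#' @param grid Numeric vector of relative assay temperatures (assay minus
#'   selection temperature, degrees Celsius). Defaults to 41 points over
#'   the observed range.
#' @param moderators Named list fixing the moderator setting of the curve:
#'   `var` (`"standing"` or `"de_novo"`; default reference `"standing"`),
#'   `sign` (default `"equal"`), `gen` (raw generation count; default the
#'   training-data mean). Moderators absent from the model are ignored.
#' @return Tibble with columns `rel_assay_temp`, `estimate` (posterior
#'   median of the population mean), `conf.low`, `conf.high` (95% interval)
#'   and `extrapolated`.
#' @export
predict_curve <- function(fit, grid = NULL, moderators = list()) {
  rng <- range(fit$design$effects$rel_assay_temp)
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 41)
  newdata <- tibble::tibble(
    rel_assay_temp = grid,
    variation_source = moderators$var %||% "standing",
    sign = moderators$sign %||% "equal",
    generations = moderators$gen %||% fit$design$x_info$gen_center
  )
  Xg <- .fixed_matrix(newdata, fit$spec, fit$design$x_info)$X
  mu <- fit$beta %*% t(Xg)
  qs <- apply(mu, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  extrap <- grid < rng[1] | grid > rng[2]
  if (any(extrap)) {
    cli::cli_warn(
      "{sum(extrap)} grid point{?s} outside the observed relative assay
       temperature range [{round(rng[1], 2)}, {round(rng[2], 2)}] - extrapolation."
    )
  }
  tibble::tibble(
    rel_assay_temp = grid,
    estimate = qs[1, ],
    conf.low = qs[2, ],
    conf.high = qs[3, ],
    extrapolated = extrap
  )
}
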
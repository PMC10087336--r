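## Moderator collinearity screening: point-biserial correlation for a
## binary-continuous pair and maximum-likelihood tetrachoric correlation
## for a binary-binary pair (latent bivariate normal dichotomised at
## thresholds set by the margins).

#' Point-biserial correlation
#'
#' Correlation between a binary and a continuous variable:
#' `(mean1 - mean0) / sd * sqrt(p (1 - p))`, with the population standard
#' deviation of the continuous variable and `p` the proportion of ones.
#' Equivalent to the Pearson correlation of the 0/1 coding with the
#' continuous values.
#'
#' @param binary Vector coercible to 0/1 (logical or numeric); both groups
#'   must be non-empty.
#' @param cont Continuous values of the same length, with positive variance.
#' @return Correlation in `[-1, 1]`.
#' @export
point_biserial <- function(binary, cont) {
  keep <- !is.na(binary) & !is.na(cont)
  binary <- as.numeric(binary[keep])
  cont <- cont[keep]
  if (!all(binary %in% c(0, 1))) {
    cli::cli_abort("{.arg binary} must contain only 0/1 (or logical) values.")
  }
  p <- mean(binary)
  if (p == 0 || p == 1) {
    cli::cli_abort("Both groups of {.arg binary} must be non-empty.")
  }
  sd_pop <- sqrt(mean((cont - mean(cont))^2))
  if (sd_pop == 0) {
    cli::cli_abort("{.arg cont} has zero variance.")
  }
  (mean(cont[binary == 1]) - mean(cont[binary == 0])) / sd_pop * sqrt(p * (1 - p))
}

# P(Z1 >= h, Z2 >= k) for standard bivariate normal with correlation rho,
# by numerical integration of the conditional-normal form.
.bvn_upper <- function(h, k, rho) {
  if (abs(rho) >= 1) {
    rho <- sign(rho) * (1 - 1e-12)
  }
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((rho * x - k) / s)
  integrate(f, lower = h, upper = Inf, rel.tol = 1e-9, abs.tol = 1e-10)$value
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood correlation of a latent standard bivariate normal
#' whose two dichotomisation thresholds reproduce the table margins.
#' The table is oriented with concordance on the diagonal: `table[1, 1]`
#' counts observations in the first category of both variables. Thresholds
#' are fixed at the normal quantiles of the marginal proportions and the
#' correlation maximises the multinomial cell-probability likelihood, with
#' the bivariate normal CDF evaluated by numerical integration (accuracy
#' around 1e-6).
#'
#' Tables with a zero margin are an error. Tables with a zero cell are at
#' the boundary of the parameter space and return +1 or -1 (perfect
#' concordance or discordance) with attribute `boundary = TRUE` and a
#' warning, rather than a continuity-corrected interior value.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return Correlation in `[-1, 1]`, with attribute `boundary`.
#' @export
#' @examples
#' tetrachoric(matrix(c(40, 10, 10, 40), 2, 2))
tetrachoric <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    cli::cli_abort("{.arg table} must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    cli::cli_abort("Zero margin: the tetrachoric correlation is undefined.")
  }
  n <- sum(table)
  if (any(table == 0)) {
    # boundary: a zero off-diagonal cell is the perfect-concordance limit,
    # a zero diagonal cell the perfect-discordance limit
    est <- if (table[1, 2] == 0 || table[2, 1] == 0) 1 else -1
    cli::cli_warn("Zero cell: returning the boundary estimate {est}.")
    return(structure(est, boundary = TRUE))
  }
  # thresholds from margins: latent X >= h <=> first row, Y >= k <=> first col
  h <- qnorm(1 - rowSums(table)[1] / n)
  k <- qnorm(1 - colSums(table)[1] / n)
  loglik <- function(rho) {
    p11 <- .bvn_upper(h, k, rho)
    p1x <- 1 - pnorm(h)
    px1 <- 1 - pnorm(k)
    p <- c(p11, p1x - p11, px1 - p11, 1 - p1x - px1 + p11)
    p <- pmax(p, 1e-12)
    sum(c(table[1, 1], table[1, 2], table[2, 1], table[2, 2]) * log(p))
  }
  opt <- optimize(loglik, interval = c(-0.999, 0.999), maximum = TRUE, tol = 1e-6)
  structure(opt$maximum, boundary = FALSE)
}

#' Screen moderators for collinearity
#'
#' Computes pairwise correlations among the moderators of an effect table
#' (variation source, reproduction/sexuality, comparison type, generations)
#' using the tetrachoric correlation for binary-binary pairs and the
#' point-biserial correlation for binary-continuous pairs, and flags pairs
#' whose absolute correlation exceeds `threshold`. For each cluster of
#' flagged moderators one representative is retained (preference order:
#' variation source, generations, sexuality, comparison) and the rest are
#' recommended for dropping — strongly collinear moderators cannot be
#' estimated jointly.
#'
#' @param effects Effect tibble with columns `variation_source`, `sexual`,
#'   `comparison` and `generations` (rows with missing generations are
#'   ignored for pairs involving it).
#' @param threshold Absolute-correlation flag threshold. Default 0.7.
#' @return List with `correlations` (tibble: `pair`, `method`, `estimate`,
#'   `flagged`) and `drop` (character vector of moderators recommended for
#'   removal).
#' @export
screen_moderators <- function(effects, threshold = 0.7) {
  effects <- tibble::as_tibble(effects)
  binaries <- list(
    var = as.numeric(effects$variation_source == "de_novo"),
    rep = as.numeric(effects$sexual),
    comp = as.numeric(effects$comparison == "ancestor")
  )
  gen <- effects$generations
  rows <- list()
  bn <- names(binaries)
  for (i in seq_along(binaries)) {
    for (j in seq_along(binaries)) {
      if (i >= j) next
      x <- binaries[[i]]
      y <- binaries[[j]]
      est <- if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        NA_real_
      } else {
        tab <- matrix(c(
          sum(x == 1 & y == 1), sum(x == 1 & y == 0),
          sum(x == 0 & y == 1), sum(x == 0 & y == 0)
        ), 2, 2, byrow = TRUE)
        suppressWarnings(as.numeric(tetrachoric(tab)))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        pair = paste(bn[i], bn[j], sep = "-"),
        method = "tetrachoric", estimate = est
      )
    }
  }
  for (i in seq_along(binaries)) {
    keep <- !is.na(gen)
    x <- binaries[[i]][keep]
    est <- if (sum(keep) < 3 || length(unique(x)) < 2 || var(gen[keep]) == 0) {
      NA_real_
    } else {
      point_biserial(x, gen[keep])
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair = paste(bn[i], "gen", sep = "-"),
      method = "point_biserial", estimate = est
    )
  }
  correlations <- dplyr::bind_rows(rows) |>
    dplyr::mutate(flagged = !is.na(.data$estimate) & abs(.data$estimate) > threshold)
  priority <- c("var", "gen", "rep", "comp")
  drop <- character()
  flagged_pairs <- strsplit(correlations$pair[correlations$flagged], "-")
  involved <- unique(unlist(flagged_pairs))
  if (length(involved) > 1) {
    keep_one <- priority[priority %in% involved][1]
    drop <- setdiff(involved, keep_one)
  }
  list(correlations = correlations, drop = drop)
}
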
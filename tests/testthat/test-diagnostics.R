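test_that("point-biserial correlation matches its formula and symmetries", {
  # perfectly separated groups {0: 1,2 ; 1: 9,10}
  b <- c(0, 0, 1, 1)
  x <- c(1, 2, 9, 10)
  got <- point_biserial(b, x)
  manual <- (mean(x[b == 1]) - mean(x[b == 0])) /
    sqrt(mean((x - mean(x))^2)) * sqrt(0.5 * 0.5)
  expect_equal(got, manual)
  expect_gt(got, 0.9)
  # equals the Pearson correlation of the 0/1 coding
  expect_equal(got, cor(b, x))

  # symmetric paired values in both groups: zero
  expect_equal(point_biserial(c(0, 0, 1, 1), c(-1, 1, -1, 1)), 0)
  # flipping the labels flips the sign
  expect_equal(point_biserial(1 - b, x), -got)
  expect_error(point_biserial(c(1, 1), c(1, 2)), "non-empty")
  expect_error(point_biserial(c(0, 1), c(2, 2)), "variance")
})

test_that("tetrachoric boundary and independence tables behave", {
  expect_warning(r1 <- tetrachoric(matrix(c(50, 0, 0, 50), 2, 2)), "boundary")
  expect_equal(as.numeric(r1), 1)
  expect_true(attr(r1, "boundary"))
  expect_warning(r2 <- tetrachoric(matrix(c(0, 30, 30, 0), 2, 2)), "boundary")
  expect_equal(as.numeric(r2), -1)
  expect_equal(as.numeric(tetrachoric(matrix(25, 2, 2))), 0, tolerance = 1e-4)
  expect_error(tetrachoric(matrix(c(10, 0, 20, 0), 2, 2)), "margin")
})

test_that("tetrachoric is antisymmetric under swapping one margin", {
  tab <- matrix(c(40, 10, 10, 40), 2, 2)
  expect_equal(
    as.numeric(tetrachoric(tab)),
    -as.numeric(tetrachoric(tab[2:1, ])),
    tolerance = 1e-4
  )
})

test_that("tetrachoric matches a grid-search ML oracle on random tables", {
  skip_if_not_installed("mvtnorm")
  oracle <- function(tab) {
    n <- sum(tab)
    h <- qnorm(1 - rowSums(tab)[1] / n)
    k <- qnorm(1 - colSums(tab)[1] / n)
    rhos <- seq(-0.999, 0.999, by = 1e-3)
    ll <- vapply(rhos, function(r) {
      p11 <- mvtnorm::pmvnorm(
        lower = c(h, k), upper = c(Inf, Inf),
        corr = matrix(c(1, r, r, 1), 2)
      )[1]
      p <- c(
        p11, 1 - pnorm(h) - p11, 1 - pnorm(k) - p11,
        pnorm(h) + pnorm(k) + p11 - 1
      )
      sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pmax(p, 1e-12)))
    }, numeric(1))
    rhos[which.max(ll)]
  }
  set.seed(404)
  for (rep in 1:20) {
    tab <- matrix(sample(5:60, 4, replace = TRUE), 2, 2)
    expect_lt(abs(as.numeric(tetrachoric(tab)) - oracle(tab)), 1e-2)
  }
})

test_that("moderator screening flags engineered collinearity and spares
           independent moderators", {
  # var and sexuality nearly perfectly concordant: tetrachoric near 1
  set.seed(7)
  n <- 400
  var_bin <- rbinom(n, 1, 0.5)
  flip <- rbinom(n, 1, 0.02) == 1
  eff <- tibble::tibble(
    variation_source = ifelse(var_bin == 1, "de_novo", "standing"),
    sexual = ifelse(flip, var_bin == 1, var_bin == 0),
    comparison = sample(c("ancestor", "control"), n, replace = TRUE),
    generations = exp(rnorm(n, 3, 0.5))
  )
  sc <- screen_moderators(eff)
  expect_true(sc$correlations$flagged[sc$correlations$pair == "var-rep"])
  expect_true("rep" %in% sc$drop)
  expect_false("var" %in% sc$drop) # representative retained

  # threshold 1.0 flags nothing
  sc2 <- screen_moderators(eff, threshold = 1.0)
  expect_false(any(sc2$correlations$flagged))
  expect_length(sc2$drop, 0)
})

test_that("independent moderators are rarely flagged", {
  set.seed(11)
  hits <- 0
  for (rep in 1:20) {
    n <- 500
    eff <- tibble::tibble(
      variation_source = sample(c("de_novo", "standing"), n, replace = TRUE),
      sexual = sample(c(TRUE, FALSE), n, replace = TRUE),
      comparison = sample(c("ancestor", "control"), n, replace = TRUE),
      generations = exp(rnorm(n, 3, 0.5))
    )
    sc <- suppressWarnings(screen_moderators(eff))
    if (!any(sc$correlations$flagged)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the bias test flags a degenerate SE spread as unidentifiable", {
  eff <- toy_effects(rnorm(20, 0.2, 0.2), rep(0.1, 20))
  expect_warning(res <- bias_test(eff), "unidentifiable")
  expect_equal(res$verdict, "unidentifiable")
  expect_true(is.na(res$slope$estimate))
  expect_equal(nrow(res$funnel), 20)
})

test_that("one-sided suppression produces a detectable funnel asymmetry", {
  eff <- simulate_effects_direct(
    mu = 0, sigma_species = 0.05, sigma_study = 0.05,
    n_species = 20, n_studies_per_species = 5, n_effects_per_study = 4,
    se = c(0.02, 0.4), seed = 303
  )
  supp <- eff[eff$rel_fitness >= 0, , drop = FALSE] # suppress negative effects
  res <- bias_test(supp, iterations = 3000, warmup = 500, seed = 303)
  expect_gt(res$slope$estimate, 0)
  expect_equal(res$verdict, "possible bias")
})
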
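# Univariable optimal discriminant analysis: cutpoint search,
# permutation inference, and the ranked screen.

test_that("perfect separation is found at the midpoint with ESS 100", {
  cp <- optimal_cutpoint(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(cp$cutpoint, 6.5)
  expect_equal(cp$direction, ">")
  expect_equal(cp$ess, 100)
  # reversed polarity flips direction, not the cut
  cp2 <- optimal_cutpoint(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_equal(cp2$cutpoint, 6.5)
  expect_equal(cp2$direction, "<=")
  expect_equal(cp2$ess, 100)
})

test_that("the result is invariant to subject order and logs missing values", {
  withr::with_seed(11, {
    v <- rnorm(60)
    y <- rbinom(60, 1, 0.4)
    v[c(3, 40)] <- NA
    cp <- optimal_cutpoint(v, y)
    perm <- sample(60)
    cp2 <- optimal_cutpoint(v[perm], y[perm])
    expect_equal(cp2$cutpoint, cp$cutpoint)
    expect_equal(cp2$ess, cp$ess)
    expect_equal(cp$n_missing, 2L)
    expect_equal(cp$n_used, 58L)
  })
})

test_that("degenerate inputs give the no-model signal", {
  expect_null(optimal_cutpoint(rep(5, 10), rbinom(10, 1, 0.5)))
  expect_null(optimal_cutpoint(1:10, rep(1, 10)))
  expect_null(optimal_cutpoint(1:10, rep(0, 10)))
})

test_that("the search matches a brute-force midpoint scan on random instances", {
  withr::with_seed(202, {
    for (i in 1:60) {
      n <- sample(10:60, 1)
      # mixed granularities so ties and repeated values occur
      v <- sample(round(stats::rnorm(n, 50, 20), sample(c(0, 1), 1)))
      y <- stats::rbinom(n, 1, runif(1, 0.15, 0.85))
      if (length(unique(y)) < 2 || length(unique(v)) < 2) next
      cp <- optimal_cutpoint(v, y)
      bb <- oracle_cutpoint(v, y)
      expect_equal(cp$ess, bb$ess, tolerance = 1e-9)
      # the optimum must dominate every midpoint x direction
      expect_true(cp$ess >= bb$ess - 1e-9)
    }
  })
})

test_that("exhaustive permutation p enumerates all labellings", {
  v <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  cp <- permutation_p(optimal_cutpoint(v, y), v, y)
  # of the C(6,3) = 20 labellings, only the two monotone ones reach ESS 100
  expect_equal(cp$p_value, 2 / 20)
  expect_equal(cp$p_method, "exhaustive")
  expect_equal(cp$n_permutations, 20L)
})

test_that("Monte Carlo p is reproducible and agrees with enumeration", {
  withr::with_seed(5, {
    v <- rnorm(12)
    y <- c(rep(1, 5), rep(0, 7))[sample(12)]
  })
  cp <- optimal_cutpoint(v, y)
  exact <- permutation_p(cp, v, y, exhaustive_limit = 1e4)
  expect_equal(exact$p_method, "exhaustive")
  mc <- permutation_p(cp, v, y, n_mc = 4000, seed = 99, exhaustive_limit = 0)
  expect_equal(mc$p_method, "monte_carlo")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / 4001)
  mc2 <- permutation_p(cp, v, y, n_mc = 4000, seed = 99,
                       exhaustive_limit = 0)
  expect_identical(mc2$p_value, mc$p_value)
  expect_warning(permutation_p(cp, v, y, n_mc = 50, seed = 1,
                               exhaustive_limit = 0),
                 class = "odacta_config_warning")
})

test_that("fixed-cutpoint null equals the hypergeometric tail", {
  v <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  cp <- optimal_cutpoint(v, y)
  fx <- permutation_p(cp, v, y, null = "fixed")
  expect_equal(fx$p_method, "hypergeometric")
  expect_equal(fx$p_value, 2 / choose(10, 5))
})

test_that("binary-attribute p matches full enumeration and boundary cases", {
  expect_equal(binary_attribute_p(counts_2x2(5, 0, 0, 5)),
               2 / choose(10, 5))
  expect_equal(binary_attribute_p(counts_2x2(5, 5, 5, 5)), 1)
  # cross-check against the re-optimised enumeration on a binary
  # attribute, where the two nulls coincide (only one cutpoint exists)
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- rbinom(10, 1, 0.5)
      y <- rbinom(10, 1, 0.5)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      counts <- counts_2x2(sum(x & y), sum(x & !y),
                           sum(!x & y), sum(!x & !y))
      m <- metrics_from_counts(counts)
      cc <- if (m$ess >= 0) counts else
        counts_2x2(counts$c, counts$d, counts$a, counts$b)
      cp <- optimal_cutpoint(x, y)
      ex <- permutation_p(cp, x, y, exhaustive_limit = 1e4)
      expect_equal(binary_attribute_p(cc), ex$p_value, tolerance = 1e-12)
    }
  })
})

test_that("Sidak criterion follows the closed form and is monotone", {
  expect_equal(sidak_criterion(0.05, 1), 0.05)
  expect_equal(sidak_criterion(0.05, 10), 1 - 0.95^0.1)
  expect_equal(round(sidak_criterion(0.05, 10), 6), 0.005116)
  ks <- sidak_criterion(0.05, 1:30)
  expect_true(all(diff(ks) < 0))
  expect_error(sidak_criterion(1.2, 3), class = "odacta_input_error")
})

test_that("the screen ranks a planted duration effect first and honours modes", {
  tab <- make_screen_cohort()
  sc <- univariable_screen(tab, predictors = c("exposure_days", "nsaid",
                                               "age", "noise"),
                           n_mc = 499, seed = 3)
  expect_s3_class(sc, "odacta_screen")
  expect_equal(sc$predictor[1], "exposure_days")
  expect_true(all(diff(sc$ess) <= 0))
  expect_true(all(sc$p_value <= 0.05))
  # experimentwise mode tightens the threshold
  sc2 <- univariable_screen(tab, predictors = c("exposure_days", "nsaid",
                                                "age", "noise"),
                            mode = "experimentwise", n_mc = 499, seed = 3)
  expect_equal(attr(sc2, "threshold"), sidak_criterion(0.05, 4))
  expect_true(all(sc2$p_value <= attr(sc2, "threshold")))
  # a single screened predictor gets the unadjusted threshold
  sc1 <- univariable_screen(tab, predictors = "exposure_days",
                            mode = "experimentwise", n_mc = 199, seed = 3)
  expect_equal(attr(sc1, "threshold"), 0.05)
  # binary predictors carry no cutpoint, ordered ones do
  sc_all <- univariable_screen(tab, predictors = c("exposure_days", "nsaid"),
                               n_mc = 199, seed = 3, filter = FALSE)
  expect_true(is.na(sc_all$cutpoint[sc_all$predictor == "nsaid"]))
  expect_false(is.na(sc_all$cutpoint[sc_all$predictor == "exposure_days"]))
})

test_that("null predictors pass the generalized screen at about the nominal rate", {
  hits <- withr::with_seed(77, {
    vapply(1:150, function(i) {
      y <- rbinom(40, 1, 0.5)
      x <- rnorm(40)
      cp <- optimal_cutpoint(x, y)
      if (is.null(cp)) return(FALSE)
      permutation_p(cp, x, y, n_mc = 199, seed = i,
                    exhaustive_limit = 0)$p_value <= 0.05
    }, logical(1))
  })
  # 99% binomial envelope around 0.05 at 150 replicates
  expect_lt(abs(mean(hits) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 150) + 0.01)
})

test_that("screen output converts to a plot", {
  tab <- make_screen_cohort(n = 300)
  sc <- univariable_screen(tab, predictors = c("exposure_days", "nsaid"),
                           n_mc = 199, seed = 2, filter = FALSE)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
})
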
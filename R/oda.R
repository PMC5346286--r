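#' @importFrom rlang .data
NULL

# ---- internal machinery -----------------------------------------------------

# Sorted-order representation of an (attribute, outcome) instance.
# Cutpoint candidates are midpoints between adjacent *distinct* sorted
# values; `boundary` holds the sorted positions i such that a cut can be
# placed between position i and i + 1.
oda_instance <- function(values, outcome, min_size = 0L) {
  keep <- !is.na(values) & !is.na(outcome)
  v <- as.numeric(values[keep])
  y <- as.integer(outcome[keep])
  ord <- order(v)
  v <- v[ord]
  y <- y[ord]
  n <- length(v)
  boundary <- which(v[-n] != v[-1])
  if (min_size > 0) {
    boundary <- boundary[boundary >= min_size & (n - boundary) >= min_size]
  }
  list(v = v, y = y, n = n, n_cases = sum(y), n_controls = n - sum(y),
       boundary = boundary, n_missing = sum(!keep))
}

# Signed ESS profile for direction ">" at every boundary: with the first
# i sorted subjects on the "<=" side, sens = (P - cases_le)/P and
# spec = ctrl_le/N, so ESS_gt = 100 * (ctrl_le/N - cases_le/P).  The
# "<=" direction is the mirror image, ESS_le = -ESS_gt, so a single
# signed profile covers both directions.
ess_profile_gt <- function(inst, y = inst$y) {
  cases_le <- cumsum(y)[inst$boundary]
  ctrl_le <- inst$boundary - cases_le
  100 * (ctrl_le / inst$n_controls - cases_le / inst$n_cases)
}

# Maximal two-direction ESS for one labelling of a fixed instance.
max_ess <- function(inst, y = inst$y) {
  if (length(inst$boundary) == 0L) return(0)
  max(abs(ess_profile_gt(inst, y)))
}

# ---- optimal cutpoint -------------------------------------------------------

#' Univariable optimal discriminant cutpoint
#'
#' Exhaustive search for the cutpoint and direction that maximise the
#' effect strength for sensitivity (ESS) of the dichotomised attribute
#' against a binary outcome. Every midpoint between adjacent distinct
#' observed values is evaluated in both directions (effect-positive side
#' `>` or `<=` the cutpoint), which is why reported cutpoints take
#' half-way forms such as 90.5 or 208.5 when observations are integer.
#'
#' Ties in ESS are broken deterministically: first by the larger
#' accuracy on the smaller outcome class, then by the smaller cutpoint,
#' then by direction (`<=` before `>`).
#'
#' Missing values are excluded pairwise and their number recorded.
#'
#' @param values Numeric (ordered) attribute, one per subject.
#' @param outcome Binary outcome (0/1 or logical), one per subject.
#' @param attribute Name used in printed and tabulated output.
#' @param min_size Minimum number of subjects required on each side of
#'   the cut (0 = unconstrained). Used by the tree fitter to enforce
#'   its minimum-endpoint-size constraint.
#' @return An object of class `odacta_cutpoint`: a list with elements
#'   `attribute`, `direction` (`">"` or `"<="`), `cutpoint`, `counts`
#'   (an `odacta_counts`), `metrics` (tibble from
#'   [metrics_from_counts()]), `ess`, `n_used`, `n_missing`. Returns
#'   `NULL` (no-model signal) when the attribute is constant, either
#'   outcome class is empty, or no cut satisfies `min_size`.
#' @export
#' @examples
#' optimal_cutpoint(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
optimal_cutpoint <- function(values, outcome, attribute = "x", min_size = 0L) {
  if (length(values) != length(outcome)) {
    abort_odacta("`values` and `outcome` must have the same length.",
                 "odacta_input_error")
  }
  inst <- oda_instance(values, outcome, min_size = min_size)
  if (inst$n_cases == 0L || inst$n_controls == 0L ||
      length(inst$boundary) == 0L) {
    return(NULL)
  }
  prof <- ess_profile_gt(inst)
  cand <- tibble::tibble(
    i = rep(inst$boundary, 2L),
    direction = rep(c(">", "<="), each = length(inst$boundary)),
    ess = c(prof, -prof)
  )
  cand$cutpoint <- (inst$v[cand$i] + inst$v[cand$i + 1L]) / 2
  # accuracy on the smaller outcome class, for tie-breaking
  cases_le <- cumsum(inst$y)[cand$i]
  ctrl_le <- cand$i - cases_le
  sens <- ifelse(cand$direction == ">",
                 (inst$n_cases - cases_le) / inst$n_cases,
                 cases_le / inst$n_cases)
  spec <- ifelse(cand$direction == ">",
                 ctrl_le / inst$n_controls,
                 (inst$n_controls - ctrl_le) / inst$n_controls)
  cand$minor_acc <- if (inst$n_cases <= inst$n_controls) sens else spec
  ord <- order(-cand$ess, -cand$minor_acc, cand$cutpoint,
               match(cand$direction, c("<=", ">")))
  best <- cand[ord[1L], ]

  i <- best$i
  cases_le_b <- cumsum(inst$y)[i]
  ctrl_le_b <- i - cases_le_b
  if (best$direction == ">") {
    counts <- counts_2x2(a = inst$n_cases - cases_le_b,
                         b = inst$n_controls - ctrl_le_b,
                         c = cases_le_b, d = ctrl_le_b)
  } else {
    counts <- counts_2x2(a = cases_le_b, b = ctrl_le_b,
                         c = inst$n_cases - cases_le_b,
                         d = inst$n_controls - ctrl_le_b)
  }
  metrics <- metrics_from_counts(counts)
  structure(
    list(attribute = attribute, direction = best$direction,
         cutpoint = best$cutpoint, counts = counts, metrics = metrics,
         ess = metrics$ess, n_used = inst$n, n_missing = inst$n_missing,
         p_value = NULL, p_method = NULL, n_permutations = NULL,
         seed = NULL),
    class = "odacta_cutpoint")
}

#' @export
print.odacta_cutpoint <- function(x, ...) {
  cat(sprintf("Optimal discriminant cutpoint for '%s'\n", x$attribute))
  cat(sprintf("  effect-positive side: %s %g\n", x$direction, x$cutpoint))
  cat(sprintf("  ESS %.1f%% (sens %.1f%%, spec %.1f%%), n = %d (%d missing)\n",
              x$ess, x$metrics$sensitivity, x$metrics$specificity,
              x$n_used, x$n_missing))
  if (!is.null(x$p_value)) {
    cat(sprintf("  permutation p = %.5g (%s, %s permutations)\n", x$p_value,
                x$p_method, format(x$n_permutations %||% NA, big.mark = ",")))
  }
  invisible(x)
}

#' @method tidy odacta_cutpoint
#' @export
tidy.odacta_cutpoint <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(attribute = x$attribute, direction = x$direction,
                   cutpoint = x$cutpoint),
    x$metrics,
    tibble::tibble(n_used = x$n_used, n_missing = x$n_missing,
                   p_value = x$p_value %||% NA_real_,
                   p_method = x$p_method %||% NA_character_)
  )
}

# ---- permutation inference --------------------------------------------------

#' Permutation p-value for an optimal cutpoint
#'
#' Significance of an ODA cutpoint by label permutation: the p-value is
#' the proportion of outcome relabellings whose maximal ESS is at least
#' the observed ESS. By default the cutpoint is re-optimised (both
#' directions, all midpoints) for every relabelling — the conservative
#' null that matches an exhaustive-search statistic. A fixed-cutpoint
#' null, which keeps the observed dichotomy and permutes labels (exact
#' via the hypergeometric distribution), is available with
#' `null = "fixed"`.
#'
#' All `choose(n, n_cases)` distinct labellings are enumerated when
#' their number is at most `exhaustive_limit`; otherwise the p-value is
#' estimated by Monte Carlo with `n_mc` random relabellings and
#' reported with the (r + 1)/(n_mc + 1) small-sample correction.
#'
#' @param result An `odacta_cutpoint` from [optimal_cutpoint()], fitted
#'   on the same `values` and `outcome`.
#' @param values,outcome The data the result was fitted on.
#' @param n_mc Number of Monte Carlo relabellings (default 25,000).
#' @param seed Integer seed for the Monte Carlo stream.
#' @param exhaustive_limit Enumerate all labellings when
#'   `choose(n, n_cases)` does not exceed this bound.
#' @param null `"max"` (re-optimised, default) or `"fixed"`.
#' @return The input `result` with `p_value`, `p_method`
#'   (`"exhaustive"`, `"monte_carlo"` or `"hypergeometric"`),
#'   `n_permutations` and `seed` filled in.
#' @export
permutation_p <- function(result, values, outcome, n_mc = 25000L,
                          seed = 1L, exhaustive_limit = 20000,
                          null = c("max", "fixed")) {
  null <- match.arg(null)
  if (!inherits(result, "odacta_cutpoint")) {
    abort_odacta("`result` must come from optimal_cutpoint().",
                 "odacta_input_error")
  }
  if (n_mc < 100L) {
    rlang::warn("n_mc < 100 gives a very coarse Monte Carlo p-value.",
                class = "odacta_config_warning")
  }
  inst <- oda_instance(values, outcome)

  if (null == "fixed") {
    result$p_value <- hypergeom_ess_p(result$counts)
    result$p_method <- "hypergeometric"
    result$n_permutations <- NA_integer_
    return(result)
  }

  obs <- result$ess
  eps <- 1e-9
  n_label <- choose(inst$n, inst$n_cases)
  if (n_label <= exhaustive_limit) {
    hits <- 0
    combos <- utils::combn(inst$n, inst$n_cases)
    for (j in seq_len(ncol(combos))) {
      y <- integer(inst$n)
      y[combos[, j]] <- 1L
      if (max_ess(inst, y) >= obs - eps) hits <- hits + 1
    }
    result$p_value <- hits / n_label
    result$p_method <- "exhaustive"
    result$n_permutations <- as.integer(n_label)
    result$seed <- NA_integer_
  } else {
    stats <- withr::with_seed(seed, mc_max_ess(inst, n_mc))
    result$p_value <- (1 + sum(stats >= obs - eps)) / (n_mc + 1)
    result$p_method <- "monte_carlo"
    result$n_permutations <- as.integer(n_mc)
    result$seed <- as.integer(seed)
  }
  result
}

# Monte Carlo max-ESS null draws, chunked so the label matrix stays small.
mc_max_ess <- function(inst, n_mc) {
  n <- inst$n
  P <- inst$n_cases
  if (length(inst$boundary) == 0L) return(numeric(n_mc))
  chunk <- max(1L, min(n_mc, as.integer(ceiling(2e6 / n))))
  out <- numeric(n_mc)
  done <- 0L
  inv_N <- 1 / inst$n_controls
  inv_P <- 1 / inst$n_cases
  while (done < n_mc) {
    b <- min(chunk, n_mc - done)
    ymat <- matrix(0, nrow = n, ncol = b)
    for (j in seq_len(b)) ymat[sample.int(n, P), j] <- 1
    cs <- apply(ymat, 2, cumsum)[inst$boundary, , drop = FALSE]
    idx <- matrix(inst$boundary, nrow = length(inst$boundary), ncol = b)
    prof <- abs((idx - cs) * inv_N - cs * inv_P)
    out[(done + 1L):(done + b)] <- 100 * apply(prof, 2, max)
    done <- done + b
  }
  out
}

# Exact tail probability of |ESS| >= observed for a fixed binary
# predictor under label permutation (hypergeometric on the case count
# in the predictor-positive margin).
hypergeom_ess_p <- function(counts) {
  a <- counts$a; b <- counts$b; c <- counts$c; d <- counts$d
  P <- a + c; N <- b + d; n1 <- a + b
  if (P == 0L || N == 0L) return(1)
  k <- max(0L, n1 - N):min(n1, P)
  ess_k <- abs(100 * (k / P - (n1 - k) / N))
  obs <- abs(100 * (a / P - b / N))
  sum(stats::dhyper(k[ess_k >= obs - 1e-9], P, N, n1))
}

#' Exact permutation p-value for a fixed binary attribute
#'
#' For a binary predictor there is no cutpoint to optimise: under label
#' permutation the case count in the predictor-positive margin is
#' hypergeometric, and the two-direction permutation p-value is the
#' exact tail probability of tables whose |ESS| reaches the observed
#' value. Equivalent to full enumeration over all labellings (a
#' two-direction Fisher-type test on ESS).
#'
#' @param counts An `odacta_counts` table.
#' @return Exact p-value in `[0, 1]`.
#' @export
#' @examples
#' binary_attribute_p(counts_2x2(5, 0, 0, 5)) # 2 / choose(10, 5)
binary_attribute_p <- function(counts) {
  if (!inherits(counts, "odacta_counts")) {
    abort_odacta("`counts` must be an odacta_counts object.",
                 "odacta_input_error")
  }
  hypergeom_ess_p(counts)
}

#' Sidak multiple-comparison criterion
#'
#' Experimentwise-adjusted per-comparison significance threshold
#' `1 - (1 - alpha)^(1/k)` for `k` comparisons.
#'
#' @param alpha Experimentwise type-I error rate, in (0, 1).
#' @param k Number of comparisons, at least 1.
#' @return The adjusted per-comparison threshold.
#' @export
#' @examples
#' sidak_criterion(0.05, 10)
sidak_criterion <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_odacta("`alpha` must be in (0, 1).", "odacta_input_error")
  }
  if (any(k < 1)) abort_odacta("`k` must be at least 1.", "odacta_input_error")
  1 - (1 - alpha)^(1 / k)
}

# ---- the screen -------------------------------------------------------------

#' Univariable optimal-discriminant screen of a predictor pool
#'
#' Runs [optimal_cutpoint()] (ordered attributes) or a direct 2x2
#' analysis with an exact hypergeometric permutation p-value (binary
#' attributes) for every predictor against a binary outcome, and
#' returns the rows ranked by descending ESS — the layout of a
#' published univariable risk-factor table. The two-direction search
#' counts as a single comparison per predictor.
#'
#' @param data A data frame with one row per subject.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor columns; defaults to
#'   every column except `outcome` and `patient_id`.
#' @param alpha Significance level (default 0.05).
#' @param mode `"generalized"` keeps predictors with per-comparison
#'   p <= alpha; `"experimentwise"` applies the Sidak criterion over
#'   the `k` screened predictors.
#' @param filter Drop non-significant rows (default `TRUE`, matching
#'   published screens that exclude p >= 0.05)?
#' @param n_mc,exhaustive_limit,null Passed to [permutation_p()] for
#'   ordered predictors.
#' @param seed Master seed; each predictor's Monte Carlo stream is
#'   derived from it.
#' @return A tibble of class `odacta_screen`, one row per (significant)
#'   predictor with columns `predictor`, `type`, `direction`,
#'   `cutpoint`, the 2x2 counts, all effect metrics, `p_value`,
#'   `p_method`, `n_used`, `n_missing`, `significant`. The Sidak or
#'   per-comparison threshold is in `attr(, "threshold")`.
#' @export
univariable_screen <- function(data, outcome = "outcome", predictors = NULL,
                               alpha = 0.05,
                               mode = c("generalized", "experimentwise"),
                               filter = TRUE, n_mc = 25000L, seed = 1L,
                               exhaustive_limit = 20000,
                               null = c("max", "fixed")) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  predictors <- predictors %||%
    setdiff(names(data), c(outcome, "patient_id"))
  if (length(predictors) < 1L) {
    abort_odacta("No predictors to screen.", "odacta_input_error")
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)

  rows <- purrr::imap(
    stats::setNames(predictors, predictors),
    function(p, nm) {
      x <- data[[p]]
      if (is.logical(x)) x <- as.integer(x)
      i <- match(p, predictors)
      if (is_binary_col(x)) {
        screen_binary_row(x, y, nm)
      } else {
        screen_ordered_row(x, y, nm, n_mc = n_mc,
                           seed = seed + i, exhaustive_limit = exhaustive_limit,
                           null = null)
      }
    })
  res <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(res) == 0L) {
    abort_odacta("No predictor admitted a model (constant attributes or single-class outcome).",
                 "odacta_no_model")
  }
  k <- length(predictors)
  threshold <- if (mode == "experimentwise") sidak_criterion(alpha, k) else alpha
  res$significant <- res$p_value <= threshold
  res <- dplyr::arrange(res, dplyr::desc(.data$ess))
  if (filter) res <- dplyr::filter(res, .data$significant)
  structure(res, class = c("odacta_screen", class(res)),
            alpha = alpha, mode = mode, threshold = threshold,
            k = k, outcome = outcome)
}

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}

screen_binary_row <- function(x, y, nm) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NULL)
  counts <- counts_2x2(a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0),
                       c = sum(x == 0 & y == 1), d = sum(x == 0 & y == 0))
  m <- metrics_from_counts(counts)
  direction <- "yes"
  if (m$ess < 0) { # risk sits on the predictor-negative side
    counts <- counts_2x2(counts$c, counts$d, counts$a, counts$b)
    m <- metrics_from_counts(counts)
    direction <- "no"
  }
  dplyr::bind_cols(
    tibble::tibble(predictor = nm, type = "binary", direction = direction,
                   cutpoint = NA_real_),
    m,
    tibble::tibble(p_value = binary_attribute_p(counts),
                   p_method = "hypergeometric",
                   n_permutations = NA_integer_,
                   n_used = length(x), n_missing = sum(!ok))
  )
}

screen_ordered_row <- function(x, y, nm, n_mc, seed, exhaustive_limit, null) {
  cp <- optimal_cutpoint(x, y, attribute = nm)
  if (is.null(cp)) return(NULL)
  cp <- permutation_p(cp, x, y, n_mc = n_mc, seed = seed,
                      exhaustive_limit = exhaustive_limit, null = null)
  dplyr::bind_cols(
    tibble::tibble(predictor = nm, type = "ordered",
                   direction = cp$direction, cutpoint = cp$cutpoint),
    cp$metrics,
    tibble::tibble(p_value = cp$p_value, p_method = cp$p_method,
                   n_permutations = cp$n_permutations,
                   n_used = cp$n_used, n_missing = cp$n_missing)
  )
}

#' Plot a univariable screen as a ranked ESS bar chart
#'
#' @param object An `odacta_screen` from [univariable_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odacta_screen
#' @export
autoplot.odacta_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$cutpoint), df$predictor,
                     sprintf("%s %s %g", df$predictor, df$direction,
                             df$cutpoint))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$ess),
                                   y = .data$ess)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ESS (%)",
                  title = "Univariable optimal-discriminant screen") +
    ggplot2::theme_minimal()
}
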
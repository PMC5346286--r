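# Hierarchically optimal classification tree analysis: chained ODA
# splits, a minimum-endpoint-size constraint, endpoint classes chosen to
# maximise overall model ESS, and a bounded exhaustive search that is
# guaranteed optimal within its enumerated family.

#' Fit a classification tree by chained optimal discriminant analysis
#'
#' Builds a binary classification tree for a 0/1 outcome by chaining
#' ODA cutpoint analyses over the strata defined by earlier splits.
#' Every candidate split is the ODA-optimal cutpoint of one predictor
#' for the subjects reaching that node (binary predictors split on
#' yes/no), must leave at least `min_leaf_frac` of the root sample on
#' each side, and must pass the Sidak-adjusted permutation criterion
#' over the node's testable predictor pool (the predictors that admit
#' a size-feasible split at that node — a predictor that is constant
#' within a stratum poses no hypothesis there). Terminal endpoints are
#' assigned the
#' predicted class that maximises the overall model ESS (see
#' [assign_endpoint_classes()]).
#'
#' `mode = "greedy"` recursively takes the significant feasible split
#' with the highest node-level ESS. `mode = "exhaustive"` maximises the
#' overall model ESS over *all* trees whose splits are drawn from the
#' per-node ODA-optimal candidates, by dynamic programming over the
#' node partition — optimal within that enumerated family (it never
#' claims optimality over cutpoints that are not per-node ODA optima).
#' Ties between equal-ESS trees go to fewer endpoints, then shallower
#' depth, then earlier predictor order. The exhaustive search aborts
#' with a capacity error if it would evaluate more than `max_eval`
#' candidate nodes; it never falls back silently.
#'
#' Subjects with a missing split value are routed to the
#' condition-false side.
#'
#' @param data Data frame, one row per subject.
#' @param outcome Name of the 0/1 outcome column.
#' @param predictors Character vector of candidate predictor columns.
#' @param alpha Experimentwise significance level for split gating.
#' @param min_leaf_frac Minimum terminal-endpoint size as a fraction of
#'   the root sample (default 0.10).
#' @param max_depth Maximum number of splits along any path (default 4).
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param n_mc,exhaustive_limit Permutation settings for split p-values
#'   (see [permutation_p()]).
#' @param seed Master seed for Monte Carlo p-values.
#' @param max_eval Candidate-node budget for the exhaustive search.
#' @return An object of class `odacta_cta`; see [tidy.odacta_cta()],
#'   [glance.odacta_cta()], [predict.odacta_cta()],
#'   [validate_holdout()].
#' @export
fit_cta <- function(data, outcome = "outcome", predictors,
                    alpha = 0.05, min_leaf_frac = 0.10, max_depth = 4L,
                    mode = c("greedy", "exhaustive"), n_mc = 999L,
                    exhaustive_limit = 5000, seed = 1L, max_eval = 10000L) {
  mode <- match.arg(mode)
  if (length(predictors) < 1L) {
    abort_odacta("At least one predictor is required.", "odacta_input_error")
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (any(is.na(y))) {
    abort_odacta("The outcome may not contain missing values.",
                 "odacta_input_error")
  }
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  if (P == 0L || N == 0L) {
    abort_odacta("Both outcome classes must be present.", "odacta_input_error")
  }
  n_root <- length(y)
  min_n <- as.integer(ceiling(min_leaf_frac * n_root))
  threshold <- sidak_criterion(alpha, length(predictors))

  ctx <- list(data = data, y = y, P = P, N = N, n_root = n_root,
              min_n = min_n, alpha = alpha, predictors = predictors,
              n_mc = n_mc, exhaustive_limit = exhaustive_limit, seed = seed,
              max_depth = as.integer(max_depth))
  counter <- new.env(parent = emptyenv())
  counter$eval <- 0L
  counter$max_eval <- as.integer(max_eval)

  root <- if (mode == "greedy") {
    grow_greedy(seq_len(n_root), 0L, ctx)
  } else {
    best_subtree(seq_len(n_root), 0L, max_depth, ctx, counter)$tree
  }

  model <- structure(
    list(root = root, outcome = outcome, predictors = predictors,
         alpha = alpha, min_leaf_frac = min_leaf_frac,
         max_depth = as.integer(max_depth), mode = mode,
         n = n_root, n_cases = P, n_controls = N,
         seed = as.integer(seed), threshold = threshold,
         training = data),
    class = "odacta_cta")
  model <- assign_endpoint_classes(model, data)
  model
}

# depth counts splits along the path; greedy recursion.
grow_greedy <- function(idx, depth, ctx) {
  node <- new_node(idx, depth, ctx)
  if (depth >= ctx$max_depth) return(node)
  cands <- significant_candidates(idx, ctx)
  if (length(cands) == 0L) return(node)
  ess_node <- vapply(cands, function(cc) cc$ess_node, numeric(1))
  best <- cands[[order(-ess_node, vapply(cands, function(cc)
    match(cc$predictor, ctx$predictors), numeric(1)))[1L]]]
  node$split <- best[c("predictor", "type", "direction", "cutpoint",
                       "p_value", "p_method", "ess_node")]
  cond <- split_condition(ctx$data[idx, , drop = FALSE], node$split)
  node$children <- list(
    no = grow_greedy(idx[!cond], depth + 1L, ctx),
    yes = grow_greedy(idx[cond], depth + 1L, ctx))
  node
}

new_node <- function(idx, depth, ctx) {
  yc <- ctx$y[idx]
  list(n = length(idx), n_cases = sum(yc == 1L),
       rate = mean(yc == 1L), depth = depth,
       split = NULL, children = NULL, idx = idx)
}

# All size-feasible ODA-optimal splits at a node, with their
# permutation p-values; significance gating happens in
# significant_candidates() with k = the number of feasible candidates.
node_candidates <- function(idx, ctx) {
  yc <- ctx$y[idx]
  if (sum(yc == 1L) == 0L || sum(yc == 0L) == 0L) return(list())
  out <- list()
  for (p in ctx$predictors) {
    x <- ctx$data[[p]][idx]
    if (is.logical(x)) x <- as.integer(x)
    cand <- if (is_binary_col(x)) {
      candidate_binary(x, yc, p, ctx)
    } else {
      candidate_ordered(x, yc, p, ctx, idx)
    }
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

candidate_binary <- function(x, yc, p, ctx) {
  n1 <- sum(x == 1, na.rm = TRUE)
  n0 <- length(x) - n1 # NAs route to the condition-false side
  if (n1 < ctx$min_n || n0 < ctx$min_n) return(NULL)
  pos <- !is.na(x) & x == 1
  counts <- counts_2x2(a = sum(pos & yc == 1L), b = sum(pos & yc == 0L),
                       c = sum(!pos & yc == 1L), d = sum(!pos & yc == 0L))
  m <- metrics_from_counts(counts)
  pv <- binary_attribute_p(counts)
  list(predictor = p, type = "binary",
       direction = if (m$ess >= 0) "yes" else "no", cutpoint = NA_real_,
       p_value = pv, p_method = "hypergeometric", ess_node = abs(m$ess))
}

candidate_ordered <- function(x, yc, p, ctx, idx) {
  # the minimum-size constraint counts every subject at the node;
  # missing x go to the condition-false side, so the search over
  # non-missing boundaries uses min_n reduced by the missing count on
  # the false side.
  n_miss <- sum(is.na(x))
  cp <- optimal_cutpoint(x, yc, attribute = p,
                         min_size = max(1L, ctx$min_n - n_miss))
  if (is.null(cp)) return(NULL)
  cond <- !is.na(x) & x > cp$cutpoint
  if (sum(cond) < ctx$min_n || sum(!cond) < ctx$min_n) return(NULL)
  # seed depends only on (master seed, predictor) so that a fit is
  # reproducible and auditable by an external enumerator
  cp <- permutation_p(cp, x, yc, n_mc = ctx$n_mc,
                      seed = ctx$seed + match(p, ctx$predictors),
                      exhaustive_limit = ctx$exhaustive_limit)
  list(predictor = p, type = "ordered", direction = cp$direction,
       cutpoint = cp$cutpoint, p_value = cp$p_value, p_method = cp$p_method,
       ess_node = cp$ess)
}

# Sidak gate over the node's testable hypotheses.
significant_candidates <- function(idx, ctx) {
  cands <- node_candidates(idx, ctx)
  if (length(cands) == 0L) return(cands)
  thr <- sidak_criterion(ctx$alpha, length(cands))
  cands[vapply(cands, function(cc) cc$p_value <= thr, logical(1))]
}

# TRUE for subjects routed to the condition-true child.
split_condition <- function(rows, split) {
  x <- rows[[split$predictor]]
  if (is.logical(x)) x <- as.integer(x)
  if (split$type == "binary") {
    !is.na(x) & x == 1
  } else {
    !is.na(x) & x > split$cutpoint
  }
}

# Exhaustive search: maximise the decomposable model-ESS contribution
# sum over endpoints of max(a_i/P, b_i/N).  Returns value, endpoint
# count, max depth used, and the tree.
best_subtree <- function(idx, depth, max_depth, ctx, counter) {
  counter$eval <- counter$eval + 1L
  if (counter$eval > counter$max_eval) {
    abort_odacta(
      sprintf("Exhaustive CTA search exceeded its budget of %d candidate nodes; raise `max_eval` or reduce depth/predictors.",
              counter$max_eval),
      "odacta_capacity_error")
  }
  node <- new_node(idx, depth, ctx)
  a <- node$n_cases
  b <- node$n - a
  leaf <- list(value = max(a / ctx$P, b / ctx$N), n_end = 1L,
               depth_used = 0L, tree = node)
  if (depth >= max_depth) return(leaf)
  best <- leaf
  cands <- significant_candidates(idx, ctx)
  for (cand in cands) {
    cond <- split_condition(ctx$data[idx, , drop = FALSE], cand)
    l <- best_subtree(idx[!cond], depth + 1L, max_depth, ctx, counter)
    r <- best_subtree(idx[cond], depth + 1L, max_depth, ctx, counter)
    option <- list(value = l$value + r$value,
                   n_end = l$n_end + r$n_end,
                   depth_used = 1L + max(l$depth_used, r$depth_used))
    better <- option$value > best$value + 1e-12 ||
      (abs(option$value - best$value) <= 1e-12 &&
         (option$n_end < best$n_end ||
            (option$n_end == best$n_end &&
               option$depth_used < best$depth_used)))
    if (better) {
      tr <- node
      tr$split <- cand[c("predictor", "type", "direction", "cutpoint",
                         "p_value", "p_method", "ess_node")]
      tr$children <- list(no = l$tree, yes = r$tree)
      option$tree <- tr
      best <- option
    }
  }
  best
}

#' Assign endpoint classes that maximise overall model ESS
#'
#' With `P` total cases and `N` total non-cases, the model ESS
#' decomposes over terminal endpoints as
#' `100 * (sum_i max-or-chosen(a_i/P, b_i/N) - 1)`, so each endpoint
#' independently takes the predicted class positive exactly when
#' `a_i / P > b_i / N`; an exact tie predicts negative. Endpoint ids,
#' path predicates and the resulting model ESS are (re)computed and
#' stored on the model.
#'
#' @param model An `odacta_cta` model.
#' @param data The training data (defaults to the data the model was
#'   fitted on).
#' @return The model with `endpoints` (tibble) and `model_ess` filled.
#' @export
assign_endpoint_classes <- function(model, data = model$training) {
  P <- model$n_cases
  N <- model$n_controls
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$id <- 0L
  walk <- function(node, path) {
    if (is.null(node$split)) {
      env$id <- env$id + 1L
      a <- node$n_cases
      b <- node$n - a
      env$rows[[env$id]] <- tibble::tibble(
        endpoint = paste0("E", env$id),
        predicate = if (length(path)) paste(path, collapse = " & ") else "TRUE",
        n = node$n, cases = a, rate = node$rate,
        predicted = as.integer(a / P > b / N))
      node$endpoint <- paste0("E", env$id)
      node$endpoint_class <- as.integer(a / P > b / N)
      return(node)
    }
    lab <- split_label(node$split)
    node$children$no <- walk(node$children$no, c(path, paste0("!(", lab, ")")))
    node$children$yes <- walk(node$children$yes, c(path, lab))
    node
  }
  model$root <- walk(model$root, character())
  model$endpoints <- dplyr::bind_rows(env$rows)
  model$model_ess <- model_ess(model, data)
  model
}

split_label <- function(split) {
  if (split$type == "binary") {
    split$predictor
  } else {
    sprintf("%s > %g", split$predictor, split$cutpoint)
  }
}

#' Overall model ESS of a fitted tree on a table
#'
#' Sensitivity and specificity of the tree's predicted labels on
#' `data`, combined as ESS = sensitivity + specificity - 100.
#'
#' @param model An `odacta_cta` with endpoint classes assigned.
#' @param data Data frame with the model's predictors and outcome.
#' @return ESS in percent.
#' @export
model_ess <- function(model, data = model$training) {
  y <- data[[model$outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort_odacta("Both outcome classes are required to compute ESS.",
                 "odacta_undefined_metric")
  }
  pred <- predict(model, data)$.pred_class
  sens <- 100 * sum(pred == 1L & y == 1L) / sum(y == 1L)
  spec <- 100 * sum(pred == 0L & y == 0L) / sum(y == 0L)
  sens + spec - 100
}

#' Route subjects through a fitted tree
#'
#' @param object An `odacta_cta` model.
#' @param newdata Data frame with the model's predictor columns.
#' @param missing How to route a subject whose split value is missing:
#'   `"false_side"` (default, the condition-false child — the same
#'   half-open convention puts a value exactly at a cutpoint on the
#'   `<=` side) or `"error"`.
#' @param ... Unused.
#' @return A tibble with `.pred_class` (0/1) and `.endpoint`.
#' @export
predict.odacta_cta <- function(object, newdata,
                               missing = c("false_side", "error"), ...) {
  missing <- match.arg(missing)
  n <- nrow(newdata)
  cls <- integer(n)
  ep <- character(n)
  route <- function(node, rows_idx) {
    if (is.null(node$split)) {
      cls[rows_idx] <<- node$endpoint_class
      ep[rows_idx] <<- node$endpoint
      return(invisible())
    }
    x <- newdata[[node$split$predictor]][rows_idx]
    if (missing == "error" && anyNA(x)) {
      abort_odacta(sprintf("Missing value for split predictor '%s'.",
                           node$split$predictor),
                   "odacta_missing_predictor")
    }
    cond <- split_condition(newdata[rows_idx, , drop = FALSE], node$split)
    route(node$children$yes, rows_idx[cond])
    route(node$children$no, rows_idx[!cond])
  }
  route(object$root, seq_len(n))
  tibble::tibble(.pred_class = cls, .endpoint = ep)
}

#' Score a frozen tree on a temporal holdout sample
#'
#' Applies the fitted model, without refitting, to a holdout table and
#' returns the full 2x2 effect metrics plus holdout ESS.
#'
#' @param model An `odacta_cta`.
#' @param holdout Data frame with predictors and outcome, disjoint from
#'   the training data (an identical table triggers a warning and
#'   reproduces the training ESS).
#' @return One-row tibble of effect metrics with `ess` and `n`.
#' @export
validate_holdout <- function(model, holdout) {
  if (identical(dplyr::as_tibble(holdout), dplyr::as_tibble(model$training))) {
    rlang::warn("Holdout table is identical to the training table; metrics describe training fit.",
                class = "odacta_degenerate_holdout")
  }
  y <- holdout[[model$outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort_odacta("Holdout lacks one outcome class; metrics undefined.",
                 "odacta_undefined_metric")
  }
  pred <- predict(model, holdout)$.pred_class
  counts <- counts_2x2(a = sum(pred == 1L & y == 1L),
                       b = sum(pred == 1L & y == 0L),
                       c = sum(pred == 0L & y == 1L),
                       d = sum(pred == 0L & y == 0L))
  m <- metrics_from_counts(counts)
  dplyr::mutate(m, n = nrow(holdout))
}

# ---- presentation -----------------------------------------------------------

#' @export
print.odacta_cta <- function(x, ...) {
  cat(sprintf("Classification tree (%s search) for '%s'\n", x$mode, x$outcome))
  cat(sprintf("  n = %d (%d cases), model ESS %.1f%%, alpha %.3g (Sidak %.4g), min endpoint %d%% of n\n",
              x$n, x$n_cases, x$model_ess, x$alpha, x$threshold,
              round(100 * x$min_leaf_frac)))
  render <- function(node, prefix, label) {
    tag <- if (is.null(node$split)) {
      sprintf("%s [%s: predict %s, %d/%d = %.2f%%]",
              label, node$endpoint,
              if (node$endpoint_class == 1L) "case" else "non-case",
              node$n_cases, node$n, 100 * node$rate)
    } else {
      sprintf("%s (split %s, p = %.3g)", label, split_label(node$split),
              node$split$p_value)
    }
    cat(prefix, tag, "\n", sep = "")
    if (!is.null(node$split)) {
      render(node$children$yes, paste0(prefix, "  "),
             paste0("+ ", split_label(node$split)))
      render(node$children$no, paste0(prefix, "  "),
             paste0("- not ", split_label(node$split)))
    }
  }
  render(x$root, "  ", "root")
  invisible(x)
}

#' Per-endpoint summary of a fitted tree
#'
#' @param x An `odacta_cta` model.
#' @param ... Unused.
#' @return A tibble with one row per terminal endpoint: `endpoint`,
#'   `predicate`, `n`, `cases`, `rate`, `predicted`.
#' @method tidy odacta_cta
#' @export
tidy.odacta_cta <- function(x, ...) {
  x$endpoints
}

#' One-row model summary of a fitted tree
#'
#' @param x An `odacta_cta` model.
#' @param ... Unused.
#' @return A one-row tibble: `model_ess`, `n`, `n_cases`,
#'   `n_endpoints`, `variables`, `alpha`, `sidak_threshold`, `mode`.
#' @method glance odacta_cta
#' @export
glance.odacta_cta <- function(x, ...) {
  tibble::tibble(
    model_ess = x$model_ess, n = x$n, n_cases = x$n_cases,
    n_endpoints = nrow(x$endpoints),
    variables = paste(cta_variables(x), collapse = ";"),
    alpha = x$alpha, sidak_threshold = x$threshold, mode = x$mode)
}

#' Variables used by a fitted tree
#'
#' @param model An `odacta_cta`.
#' @return Character vector of distinct split predictors (depth-first).
#' @export
cta_variables <- function(model) {
  out <- character()
  walk <- function(node) {
    if (is.null(node$split)) return(invisible())
    out <<- c(out, node$split$predictor)
    walk(node$children$yes)
    walk(node$children$no)
  }
  walk(model$root)
  unique(out)
}

#' Serialise a fitted tree to JSON
#'
#' @param model An `odacta_cta`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
cta_to_json <- function(model, path = NULL) {
  strip <- function(node) {
    node$idx <- NULL
    if (!is.null(node$children)) {
      node$children <- lapply(node$children, strip)
    }
    node
  }
  obj <- list(outcome = model$outcome, model_ess = model$model_ess,
              alpha = model$alpha, sidak_threshold = model$threshold,
              min_leaf_frac = model$min_leaf_frac, mode = model$mode,
              n = model$n, n_cases = model$n_cases,
              endpoints = model$endpoints, tree = strip(model$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Plot a fitted tree's endpoints as an outcome-rate chart
#'
#' @param object An `odacta_cta` model.
#' @param ... Unused.
#' @return A ggplot object: endpoint event rates with the cohort rate
#'   as a reference line; endpoints predicted positive are highlighted.
#' @method autoplot odacta_cta
#' @export
autoplot.odacta_cta <- function(object, ...) {
  df <- object$endpoints
  df$predicted <- factor(ifelse(df$predicted == 1L, "case", "non-case"),
                         levels = c("non-case", "case"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$predicate, .data$rate),
                                   y = 100 * .data$rate,
                                   fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100 * object$n_cases / object$n,
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Endpoint event rate (%)",
                  fill = "Predicted",
                  title = sprintf("CTA endpoints (model ESS %.1f%%)",
                                  object$model_ess)) +
    ggplot2::theme_minimal()
}
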
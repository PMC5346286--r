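`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force oracles used to audit the package's search
# procedures, plus small fixture builders.  The oracles are written as
# plainly as possible (double loops, day-by-day scans, explicit tree
# enumeration) and share no code with the implementations they check.

# -- exhaustive cutpoint scan -------------------------------------------------
# Tries every midpoint between adjacent distinct values, both
# directions, computing ESS from the raw 2x2 each time.
oracle_cutpoint <- function(values, outcome) {
  ok <- !is.na(values) & !is.na(outcome)
  v <- values[ok]
  y <- outcome[ok]
  sv <- sort(unique(v))
  if (length(sv) < 2L || length(unique(y)) < 2L) return(NULL)
  cuts <- (sv[-1] + sv[-length(sv)]) / 2
  best <- NULL
  for (cut in cuts) {
    for (dir in c(">", "<=")) {
      pos <- if (dir == ">") v > cut else v <= cut
      a <- sum(pos & y == 1); b <- sum(pos & y == 0)
      c_ <- sum(!pos & y == 1); d <- sum(!pos & y == 0)
      ess <- 100 * (a / (a + c_) + d / (b + d) - 100 / 100) - 0 # sens+spec-1
      ess <- 100 * (a / (a + c_)) + 100 * (d / (b + d)) - 100
      if (is.null(best) || ess > best$ess + 1e-12) {
        best <- list(ess = ess, cut = cut, dir = dir)
      }
    }
  }
  best
}

# -- day-by-day exposure scan -------------------------------------------------
# Marks each covered calendar day in a logical vector and counts the
# marked days inside [first start, truncation).
oracle_covered_days <- function(starts, supplies, truncate_at = NULL) {
  first <- min(starts)
  last <- max(starts + supplies)
  days <- rep(FALSE, last - first)
  for (i in seq_along(starts)) {
    span <- seq.int(starts[i], starts[i] + supplies[i] - 1L)
    days[span - first + 1L] <- TRUE
  }
  if (!is.null(truncate_at)) {
    cut <- truncate_at - first
    if (cut < length(days)) days[seq_along(days) > cut] <- FALSE
  }
  sum(days)
}

# -- explicit classification-tree enumeration ---------------------------------
# Enumerates every tree up to `max_depth` whose splits are the per-node
# ODA-optimal cutpoints (per predictor) that satisfy the size and
# significance constraints, scoring each complete tree by explicitly
# routing subjects and computing sens + spec - 100 with the best
# per-endpoint class assignment.  Returns the maximal model ESS.
oracle_best_tree_ess <- function(data, outcome, predictors, alpha,
                                 min_n, max_depth, n_mc = 199, seed = 1) {
  y <- data[[outcome]]
  P <- sum(y == 1)
  N <- sum(y == 0)

  node_cands <- function(idx) {
    # collect every size-feasible candidate with its p-value, then gate
    # at the Sidak criterion over the candidates actually testable here
    out <- list()
    for (p in predictors) {
      x <- data[[p]][idx]
      yy <- y[idx]
      if (length(unique(yy)) < 2L) next
      u <- unique(x[!is.na(x)])
      if (length(u) <= 2L && all(u %in% c(0, 1))) {
        pos <- !is.na(x) & x == 1
        if (sum(pos) < min_n || sum(!pos) < min_n) next
        pv <- binary_attribute_p(counts_2x2(sum(pos & yy == 1),
                                            sum(pos & yy == 0),
                                            sum(!pos & yy == 1),
                                            sum(!pos & yy == 0)))
        out[[length(out) + 1L]] <- list(pred = p, cond = pos, p = pv)
      } else {
        cp <- optimal_cutpoint(x, yy, min_size = min_n)
        if (is.null(cp)) next
        pos <- !is.na(x) & x > cp$cutpoint
        if (sum(pos) < min_n || sum(!pos) < min_n) next
        cp <- permutation_p(cp, x, yy, n_mc = n_mc,
                            seed = seed + match(p, predictors),
                            exhaustive_limit = 500)
        out[[length(out) + 1L]] <- list(pred = p, cond = pos,
                                        p = cp$p_value)
      }
    }
    if (length(out) == 0L) return(out)
    thr <- 1 - (1 - alpha)^(1 / length(out))
    out[vapply(out, function(cc) cc$p <= thr, logical(1))]
  }

  # value of an endpoint under the optimal class assignment
  leaf_value <- function(idx) {
    a <- sum(y[idx] == 1)
    b <- length(idx) - a
    max(a / P, b / N)
  }
  enumerate <- function(idx, depth) {
    vals <- leaf_value(idx)
    if (depth >= max_depth) return(vals)
    for (cand in node_cands(idx)) {
      vals <- c(vals, enumerate(idx[cand$cond], depth + 1L) +
                  enumerate(idx[!cand$cond], depth + 1L))
    }
    max(vals)
  }
  100 * (enumerate(seq_len(nrow(data)), 0L) - 1)
}

# -- toy EMR bundle -----------------------------------------------------------
# A hand-built bundle with fully controlled chronology.  Day numbers
# are offsets from `origin`.
toy_day <- function(d, origin = as.Date("2005-01-01")) origin + d

toy_bundle <- function(patients = NULL, prescriptions = NULL,
                       diagnoses = NULL, encounters = NULL) {
  origin <- as.Date("2005-01-01")
  emr_bundle(
    patients = patients %||% tibble::tibble(
      patient_id = "p1", sex = "M", birth_date = as.Date("1970-01-01")),
    prescriptions = prescriptions %||% tibble::tibble(
      patient_id = character(), drug = character(), class = character(),
      daily_dose_mg = numeric(), start_date = as.Date(character()),
      days_supply = integer()),
    diagnoses = diagnoses %||% tibble::tibble(
      patient_id = character(), code = character(),
      date = as.Date(character())),
    encounters = encounters %||% tibble::tibble(
      patient_id = character(), date = as.Date(character())))
}

# one exposed patient with configurable events, for case-definition tests
toy_exposed_patient <- function(id = "p1",
                                birth = as.Date("1960-01-01"),
                                exposure_day = 100, supply = 30,
                                n_scripts = 12,
                                ed_day = NA, pde5i_day = NA,
                                ll_day = NA, resolution_day = NA,
                                extra_ed_days = integer(),
                                prior_ed_day = NA, prior_pde5i_day = NA,
                                enc_days = c(0, 50, 700)) {
  origin <- as.Date("2005-01-01")
  d <- function(x) origin + x
  rx <- tibble::tibble(
    patient_id = id, drug = "finasteride", class = "5ari",
    daily_dose_mg = 1,
    start_date = d(exposure_day + supply * (seq_len(n_scripts) - 1L)),
    days_supply = as.integer(supply))
  dx <- tibble::tibble(patient_id = character(), code = character(),
                       date = as.Date(character()))
  add_dx <- function(dx, code, day) {
    dplyr::bind_rows(dx, tibble::tibble(patient_id = id, code = code,
                                        date = d(day)))
  }
  if (!is.na(ed_day)) dx <- add_dx(dx, "607.84", ed_day)
  for (day in extra_ed_days) dx <- add_dx(dx, "607.84", day)
  if (!is.na(ll_day)) dx <- add_dx(dx, "799.81", ll_day)
  if (!is.na(resolution_day)) dx <- add_dx(dx, "607.84R", resolution_day)
  if (!is.na(prior_ed_day)) dx <- add_dx(dx, "607.84", prior_ed_day)
  dx <- add_dx(dx, "V70.0", enc_days[1])
  rx2 <- rx
  if (!is.na(pde5i_day)) {
    rx2 <- dplyr::bind_rows(rx2, tibble::tibble(
      patient_id = id, drug = "sildenafil", class = "pde5i",
      daily_dose_mg = 50, start_date = d(pde5i_day), days_supply = 30L))
  }
  if (!is.na(prior_pde5i_day)) {
    rx2 <- dplyr::bind_rows(rx2, tibble::tibble(
      patient_id = id, drug = "sildenafil", class = "pde5i",
      daily_dose_mg = 50, start_date = d(prior_pde5i_day),
      days_supply = 30L))
  }
  all_days <- sort(unique(c(enc_days, ed_day, ll_day, resolution_day,
                            extra_ed_days)))
  all_days <- all_days[!is.na(all_days)]
  toy_bundle(
    patients = tibble::tibble(patient_id = id, sex = "M",
                              birth_date = birth),
    prescriptions = rx2,
    diagnoses = dx,
    encounters = tibble::tibble(patient_id = id, date = d(all_days)))
}

# small cohort with a planted two-leaf duration effect, reused across
# screen / tree tests
make_screen_cohort <- function(n = 600, seed = 42, cut = 200,
                               risk_low = 0.03, risk_high = 0.25) {
  withr::with_seed(seed, {
    duration <- round(stats::rlnorm(n, log(180), 0.8))
    nsaid <- stats::rbinom(n, 1, 0.4)
    age <- round(stats::runif(n, 25, 80), 1)
    risk <- ifelse(duration > cut, risk_high, risk_low)
    tibble::tibble(
      patient_id = sprintf("s%04d", seq_len(n)),
      outcome = stats::rbinom(n, 1, risk),
      exposure_days = duration, nsaid = nsaid, age = age,
      noise = stats::rnorm(n))
  })
}
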
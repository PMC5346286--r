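# Synthetic EMR cohort generator.  Emulates the statistical structure
# the downstream analysis assumes: a large male cohort with
# comorbidity/co-medication prevalences differing by
# 5-alpha-reductase-inhibitor (5a-RI) exposure, prescription episodes
# carried as (start, days-of-supply) pairs with deliberate overlaps,
# gaps and exact duplicates, and — via plant_outcome() — adverse-event
# risk driven by a planted threshold tree so that parameter recovery
# can be scored against known ground truth.

BASELINE_PREVALENCES <- tibble::tribble(
  ~attribute,          ~kind,   ~unexposed, ~exposed,
  "nsaid",             "drug",  0.268, 0.558,
  "hypertension",      "dx",    0.175, 0.397,
  "smoking",           "dx",    0.166, 0.324,
  "vascular_disease",  "dx",    0.132, 0.322,
  "diuretic",          "drug",  0.090, 0.269,
  "diabetes",          "dx",    0.067, 0.134,
  "ssri",              "drug",  0.053, 0.150,
  "depression",        "dx",    0.051, 0.120,
  "alcoholism",        "dx",    0.046, 0.031,
  "obesity",           "dx",    0.045, 0.086,
  "prostate_disease",  "dx",    0.037, 0.363,
  "prostate_cancer",   "dx",    0.027, 0.066,
  "cyclovir",          "drug",  0.026, 0.084,
  "prostate_surgery",  "dx",    0.019, 0.119,
  "hsv",               "dx",    0.010, 0.031,
  "alopecia",          "dx",    0.004, 0.205,
  "peyronie",          "dx",    0.001, 0.006,
  "androgen",          "drug",  0.004, 0.015,
  "antiandrogen",      "drug",  0.002, 0.012
)

#' Specification of a synthetic EMR cohort
#'
#' Collects every tunable of the generator with defaults that emulate
#' the published baseline characteristics of a 5a-RI pharmacovigilance
#' cohort: per-stratum comorbidity and co-medication prevalences,
#' log-normal age distributions fitted to the printed per-stratum
#' median/IQR, a log-normal total-exposure-duration model, the
#' finasteride-dose / dutasteride mix, and the prescription-episode
#' process (days of supply, overlap, gap and exact-duplicate
#' probabilities) whose interval union defines exposure duration.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param exposure_fraction Probability of 5a-RI exposure (cohort
#'   default 0.025; set to 1 for exposed-only analysis cohorts).
#' @param prevalences Tibble `attribute`, `kind` (`"dx"`/`"drug"`),
#'   `unexposed`, `exposed` probabilities.
#' @param age_model Per-stratum `c(median, q1, q3)` in years; ages are
#'   drawn log-normal truncated to `[16, 89]` (the cohort's selection
#'   range), with positive skew matching the printed IQRs.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of the
#'   target total covered exposure (days).
#' @param dose_mix Probabilities of low-dose finasteride (<= 1.25
#'   mg/day), high-dose finasteride, and dutasteride exposure.
#' @param days_supply Days of supply per prescription.
#' @param p_overlap,p_gap,gap_mean,p_duplicate Episode process: chance
#'   the next script overlaps the previous by 10 days, chance of an
#'   exponential gap of mean `gap_mean` days, chance a script is
#'   duplicated exactly (duplicates must be ignored downstream).
#' @param prior_dysfunction_frac Fraction of exposed subjects given an
#'   ED code and PDE5-inhibitor prescription *before* first exposure
#'   (they must fall to the no-prior-dysfunction filter).
#' @param encounter_rate Mean number of clinical encounters per subject
#'   by stratum.
#' @param ineligible_frac Small fraction of subjects generated outside
#'   the eligibility surface (wrong sex or age) to exercise filters.
#' @param study_start,study_end Study window (half-open).
#' @param seed Default seed used when [generate_cohort()] is called
#'   without one.
#' @return A validated list of class `odacta_synth_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10000L,
                           exposure_fraction = 0.025,
                           prevalences = BASELINE_PREVALENCES,
                           age_model = list(
                             unexposed = c(median = 38.9, q1 = 28.7, q3 = 53.6),
                             exposed = c(median = 51.0, q1 = 30.8, q3 = 66.3)),
                           duration_meanlog = log(150),
                           duration_sdlog = 1.5,
                           dose_mix = c(low_finasteride = 0.42,
                                        high_finasteride = 0.43,
                                        dutasteride = 0.15),
                           days_supply = 90L,
                           p_overlap = 0.15, p_gap = 0.15, gap_mean = 30,
                           p_duplicate = 0.05,
                           prior_dysfunction_frac = 0.105,
                           encounter_rate = c(unexposed = 5, exposed = 10),
                           ineligible_frac = 0.02,
                           study_start = as.Date("1992-01-01"),
                           study_end = as.Date("2015-09-30"),
                           seed = 1L) {
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         exposure_fraction = exposure_fraction,
         prevalences = tibble::as_tibble(prevalences),
         age_model = age_model,
         duration_meanlog = duration_meanlog,
         duration_sdlog = duration_sdlog,
         dose_mix = dose_mix, days_supply = as.integer(days_supply),
         p_overlap = p_overlap, p_gap = p_gap, gap_mean = gap_mean,
         p_duplicate = p_duplicate,
         prior_dysfunction_frac = prior_dysfunction_frac,
         encounter_rate = encounter_rate,
         ineligible_frac = ineligible_frac,
         study_start = as.Date(study_start), study_end = as.Date(study_end),
         seed = as.integer(seed)),
    class = "odacta_synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  probs <- c(spec$exposure_fraction, spec$prevalences$unexposed,
             spec$prevalences$exposed, spec$dose_mix, spec$p_overlap,
             spec$p_gap, spec$p_duplicate, spec$prior_dysfunction_frac,
             spec$ineligible_frac)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_odacta("All probabilities in the spec must lie in [0, 1].",
                 "odacta_config_error")
  }
  if (spec$n_subjects < 1L) {
    abort_odacta("n_subjects must be at least 1.", "odacta_config_error")
  }
  if (spec$study_start >= spec$study_end) {
    abort_odacta("Study window start must precede its end.",
                 "odacta_config_error")
  }
  if (abs(sum(spec$dose_mix) - 1) > 1e-8) {
    abort_odacta("dose_mix probabilities must sum to 1.",
                 "odacta_config_error")
  }
  invisible(spec)
}

#' Default generator specification
#'
#' The [synthetic_spec()] defaults as an explicit object; prevalences
#' match the emulated cohort's published per-stratum values to three
#' decimals (e.g. prescription NSAID 0.268 unexposed / 0.558 exposed).
#'
#' @return An `odacta_synth_spec`.
#' @export
default_spec <- function() synthetic_spec()

# log-normal parameters from a printed (median, q1, q3)
lnorm_from_quartiles <- function(q) {
  c(meanlog = log(q[["median"]]),
    sdlog = log(q[["q3"]] / q[["q1"]]) / (2 * stats::qnorm(0.75)))
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a synthetic EMR cohort
#'
#' Draws `spec$n_subjects` patients and writes their demographics,
#' encounters, comorbidity diagnosis codes, co-medication
#' prescriptions, and — for exposed subjects — 5a-RI prescription
#' episodes into a four-table [emr_bundle()]. Output is fully
#' determined by `(spec, seed)`. Outcome events are *not* generated
#' here; see [plant_outcome()].
#'
#' Exposure episodes deliberately contain overlapping supplies, gaps
#' and exact duplicate prescriptions so that downstream interval-union
#' logic is exercised. Exposed subjects start their first script no
#' earlier than 1998 (the PDE5-inhibitor era, during which the ED
#' trigger-tool definition can fire) and at least three years before
#' the study end so persistence is observable.
#'
#' @param spec An `odacta_synth_spec`.
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return An `odacta_emr` bundle. Each exposed subject carries at
#'   least one 5a-RI script inside the study window.
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = spec$seed) {
  validate_synth_spec(spec)
  withr::with_seed(seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_subjects
  id <- sprintf("P%06d", seq_len(n))
  exposed <- stats::runif(n) < spec$exposure_fraction
  stratum <- ifelse(exposed, "exposed", "unexposed")

  ages <- numeric(n)
  for (s in c("unexposed", "exposed")) {
    i <- stratum == s
    if (!any(i)) next
    lp <- lnorm_from_quartiles(spec$age_model[[s]])
    ages[i] <- rlnorm_trunc(sum(i), lp[["meanlog"]], lp[["sdlog"]], 16, 89)
  }
  sex <- rep("M", n)
  bad <- stats::runif(n) < spec$ineligible_frac
  if (any(bad)) {
    flip_sex <- bad & stats::runif(n) < 0.5
    sex[flip_sex] <- "F"
    ages[bad & !flip_sex] <- sample(c(12, 14, 93, 97),
                                    sum(bad & !flip_sex), replace = TRUE)
  }

  window_days <- days_between(spec$study_start, spec$study_end)
  entry <- spec$study_start + floor(stats::runif(n, 0, window_days * 0.8))
  followup <- pmin(
    round(stats::rlnorm(n, log(ifelse(exposed, 7.1, 0.9) * 365.25), 0.9)) + 30,
    days_between(entry, spec$study_end))
  last_seen <- entry + followup
  birth_date <- entry - round(ages * 365.25)

  patients <- tibble::tibble(patient_id = id, sex = sex,
                             birth_date = birth_date)

  # encounters: >= 1 per subject, uniform over follow-up
  n_enc <- 1L + stats::rpois(n, ifelse(exposed,
                                       spec$encounter_rate[["exposed"]] - 1,
                                       spec$encounter_rate[["unexposed"]] - 1))
  enc_pat <- rep(id, n_enc)
  enc_off <- stats::runif(sum(n_enc)) * rep(followup, n_enc)
  encounters <- tibble::tibble(patient_id = enc_pat,
                               date = rep(entry, n_enc) + floor(enc_off))

  # comorbidity diagnosis codes and co-medication prescriptions
  dict <- default_code_sets()
  dx_rows <- list()
  rx_rows <- list()
  drug_for_class <- purrr::map_chr(dict$drugs, "class")
  for (j in seq_len(nrow(spec$prevalences))) {
    at <- spec$prevalences$attribute[j]
    p <- ifelse(exposed, spec$prevalences$exposed[j],
                spec$prevalences$unexposed[j])
    has <- stats::runif(n) < p
    if (!any(has)) next
    when <- entry[has] + floor(stats::runif(sum(has)) * pmax(followup[has], 1))
    if (spec$prevalences$kind[j] == "dx") {
      dx_rows[[at]] <- tibble::tibble(patient_id = id[has],
                                      code = dict$diagnoses[[at]][[1]],
                                      date = when)
    } else {
      drug <- names(drug_for_class)[match(at, drug_for_class)]
      appr <- dict$drugs[[drug]]$approval
      rx_rows[[at]] <- tibble::tibble(
        patient_id = id[has], drug = drug, class = at,
        daily_dose_mg = 1, start_date = pmax(when, appr),
        days_supply = spec$days_supply)
    }
  }
  # a generic wellness code so every subject has >= 1 diagnosis
  dx_rows[["wellness"]] <- tibble::tibble(
    patient_id = id, code = dict$diagnoses$wellness[[1]], date = entry)

  # 5a-RI exposure episodes; each dispensing implies a clinical
  # encounter, and a follow-up visit occurs after the last supply ends,
  # so the record keeps covering the exposure period.
  rx_rows[["5ari"]] <- generate_exposure_scripts(
    spec, id[exposed], entry[exposed], dict)
  if (nrow(rx_rows[["5ari"]])) {
    ari <- rx_rows[["5ari"]]
    fup <- dplyr::summarise(
      dplyr::group_by(ari, .data$patient_id),
      date = max(.data$start_date + .data$days_supply) + 30L,
      .groups = "drop")
    encounters <- dplyr::bind_rows(
      encounters,
      tibble::tibble(patient_id = ari$patient_id, date = ari$start_date),
      dplyr::mutate(fup, date = pmin(.data$date, spec$study_end - 1L)))
  }

  # pre-exposure sexual-dysfunction history for a fraction of exposed
  prior <- exposed & stats::runif(n) < spec$prior_dysfunction_frac
  if (any(prior)) {
    first_rx <- dplyr::summarise(
      dplyr::group_by(rx_rows[["5ari"]], .data$patient_id),
      first = min(.data$start_date), .groups = "drop")
    pr <- first_rx[first_rx$patient_id %in% id[prior], ]
    dx_rows[["prior_ed"]] <- tibble::tibble(
      patient_id = pr$patient_id, code = dict$diagnoses$ed[[1]],
      date = pr$first - 400L)
    rx_rows[["prior_pde5i"]] <- tibble::tibble(
      patient_id = pr$patient_id, drug = "sildenafil", class = "pde5i",
      daily_dose_mg = 50,
      start_date = pmax(pr$first - 380L, dict$drugs$sildenafil$approval),
      days_supply = 30L)
  }

  bundle <- emr_bundle(
    patients = patients,
    prescriptions = dplyr::arrange(dplyr::bind_rows(rx_rows),
                                   .data$patient_id, .data$start_date),
    diagnoses = dplyr::arrange(dplyr::bind_rows(dx_rows),
                               .data$patient_id, .data$date),
    encounters = dplyr::arrange(encounters, .data$patient_id, .data$date))
  attr(bundle, "stratum") <- tibble::tibble(patient_id = id,
                                            exposed = exposed,
                                            entry = entry,
                                            last_seen = last_seen)
  bundle
}

# Prescription episodes for exposed subjects: a target covered duration
# is drawn log-normal, then filled with fixed-length supplies whose
# starts may overlap, leave gaps, or be duplicated exactly.
generate_exposure_scripts <- function(spec, ids, entries, dict) {
  if (length(ids) == 0L) {
    return(tibble::tibble(patient_id = character(), drug = character(),
                          class = character(), daily_dose_mg = numeric(),
                          start_date = as.Date(character()),
                          days_supply = integer()))
  }
  n <- length(ids)
  dose_class <- sample(names(spec$dose_mix), n, replace = TRUE,
                       prob = spec$dose_mix)
  drug <- ifelse(dose_class == "dutasteride", "dutasteride", "finasteride")
  dose <- c(low_finasteride = 1, high_finasteride = 5, dutasteride = 0.5)[dose_class]
  era_start <- max(dict$drugs$sildenafil$approval, spec$study_start)
  latest_first <- spec$study_end - 3L * 365L
  appr <- as.Date(purrr::map_chr(dict$drugs[drug], ~ as.character(.x$approval)))
  lo <- pmax(entries, era_start, appr)
  lo <- pmin(lo, latest_first - 1L)
  first <- lo + floor(stats::runif(n) * pmax(days_between(lo, latest_first), 1))
  target <- pmin(round(stats::rlnorm(n, spec$duration_meanlog,
                                     spec$duration_sdlog)) + 1,
                 pmax(days_between(first, spec$study_end) - 200L,
                      spec$days_supply))
  n_scripts <- pmax(1L, as.integer(ceiling(target / spec$days_supply)))

  pat <- rep(seq_len(n), n_scripts)
  total <- length(pat)
  step <- rep(spec$days_supply, total)
  u <- stats::runif(total)
  delta <- ifelse(u < spec$p_overlap, -10L,
                  ifelse(u < spec$p_overlap + spec$p_gap,
                         round(stats::rexp(total, 1 / spec$gap_mean)), 0L))
  # offsets accumulate within each subject; the first script has none
  ord_first <- !duplicated(pat)
  inc <- step + delta
  inc[ord_first] <- 0L
  offset <- stats::ave(inc, pat, FUN = cumsum)
  scripts <- tibble::tibble(
    patient_id = ids[pat], drug = drug[pat], class = "5ari",
    daily_dose_mg = dose[pat],
    start_date = first[pat] + as.integer(offset),
    days_supply = spec$days_supply)
  # supply must end early enough that >= 90-day persistence after
  # stopping remains observable inside the study window; the first
  # script per subject always fits by construction
  ok <- scripts$start_date + scripts$days_supply <=
    spec$study_end - 120L
  scripts <- scripts[ok | !duplicated(scripts$patient_id), , drop = FALSE]
  total <- nrow(scripts)
  dup <- scripts[stats::runif(total) < spec$p_duplicate, , drop = FALSE]
  dplyr::bind_rows(scripts, dup)
}
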
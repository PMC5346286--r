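# Cohort construction: eligibility filters, the exposed
# no-prior-dysfunction cohort, the young low-dose-finasteride
# subcohort, the one-row-per-subject analysis table, and the temporal
# holdout split for prospective validation.

filter_bundle <- function(bundle, ids) {
  out <- purrr::map(bundle, ~ dplyr::filter(.x, .data$patient_id %in% ids))
  out <- structure(out, class = "odacta_emr")
  for (at in c("stratum", "truth", "planted_params")) {
    v <- attr(bundle, at)
    if (!is.null(v) && is.data.frame(v)) {
      attr(out, at) <- dplyr::filter(v, .data$patient_id %in% ids)
    } else if (!is.null(v)) {
      attr(out, at) <- v
    }
  }
  out
}

# restrict every table to records dated before `end` (half-open)
clip_bundle <- function(bundle, end) {
  out <- bundle
  out$prescriptions <- dplyr::filter(bundle$prescriptions,
                                     .data$start_date < end)
  out$diagnoses <- dplyr::filter(bundle$diagnoses, .data$date < end)
  out$encounters <- dplyr::filter(bundle$encounters, .data$date < end)
  out
}

#' Apply cohort eligibility filters
#'
#' Retains male subjects aged `min_age` to `max_age` (inclusive) at
#' their last encounter inside the study window, with at least one
#' encounter and at least one diagnosis inside the window. Idempotent.
#'
#' @param bundle An `odacta_emr`.
#' @param min_age,max_age Age bounds in whole years (defaults 16, 89).
#' @param window Length-2 date vector, half-open `[start, end)`.
#' @return The filtered bundle, with a `cohort_flow` attribute logging
#'   the counts removed by each criterion.
#' @export
select_eligible <- function(bundle, min_age = 16, max_age = 89,
                            window = c(as.Date("1992-01-01"),
                                       as.Date("2015-09-30"))) {
  enc <- dplyr::filter(bundle$encounters, .data$date >= window[1],
                       .data$date < window[2])
  dx <- dplyr::filter(bundle$diagnoses, .data$date >= window[1],
                      .data$date < window[2])
  last_enc <- dplyr::summarise(dplyr::group_by(enc, .data$patient_id),
                               last_enc = max(.data$date), .groups = "drop")
  p <- dplyr::left_join(bundle$patients, last_enc, by = "patient_id")
  p$has_dx <- p$patient_id %in% dx$patient_id
  p$age_last <- floor(as.numeric(p$last_enc - p$birth_date) / 365.25)

  n0 <- nrow(p)
  male <- p$sex == "M"
  with_enc <- !is.na(p$last_enc)
  with_dx <- p$has_dx
  age_ok <- !is.na(p$age_last) & p$age_last >= min_age & p$age_last <= max_age
  keep <- male & with_enc & with_dx & age_ok
  out <- filter_bundle(bundle, p$patient_id[keep])
  attr(out, "cohort_flow") <- tibble::tibble(
    criterion = c("input", "male", "encounter_in_window",
                  "diagnosis_in_window", "age_in_range"),
    remaining = c(n0, sum(male), sum(male & with_enc),
                  sum(male & with_enc & with_dx), sum(keep)))
  out
}

#' Exposed cohort with no prior sexual dysfunction
#'
#' Subjects with at least one 5a-RI prescription and no ED diagnosis,
#' low-libido diagnosis, or PDE5-inhibitor use dated before their
#' first 5a-RI exposure.
#'
#' @param bundle An `odacta_emr`.
#' @param dict Code dictionary.
#' @return The filtered bundle.
#' @export
select_exposed_no_prior_dysfunction <- function(bundle,
                                                dict = default_code_sets()) {
  exposure <- exposure_summary(bundle$prescriptions, "5ari", dict = dict)
  dirty <- history_flags(bundle, dict,
                         exposure[c("patient_id", "first_exposure_date")])
  filter_bundle(bundle, setdiff(exposure$patient_id, dirty))
}

#' Young low-dose-finasteride subcohort
#'
#' Men aged 16-42 at first finasteride prescription, exposed to
#' finasteride at <= 1.25 mg/day, with no finasteride above 1.25
#' mg/day, no dutasteride, no prostate surgery, disease, or cancer
#' codes, and no ED, low libido, or PDE5-inhibitor use before first
#' finasteride exposure.
#'
#' @param bundle An `odacta_emr`.
#' @param dict Code dictionary.
#' @param age_range Inclusive age bounds at first prescription.
#' @return The filtered bundle.
#' @export
select_young_finasteride_cohort <- function(bundle,
                                            dict = default_code_sets(),
                                            age_range = c(16, 42)) {
  dose <- classify_dose(bundle$prescriptions)
  ok_dose <- dose$patient_id[dose$low_finasteride]
  fin <- exposure_summary(bundle$prescriptions, "5ari",
                          drugs = "finasteride", dict = dict)
  fin <- dplyr::filter(fin, .data$patient_id %in% ok_dose)
  born <- stats::setNames(bundle$patients$birth_date,
                          bundle$patients$patient_id)
  age_first <- floor(as.numeric(fin$first_exposure_date -
                                  born[fin$patient_id]) / 365.25)
  fin <- fin[!is.na(age_first) & age_first >= age_range[1] &
               age_first <= age_range[2], ]
  prostate_codes <- unlist(dict$diagnoses[c("prostate_disease",
                                            "prostate_cancer",
                                            "prostate_surgery")])
  with_prostate <- unique(bundle$diagnoses$patient_id[
    bundle$diagnoses$code %in% prostate_codes])
  dirty <- history_flags(bundle, dict,
                         fin[c("patient_id", "first_exposure_date")])
  filter_bundle(bundle,
                setdiff(fin$patient_id, union(with_prostate, dirty)))
}

binary_dx_attributes <- c(
  "prostate_disease", "prostate_cancer", "prostate_surgery",
  "hypertension", "diabetes", "smoking", "vascular_disease", "depression",
  "obesity", "alcoholism", "hsv", "hiv", "peyronie", "alopecia")
binary_drug_attributes <- c(
  "nsaid", "ssri", "diuretic", "cyclovir", "androgen", "antiandrogen")

#' Build the one-row-per-subject analysis table
#'
#' Applies the case definition for the requested outcome and evaluates
#' every predictor at the subject's reference time: adverse-effect
#' onset for cases, last encounter on record for non-cases. Ordered
#' predictors are age (years), covered 5a-RI exposure days truncated
#' at the reference time, age at first exposure, and clinical
#' encounter counts (total before reference, before first exposure,
#' and between first exposure and reference). Binary predictors are
#' coded from code/prescription presence at any date — except
#' prostate surgery, which for cases ignores surgery after onset.
#'
#' @param bundle An `odacta_emr`, already filtered to the cohort of
#'   interest (see [select_eligible()],
#'   [select_exposed_no_prior_dysfunction()]).
#' @param outcome `"ed"`, `"low_libido"`, or `"ped"`.
#' @param dict Code dictionary.
#' @param window Observation window; records on/after its end are
#'   ignored (the PED-evaluable cohort uses an earlier end than the
#'   ED cohort).
#' @param pde5i_window_days,min_persistence_days Case-definition
#'   parameters (see [detect_new_ed()], [detect_ped()]).
#' @return A tibble, one row per subject: `patient_id`, `outcome`
#'   (0/1), `event_date`, and the predictor columns. An empty cohort
#'   yields an empty tibble.
#' @export
build_analysis_table <- function(bundle,
                                 outcome = c("ed", "low_libido", "ped"),
                                 dict = default_code_sets(),
                                 window = c(as.Date("1992-01-01"),
                                            as.Date("2015-09-30")),
                                 pde5i_window_days = 90L,
                                 min_persistence_days = 90L) {
  outcome <- match.arg(outcome)
  bundle <- clip_bundle(bundle, window[2])
  ids <- bundle$patients$patient_id
  if (length(ids) == 0L) return(empty_analysis_table())

  exposure <- exposure_summary(bundle$prescriptions, "5ari", dict = dict)
  new_ed <- detect_new_ed(bundle, pde5i_window_days = pde5i_window_days,
                          dict = dict, exposure = exposure)
  base <- tibble::tibble(patient_id = ids)
  base <- dplyr::left_join(base, exposure, by = "patient_id")

  ev <- switch(
    outcome,
    ed = dplyr::rename(new_ed, event_date = "new_ed_date"),
    low_libido = dplyr::rename(
      detect_new_low_libido(bundle, dict = dict, exposure = exposure),
      event_date = "new_low_libido_date"),
    ped = {
      if (any(!is.na(new_ed$new_ed_date))) {
        ped <- detect_ped(bundle, min_persistence_days = min_persistence_days,
                          dict = dict, new_ed = new_ed, exposure = exposure)
        ped$event_date <- dplyr::if_else(ped$ped_flag, ped$new_ed_date,
                                         as.Date(NA))
        dplyr::left_join(new_ed["patient_id"],
                         ped[c("patient_id", "event_date")],
                         by = "patient_id")
      } else {
        tibble::tibble(patient_id = new_ed$patient_id,
                       event_date = as.Date(NA))
      }
    })
  base <- dplyr::left_join(base, ev, by = "patient_id")

  enc <- bundle$encounters
  last_enc <- dplyr::summarise(dplyr::group_by(enc, .data$patient_id),
                               last_enc = max(.data$date), .groups = "drop")
  base <- dplyr::left_join(base, last_enc, by = "patient_id")
  base$reference_date <- dplyr::coalesce(base$event_date, base$last_enc,
                                         window[2] - 1L)

  # exposure days truncated at the reference time
  trunc <- exposure_summary(
    bundle$prescriptions, "5ari", dict = dict,
    truncate_at = tibble::tibble(patient_id = base$patient_id,
                                 truncate_at = base$reference_date))
  base <- dplyr::left_join(
    base, dplyr::select(trunc, "patient_id",
                        exposure_days = "covered_days"),
    by = "patient_id")
  base$exposure_days <- dplyr::coalesce(base$exposure_days, 0L)

  born <- stats::setNames(bundle$patients$birth_date,
                          bundle$patients$patient_id)
  base$age <- as.numeric(base$reference_date -
                           born[base$patient_id]) / 365.25
  base$age_at_first_exposure <- as.numeric(
    base$first_exposure_date - born[base$patient_id]) / 365.25

  # encounter counts at the reference time
  ec <- dplyr::inner_join(
    enc, base[c("patient_id", "reference_date", "first_exposure_date")],
    by = "patient_id")
  counts <- dplyr::summarise(
    dplyr::group_by(ec, .data$patient_id),
    encounters_total = sum(.data$date < .data$reference_date),
    encounters_before_exposure = sum(!is.na(.data$first_exposure_date) &
                                       .data$date < .data$first_exposure_date),
    encounters_after_exposure = sum(!is.na(.data$first_exposure_date) &
                                      .data$date >= .data$first_exposure_date &
                                      .data$date < .data$reference_date),
    .groups = "drop")
  base <- dplyr::left_join(base, counts, by = "patient_id")

  # binary attributes from code / prescription presence
  for (at in binary_dx_attributes) {
    codes <- dict$diagnoses[[at]]
    tab <- dplyr::filter(bundle$diagnoses, .data$code %in% codes)
    if (at == "prostate_surgery") {
      tab <- dplyr::left_join(tab, base[c("patient_id", "event_date")],
                              by = "patient_id")
      tab <- dplyr::filter(tab, is.na(.data$event_date) |
                             .data$date < .data$event_date)
    }
    base[[at]] <- as.integer(base$patient_id %in% tab$patient_id)
  }
  for (at in binary_drug_attributes) {
    with_rx <- bundle$prescriptions$patient_id[
      bundle$prescriptions$class == at]
    base[[at]] <- as.integer(base$patient_id %in% with_rx)
  }
  dose <- classify_dose(bundle$prescriptions)
  base <- dplyr::left_join(base, dose, by = "patient_id")
  for (at in c("low_finasteride", "high_finasteride", "dutasteride")) {
    base[[at]] <- as.integer(dplyr::coalesce(base[[at]], FALSE))
  }

  base$outcome <- as.integer(!is.na(base$event_date))
  dplyr::select(base, "patient_id", "outcome", "event_date", "age",
                "age_at_first_exposure", "exposure_days",
                "encounters_total", "encounters_before_exposure",
                "encounters_after_exposure",
                dplyr::all_of(binary_dx_attributes),
                dplyr::all_of(binary_drug_attributes),
                "low_finasteride", "high_finasteride", "dutasteride")
}

empty_analysis_table <- function() {
  tibble::tibble(patient_id = character(), outcome = integer(),
                 event_date = as.Date(character()), age = numeric(),
                 age_at_first_exposure = numeric(),
                 exposure_days = integer(), encounters_total = integer(),
                 encounters_before_exposure = integer(),
                 encounters_after_exposure = integer())
}

#' Default predictor set of an analysis table
#'
#' The screened predictor pool: every analysis-table column except the
#' identifiers, the outcome, and the event date.
#'
#' @param table An analysis table from [build_analysis_table()].
#' @return Character vector of predictor names.
#' @export
analysis_predictors <- function(table) {
  setdiff(names(table), c("patient_id", "outcome", "event_date"))
}

#' Split a cohort into a training interval and a prospective holdout
#'
#' The training table uses records up to `cutoff` only. The holdout
#' comprises subjects with no detected event in the training interval;
#' they are scored on events occurring in the
#' `(cutoff, cutoff + holdout_days]` interval, with records after that
#' interval ignored.
#'
#' @param bundle An `odacta_emr`, filtered to the cohort of interest.
#' @param cutoff Date ending the training interval; must lie inside
#'   `window`.
#' @param holdout_days Length of the validation interval (default 183,
#'   about six months).
#' @param outcome,dict,... Passed to [build_analysis_table()].
#' @param window Overall study window.
#' @return List with `train` and `holdout` analysis tables.
#' @export
temporal_holdout <- function(bundle, cutoff, holdout_days = 183L,
                             outcome = "ed", dict = default_code_sets(),
                             window = c(as.Date("1992-01-01"),
                                        as.Date("2015-09-30")), ...) {
  cutoff <- as.Date(cutoff)
  if (cutoff <= window[1] || cutoff >= window[2]) {
    abort_odacta("`cutoff` must lie strictly inside the study window.",
                 "odacta_config_error")
  }
  train <- build_analysis_table(bundle, outcome = outcome, dict = dict,
                                window = c(window[1], cutoff), ...)
  ext <- build_analysis_table(
    bundle, outcome = outcome, dict = dict,
    window = c(window[1], min(cutoff + holdout_days + 1L, window[2])), ...)
  # exclude subjects with any detected dysfunction in the main interval
  dirty_main <- unique(c(
    train$patient_id[train$outcome == 1L],
    main_dysfunction_ids(bundle, cutoff, dict)))
  hold <- dplyr::filter(ext, !(.data$patient_id %in% dirty_main))
  hold$outcome <- as.integer(!is.na(hold$event_date) &
                               hold$event_date > cutoff &
                               hold$event_date <= cutoff + holdout_days)
  list(train = train, holdout = hold)
}

# any ED or low-libido designation during the main interval
main_dysfunction_ids <- function(bundle, cutoff, dict) {
  main <- clip_bundle(bundle, cutoff)
  exposure <- exposure_summary(main$prescriptions, "5ari", dict = dict)
  if (nrow(exposure) == 0L) return(character())
  ed <- detect_new_ed(main, dict = dict, exposure = exposure)
  ll <- detect_new_low_libido(main, dict = dict, exposure = exposure)
  unique(c(ed$patient_id[!is.na(ed$new_ed_date)],
           ll$patient_id[!is.na(ll$new_low_libido_date)]))
}
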
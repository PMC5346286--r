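# Drug-exposure summaries from prescription records.  Exposure
# duration is the length of the union of half-open supply intervals
# [start, start + days_supply), intersected with [first start,
# truncation point): duplicate prescriptions therefore count once and
# uncovered gaps contribute nothing.

#' Summarise drug exposure per patient
#'
#' For every patient with at least one prescription of `drug_class`
#' (optionally restricted to named drugs), computes the first exposure
#' date, the end of the last supply interval, and the covered exposure
#' days: the union of the half-open supply intervals, intersected with
#' `[first_exposure_date, truncate_at)`. Exact duplicate prescriptions
#' are dropped before the union; for drugs approved after the start of
#' the assessment era, exposure assessment begins at the approval date
#' recorded in the drug dictionary (supply before approval is
#' clipped).
#'
#' Patients with no prescription of the class are simply absent from
#' the result — an empty exposure, which is distinct from a patient
#' with zero covered days after truncation.
#'
#' @param prescriptions Prescription tibble (`patient_id`, `drug`,
#'   `class`, `daily_dose_mg`, `start_date`, `days_supply`).
#' @param drug_class Class to summarise (default `"5ari"`).
#' @param drugs Optional character vector restricting to named drugs
#'   (e.g. `"finasteride"` for the young-men cohort).
#' @param truncate_at Either a single date, or a tibble
#'   (`patient_id`, `truncate_at`) giving a per-patient truncation
#'   point (e.g. adverse-effect onset); `NULL` leaves supply
#'   untruncated.
#' @param dict Drug dictionary from [default_code_sets()], used for
#'   approval-date clipping; `NULL` skips clipping.
#' @return Tibble, one row per exposed patient: `patient_id`,
#'   `first_exposure_date`, `covered_days`, `last_supply_end`,
#'   `n_prescriptions`.
#' @export
#' @examples
#' rx <- tibble::tibble(
#'   patient_id = "p1", drug = "finasteride", class = "5ari",
#'   daily_dose_mg = 1, start_date = as.Date("2005-01-01") + c(0, 15),
#'   days_supply = 30L)
#' exposure_summary(rx)$covered_days # 45: overlap counted once
exposure_summary <- function(prescriptions, drug_class = "5ari",
                             drugs = NULL, truncate_at = NULL, dict = NULL) {
  rx <- dplyr::filter(prescriptions, .data$class == drug_class)
  if (!is.null(drugs)) rx <- dplyr::filter(rx, .data$drug %in% drugs)
  if (nrow(rx) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          first_exposure_date = as.Date(character()),
                          covered_days = integer(),
                          last_supply_end = as.Date(character()),
                          n_prescriptions = integer()))
  }
  rx <- dplyr::distinct(rx, .data$patient_id, .data$drug,
                        .data$daily_dose_mg, .data$start_date,
                        .data$days_supply)
  s <- as.numeric(rx$start_date)
  e <- s + rx$days_supply
  if (!is.null(dict)) {
    appr <- vapply(dict$drugs, function(d) as.numeric(d$approval),
                   numeric(1))
    ad <- unname(appr[rx$drug])
    ad[is.na(ad)] <- -Inf
    s <- pmax(s, ad)
    keep <- e > s
    rx <- rx[keep, , drop = FALSE]
    s <- s[keep]
    e <- e[keep]
  }
  if (is.null(truncate_at)) {
    tr <- rep(Inf, nrow(rx))
  } else if (inherits(truncate_at, "Date") && length(truncate_at) == 1L) {
    tr <- rep(as.numeric(truncate_at), nrow(rx))
  } else {
    tr <- as.numeric(truncate_at$truncate_at)[
      match(rx$patient_id, truncate_at$patient_id)]
    tr[is.na(tr)] <- Inf
  }

  o <- order(rx$patient_id, s)
  pid <- rx$patient_id[o]
  s <- s[o]; e <- e[o]; tr <- tr[o]
  grp <- cumsum(!duplicated(pid))
  e_cap <- pmin(e, tr)
  # within-group running maximum without grouping: add a per-group
  # offset large enough that earlier groups can never dominate
  big <- max(e) - min(s) + 1
  run_max <- cummax(e_cap + big * grp) - big * grp
  first_of_grp <- !duplicated(grp)
  prev_max <- c(-Inf, run_max[-length(run_max)])
  prev_max[first_of_grp] <- -Inf
  contrib <- pmax(0, e_cap - pmax(s, prev_max))

  covered <- rowsum(contrib, grp)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  run_max_e <- cummax(e + big * grp) - big * grp
  tibble::tibble(
    patient_id = pid[first_of_grp],
    first_exposure_date = as.Date(s[first_of_grp], origin = "1970-01-01"),
    covered_days = as.integer(round(covered[, 1])),
    last_supply_end = as.Date(run_max_e[last_of_grp], origin = "1970-01-01"),
    n_prescriptions = tabulate(grp))
}

#' Classify 5a-RI dosing per patient
#'
#' Finasteride dosing is split at 1.25 mg/day (tablet splitting of the
#' 5 mg form makes <= 1.25 mg the alopecia-range dose); dutasteride is
#' its own indicator. The three flags are per-drug indicators and not
#' mutually exclusive; `dose_class` is the exclusive summary label
#' used for stratified reporting: `dutasteride` if any dutasteride
#' exposure, else `high_finasteride` if any finasteride above 1.25
#' mg/day, else `low_finasteride`.
#'
#' @param prescriptions Prescription tibble.
#' @return Tibble per patient with >= 1 5a-RI script: `patient_id`,
#'   `low_finasteride` (all finasteride <= 1.25 mg/day, none higher,
#'   no dutasteride), `high_finasteride`, `dutasteride`, `dose_class`.
#' @export
classify_dose <- function(prescriptions) {
  rx <- dplyr::filter(prescriptions, .data$class == "5ari")
  if (nrow(rx) == 0L) {
    return(tibble::tibble(patient_id = character(),
                          low_finasteride = logical(),
                          high_finasteride = logical(),
                          dutasteride = logical(),
                          dose_class = character()))
  }
  if (any(rx$daily_dose_mg <= 0, na.rm = TRUE)) {
    abort_odacta("5a-RI prescriptions must carry a positive daily dose.",
                 "odacta_validation_error")
  }
  dplyr::summarise(
    dplyr::group_by(rx, .data$patient_id),
    any_low_fin = any(.data$drug == "finasteride" & .data$daily_dose_mg <= 1.25),
    high_finasteride = any(.data$drug == "finasteride" & .data$daily_dose_mg > 1.25),
    dutasteride = any(.data$drug == "dutasteride"),
    .groups = "drop") |>
    dplyr::mutate(
      low_finasteride = .data$any_low_fin & !.data$high_finasteride &
        !.data$dutasteride,
      dose_class = dplyr::case_when(
        .data$dutasteride ~ "dutasteride",
        .data$high_finasteride ~ "high_finasteride",
        TRUE ~ "low_finasteride")) |>
    dplyr::select("patient_id", "low_finasteride", "high_finasteride",
                  "dutasteride", "dose_class")
}
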
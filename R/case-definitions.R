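# Trigger-tool case definitions on structured records.  New ED needs a
# coded diagnosis plus a contemporaneous PDE5-inhibitor prescription
# (the "antidote") in the PDE5I era, with a clean pre-exposure history;
# persistent ED (PED) additionally needs the ED documented as ongoing
# at least `min_persistence_days` after the end of the last 5a-RI
# supply, with resolution determined from structured resolution codes
# rather than chart review.

# shared per-patient history relative to first exposure
history_flags <- function(bundle, dict, first_exposure) {
  ed_dx <- dplyr::filter(bundle$diagnoses, .data$code %in% dict$diagnoses$ed)
  ll_dx <- dplyr::filter(bundle$diagnoses,
                         .data$code %in% dict$diagnoses$low_libido)
  pde <- dplyr::filter(bundle$prescriptions, .data$class == "pde5i")
  prior_ids <- function(tab, datecol) {
    tb <- dplyr::inner_join(tab, first_exposure, by = "patient_id")
    unique(tb$patient_id[tb[[datecol]] < tb$first_exposure_date])
  }
  unique(c(prior_ids(ed_dx, "date"), prior_ids(ll_dx, "date"),
           prior_ids(pde, "start_date")))
}

#' Detect new erectile dysfunction after first 5a-RI exposure
#'
#' Per exposed patient, the earliest ED diagnosis that (a) falls after
#' the first 5a-RI exposure date, (b) falls in `pde5i_era_start`'s
#' year or later, and (c) has a PDE5-inhibitor prescription within
#' `pde5i_window_days` days — provided no ED diagnosis, low-libido
#' diagnosis, or PDE5I prescription predates first exposure.
#'
#' @param bundle An `odacta_emr`.
#' @param pde5i_window_days Half-width (days) of the contemporaneity
#'   window between ED diagnosis and PDE5I prescription (default 90;
#'   not pinned down by the trigger-tool definition, so configurable).
#' @param pde5i_era_start Earliest calendar date an ED event may
#'   qualify (first PDE5I marketing).
#' @param dict Code dictionary.
#' @param exposure Optional precomputed [exposure_summary()].
#' @return Tibble for every exposed patient: `patient_id`,
#'   `new_ed_date` (`NA` if no qualifying event).
#' @export
detect_new_ed <- function(bundle, pde5i_window_days = 90L,
                          pde5i_era_start = as.Date("1998-01-01"),
                          dict = default_code_sets(),
                          exposure = NULL) {
  exposure <- exposure %||%
    exposure_summary(bundle$prescriptions, "5ari", dict = dict)
  first_exposure <- exposure[c("patient_id", "first_exposure_date")]
  dirty <- history_flags(bundle, dict, first_exposure)

  ed_dx <- dplyr::filter(bundle$diagnoses, .data$code %in% dict$diagnoses$ed)
  pde <- dplyr::select(
    dplyr::filter(bundle$prescriptions, .data$class == "pde5i"),
    "patient_id", pde_date = "start_date")
  cand <- dplyr::inner_join(ed_dx, first_exposure, by = "patient_id")
  cand <- dplyr::filter(cand,
                        .data$date > .data$first_exposure_date,
                        .data$date >= pde5i_era_start,
                        !(.data$patient_id %in% dirty))
  cand <- dplyr::inner_join(cand, pde, by = "patient_id",
                            relationship = "many-to-many")
  cand <- dplyr::filter(cand, abs(as.numeric(.data$date - .data$pde_date)) <=
                          pde5i_window_days)
  hits <- if (nrow(cand)) {
    dplyr::summarise(dplyr::group_by(cand, .data$patient_id),
                     new_ed_date = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(),
                   new_ed_date = as.Date(character()))
  }
  dplyr::left_join(first_exposure["patient_id"], hits, by = "patient_id")
}

#' Detect new low libido after first 5a-RI exposure
#'
#' Earliest low-libido diagnosis after first exposure, in patients
#' with no ED/low-libido diagnosis or PDE5I use before first exposure.
#'
#' @inheritParams detect_new_ed
#' @return Tibble: `patient_id`, `new_low_libido_date` (`NA` if none).
#' @export
detect_new_low_libido <- function(bundle, dict = default_code_sets(),
                                  exposure = NULL) {
  exposure <- exposure %||%
    exposure_summary(bundle$prescriptions, "5ari", dict = dict)
  first_exposure <- exposure[c("patient_id", "first_exposure_date")]
  dirty <- history_flags(bundle, dict, first_exposure)
  ll <- dplyr::filter(bundle$diagnoses,
                      .data$code %in% dict$diagnoses$low_libido)
  cand <- dplyr::inner_join(ll, first_exposure, by = "patient_id")
  cand <- dplyr::filter(cand, .data$date > .data$first_exposure_date,
                        !(.data$patient_id %in% dirty))
  hits <- if (nrow(cand)) {
    dplyr::summarise(dplyr::group_by(cand, .data$patient_id),
                     new_low_libido_date = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(),
                   new_low_libido_date = as.Date(character()))
  }
  dplyr::left_join(first_exposure["patient_id"], hits, by = "patient_id")
}

#' Determine persistence of new ED after stopping the 5a-RI
#'
#' Applies the >= 90-day persistence criterion on structured records.
#' "Stopping" is the end of the last supply interval
#' (start + days of supply), not the last prescription date. The flag
#' requires *positive documentation* of ongoing ED: the latest
#' ED-supporting record must fall at least `min_persistence_days`
#' after stopping, and either no resolution is recorded or resolution
#' itself falls at least that long after stopping. Persistence days
#' run from stopping to the resolution date when recorded, otherwise
#' to the last ED-supporting documentation.
#'
#' @param bundle An `odacta_emr`.
#' @param min_persistence_days Persistence criterion in days
#'   (regulatory definition: 90).
#' @param dict Code dictionary.
#' @param new_ed Optional precomputed [detect_new_ed()] result.
#' @param exposure Optional precomputed [exposure_summary()].
#' @param ... Passed to [detect_new_ed()] when it must be computed.
#' @return Tibble for each patient with new ED: `patient_id`,
#'   `new_ed_date`, `last_supply_end`, `resolution_date`,
#'   `last_ed_documentation`, `ped_persistence_days`, `ped_flag`.
#' @export
detect_ped <- function(bundle, min_persistence_days = 90L,
                       dict = default_code_sets(), new_ed = NULL,
                       exposure = NULL, ...) {
  exposure <- exposure %||%
    exposure_summary(bundle$prescriptions, "5ari", dict = dict)
  new_ed <- new_ed %||% detect_new_ed(bundle, dict = dict,
                                      exposure = exposure, ...)
  cases <- dplyr::filter(new_ed, !is.na(.data$new_ed_date))
  if (nrow(cases) == 0L) {
    abort_odacta("detect_ped() requires at least one patient with new ED.",
                 "odacta_precondition_error")
  }
  cases <- dplyr::inner_join(cases,
                             exposure[c("patient_id", "last_supply_end")],
                             by = "patient_id")

  ed_dx <- dplyr::filter(bundle$diagnoses, .data$code %in% dict$diagnoses$ed)
  last_doc <- dplyr::summarise(dplyr::group_by(ed_dx, .data$patient_id),
                               last_ed_documentation = max(.data$date),
                               .groups = "drop")
  res <- dplyr::filter(bundle$diagnoses,
                       .data$code %in% dict$diagnoses$ed_resolved)
  res <- dplyr::inner_join(res, cases[c("patient_id", "new_ed_date")],
                           by = "patient_id")
  res <- dplyr::filter(res, .data$date >= .data$new_ed_date)
  res <- if (nrow(res)) {
    dplyr::summarise(dplyr::group_by(res, .data$patient_id),
                     resolution_date = min(.data$date), .groups = "drop")
  } else {
    tibble::tibble(patient_id = character(),
                   resolution_date = as.Date(character()))
  }

  out <- dplyr::left_join(cases, last_doc, by = "patient_id")
  out <- dplyr::left_join(out, res, by = "patient_id")
  out <- dplyr::mutate(
    out,
    documented_persistence = as.numeric(.data$last_ed_documentation -
                                          .data$last_supply_end),
    resolution_lag = as.numeric(.data$resolution_date -
                                  .data$last_supply_end),
    ped_flag = .data$documented_persistence >= min_persistence_days &
      (is.na(.data$resolution_date) |
         .data$resolution_lag >= min_persistence_days),
    ped_persistence_days = as.integer(
      dplyr::if_else(is.na(.data$resolution_date),
                     .data$documented_persistence, .data$resolution_lag)))
  dplyr::select(out, "patient_id", "new_ed_date", "last_supply_end",
                "resolution_date", "last_ed_documentation",
                "ped_persistence_days", "ped_flag")
}
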
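# The four-table EMR bundle: patients, prescriptions, diagnoses,
# encounters.  Dates are ISO-8601 calendar dates; every interval in the
# package is half-open [start, end) and date arithmetic is in whole
# days.  Procedure codes (e.g. prostate surgery) are carried in the
# diagnoses table with the other coded events, keeping the bundle to
# four files.

#' Toy clinical code dictionary
#'
#' Loads the packaged dictionary mapping analysis concepts to a small
#' set of diagnosis codes and to drug names with their class and market
#' approval date. It is deliberately tiny — a stand-in vocabulary, not
#' a clinical terminology.
#'
#' @param path Optional path to an alternative JSON dictionary with the
#'   same structure.
#' @return A list with elements `diagnoses` (named list of code
#'   character vectors, including `ed`, `ed_resolved`, `low_libido`,
#'   `prostate_disease`, ...) and `drugs` (named list of
#'   `list(class, approval)`).
#' @export
default_code_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_dictionary.json",
                                package = "odacta", mustWork = TRUE)
  dict <- jsonlite::read_json(path, simplifyVector = TRUE)
  dict$drugs <- purrr::map(dict$drugs, function(d) {
    d$approval <- as.Date(d$approval)
    d
  })
  dict
}

#' Assemble and validate an EMR bundle
#'
#' @param patients Tibble: `patient_id`, `sex` (`"M"`/`"F"`),
#'   `birth_date` (Date).
#' @param prescriptions Tibble: `patient_id`, `drug`, `class`,
#'   `daily_dose_mg`, `start_date`, `days_supply`.
#' @param diagnoses Tibble: `patient_id`, `code`, `date`.
#' @param encounters Tibble: `patient_id`, `date`.
#' @return A validated list of the four tibbles, class `odacta_emr`.
#' @export
emr_bundle <- function(patients, prescriptions, diagnoses, encounters) {
  b <- list(patients = tibble::as_tibble(patients),
            prescriptions = tibble::as_tibble(prescriptions),
            diagnoses = tibble::as_tibble(diagnoses),
            encounters = tibble::as_tibble(encounters))
  validate_emr(b)
  structure(b, class = "odacta_emr")
}

validate_emr <- function(b) {
  need <- list(
    patients = c("patient_id", "sex", "birth_date"),
    prescriptions = c("patient_id", "drug", "class", "daily_dose_mg",
                      "start_date", "days_supply"),
    diagnoses = c("patient_id", "code", "date"),
    encounters = c("patient_id", "date"))
  for (tb in names(need)) {
    miss <- setdiff(need[[tb]], names(b[[tb]]))
    if (length(miss)) {
      abort_odacta(sprintf("EMR table '%s' lacks column(s): %s.", tb,
                           paste(miss, collapse = ", ")),
                   "odacta_validation_error")
    }
  }
  if (anyDuplicated(b$patients$patient_id)) {
    abort_odacta("Duplicate patient_id in patients table.",
                 "odacta_validation_error")
  }
  for (tb in c("prescriptions", "diagnoses", "encounters")) {
    datecol <- if (tb == "prescriptions") "start_date" else "date"
    bad <- b[[tb]][is.na(b[[tb]][[datecol]]), , drop = FALSE]
    if (nrow(bad)) {
      abort_odacta(sprintf("Table '%s' row for patient '%s' has a malformed %s.",
                           tb, bad$patient_id[[1]], datecol),
                   "odacta_validation_error")
    }
  }
  # event dates must not precede birth; supplies at least one day
  born <- stats::setNames(b$patients$birth_date, b$patients$patient_id)
  pre <- b$prescriptions$start_date < born[b$prescriptions$patient_id]
  if (any(pre, na.rm = TRUE)) {
    abort_odacta(sprintf("Prescription before birth for patient '%s'.",
                         b$prescriptions$patient_id[which(pre)[1]]),
                 "odacta_validation_error")
  }
  if (any(b$prescriptions$days_supply < 1, na.rm = TRUE)) {
    bad <- b$prescriptions$patient_id[which(b$prescriptions$days_supply < 1)[1]]
    abort_odacta(sprintf("days_supply < 1 for patient '%s'.", bad),
                 "odacta_validation_error")
  }
  invisible(b)
}

#' @export
print.odacta_emr <- function(x, ...) {
  cat("EMR bundle:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s %7d rows\n", nm, nrow(x[[nm]])))
  }
  tr <- attr(x, "truth")
  if (!is.null(tr)) {
    cat(sprintf("  planted truth for %d subjects (%d events)\n",
                nrow(tr), sum(tr$ed | tr$low_libido)))
  }
  invisible(x)
}

#' Write / read an EMR bundle as four CSV files
#'
#' `patients.csv`, `prescriptions.csv`, `diagnoses.csv`,
#' `encounters.csv`; when the bundle carries planted ground truth it is
#' written alongside as `truth.json` (leaf assignments and planted
#' parameters) and restored on read.
#'
#' @param bundle An `odacta_emr`.
#' @param dir Directory (created if needed).
#' @return `write_emr_bundle` returns `dir` invisibly;
#'   `read_emr_bundle` the bundle.
#' @export
write_emr_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  truth <- attr(bundle, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(truth = truth, planted = attr(bundle, "planted_params")),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(dir)
}

#' @rdname write_emr_bundle
#' @export
read_emr_bundle <- function(dir) {
  rd <- function(nm, types) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                    col_types = types, progress = FALSE)
  }
  b <- emr_bundle(
    patients = rd("patients", readr::cols(patient_id = "c", sex = "c",
                                          birth_date = "D")),
    prescriptions = rd("prescriptions",
                       readr::cols(patient_id = "c", drug = "c", class = "c",
                                   daily_dose_mg = "d", start_date = "D",
                                   days_supply = "i")),
    diagnoses = rd("diagnoses", readr::cols(patient_id = "c", code = "c",
                                            date = "D")),
    encounters = rd("encounters", readr::cols(patient_id = "c", date = "D")))
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    attr(b, "truth") <- tibble::as_tibble(tj$truth)
    attr(b, "planted_params") <- tj$planted
  }
  b
}
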
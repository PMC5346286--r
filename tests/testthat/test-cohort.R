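# Eligibility filters, subcohort definitions, the analysis table, and
# the temporal holdout split.

five_eligible <- function() {
  origin <- as.Date("2005-01-01")
  ids <- paste0("p", 1:5)
  toy_bundle(
    patients = tibble::tibble(patient_id = ids, sex = "M",
                              birth_date = as.Date("1960-06-15")),
    diagnoses = tibble::tibble(patient_id = ids, code = "V70.0",
                               date = origin + 10),
    encounters = tibble::tibble(patient_id = ids, date = origin + 10))
}

test_that("eligibility enforces sex, age range, encounter and diagnosis", {
  b5 <- five_eligible()
  out <- select_eligible(b5)
  expect_equal(sort(out$patients$patient_id), sort(b5$patients$patient_id))
  # idempotent
  out2 <- select_eligible(out)
  expect_equal(out2$patients, out$patients)

  origin <- as.Date("2005-01-01")
  b <- toy_bundle(
    patients = tibble::tibble(
      patient_id = c("young", "old", "female", "no_dx", "no_enc", "ok"),
      sex = c("M", "M", "F", "M", "M", "M"),
      birth_date = c(origin - round(15.5 * 365.25),
                     origin - round(91 * 365.25),
                     rep(as.Date("1960-01-01"), 4))),
    diagnoses = tibble::tibble(
      patient_id = c("young", "old", "female", "no_enc", "ok"),
      code = "V70.0", date = origin),
    encounters = tibble::tibble(
      patient_id = c("young", "old", "female", "no_dx", "ok"),
      date = origin))
  out <- select_eligible(b)
  expect_equal(out$patients$patient_id, "ok")
  flow <- attr(out, "cohort_flow")
  expect_equal(flow$remaining[1], 6)
  expect_equal(flow$remaining[nrow(flow)], 1)
})

test_that("the young low-dose finasteride subcohort applies every exclusion", {
  origin <- as.Date("2005-01-01")
  mk <- function(id, age, dose = 1, drug = "finasteride",
                 extra_rx = NULL, extra_dx = NULL) {
    rx <- tibble::tibble(patient_id = id, drug = drug, class = "5ari",
                         daily_dose_mg = dose, start_date = origin,
                         days_supply = 30L)
    if (!is.null(extra_rx)) rx <- dplyr::bind_rows(rx, extra_rx)
    dx <- tibble::tibble(patient_id = id, code = "V70.0", date = origin)
    if (!is.null(extra_dx)) dx <- dplyr::bind_rows(dx, extra_dx)
    list(patients = tibble::tibble(
      patient_id = id, sex = "M",
      birth_date = origin - round(age * 365.25) - 10),
      rx = rx, dx = dx,
      enc = tibble::tibble(patient_id = id, date = origin))
  }
  parts <- list(
    mk("young_ok", 30),
    mk("too_old", 43),
    mk("duta", 30, extra_rx = tibble::tibble(
      patient_id = "duta", drug = "dutasteride", class = "5ari",
      daily_dose_mg = 0.5, start_date = origin + 50, days_supply = 30L)),
    mk("high_dose", 30, dose = 5),
    mk("prostate", 30, extra_dx = tibble::tibble(
      patient_id = "prostate", code = "600.00", date = origin + 5)),
    mk("prior_pde5i", 30, extra_rx = tibble::tibble(
      patient_id = "prior_pde5i", drug = "sildenafil", class = "pde5i",
      daily_dose_mg = 50, start_date = origin - 100, days_supply = 30L)))
  b <- toy_bundle(
    patients = dplyr::bind_rows(purrr::map(parts, "patients")),
    prescriptions = dplyr::bind_rows(purrr::map(parts, "rx")),
    diagnoses = dplyr::bind_rows(purrr::map(parts, "dx")),
    encounters = dplyr::bind_rows(purrr::map(parts, "enc")))
  out <- select_young_finasteride_cohort(b)
  expect_equal(out$patients$patient_id, "young_ok")
})

test_that("predictors are evaluated at onset for cases, last encounter otherwise", {
  # case: ED onset day 400; encounters at 0, 50, 700 plus event days
  b <- toy_exposed_patient(ed_day = 400, pde5i_day = 410,
                           extra_ed_days = 650,
                           enc_days = c(0, 50, 300, 500, 700))
  tab <- build_analysis_table(b, outcome = "ed")
  expect_equal(tab$outcome, 1L)
  # encounters strictly before onset: days 0, 50, 300
  expect_equal(tab$encounters_total, 3L)
  # before first exposure (day 100): days 0, 50
  expect_equal(tab$encounters_before_exposure, 2L)
  expect_equal(tab$encounters_after_exposure, 1L)
  # exposure truncated at onset day 400 (exposure runs 100..460)
  expect_equal(tab$exposure_days, 300L)
  # age at onset
  expect_equal(tab$age,
               as.numeric(toy_day(400) - as.Date("1960-01-01")) / 365.25)

  # non-case: same chronology without the PDE5I antidote
  b0 <- toy_exposed_patient(ed_day = 400, extra_ed_days = 650,
                            enc_days = c(0, 50, 300, 500, 700))
  tab0 <- build_analysis_table(b0, outcome = "ed")
  expect_equal(tab0$outcome, 0L)
  # reference = last encounter (day 700): all encounters before it count
  expect_equal(tab0$encounters_total, 6L)
  expect_equal(tab0$exposure_days, 360L)
  expect_equal(tab0$age,
               as.numeric(toy_day(700) - as.Date("1960-01-01")) / 365.25)
})

test_that("an empty cohort yields an empty table without error", {
  b <- toy_bundle(patients = tibble::tibble(
    patient_id = character(), sex = character(),
    birth_date = as.Date(character())))
  tab <- build_analysis_table(b, outcome = "ed")
  expect_equal(nrow(tab), 0L)
})

test_that("the temporal holdout scores only the six-month validation interval", {
  origin <- as.Date("2005-01-01")
  cutoff <- origin + 1000
  mk_case <- function(id, ed_day) {
    toy_exposed_patient(id = id, ed_day = ed_day, pde5i_day = ed_day + 5,
                        enc_days = c(0, 50, 700, 1400))
  }
  parts <- list(
    mk_case("train_case", 400),          # event before cutoff
    mk_case("holdout_case", 1060),       # ~2 months after cutoff
    mk_case("late_case", 1250),          # ~8 months after cutoff
    toy_exposed_patient(id = "never", enc_days = c(0, 50, 700, 1400)))
  b <- structure(purrr::map(
    stats::setNames(names(parts[[1]]), names(parts[[1]])),
    function(nm) dplyr::bind_rows(purrr::map(parts, nm))),
    class = "odacta_emr")
  split <- temporal_holdout(b, cutoff = cutoff, holdout_days = 183,
                            outcome = "ed",
                            window = c(origin, origin + 2000))
  expect_true("train_case" %in%
                split$train$patient_id[split$train$outcome == 1])
  # the training case is excluded from the holdout
  expect_false("train_case" %in% split$holdout$patient_id)
  h <- split$holdout
  expect_equal(h$outcome[h$patient_id == "holdout_case"], 1L)
  expect_equal(h$outcome[h$patient_id == "late_case"], 0L)
  expect_equal(h$outcome[h$patient_id == "never"], 0L)
  expect_error(temporal_holdout(b, cutoff = origin + 3000,
                                window = c(origin, origin + 2000)),
               class = "odacta_config_error")
})
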
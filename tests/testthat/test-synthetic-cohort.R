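# The synthetic EMR generator and the planted threshold-tree outcome
# model: determinism, statistical fidelity, and truth-set behaviour.

test_that("the default spec carries the emulated per-stratum prevalences", {
  spec <- default_spec()
  pv <- spec$prevalences
  expect_equal(pv$unexposed[pv$attribute == "nsaid"], 0.268)
  expect_equal(pv$exposed[pv$attribute == "nsaid"], 0.558)
  expect_equal(pv$unexposed[pv$attribute == "hypertension"], 0.175)
  expect_equal(pv$unexposed[pv$attribute == "prostate_disease"], 0.037)
  expect_error(synthetic_spec(n_subjects = 0), class = "odacta_config_error")
  expect_error(synthetic_spec(exposure_fraction = 1.2),
               class = "odacta_config_error")
  expect_error(synthetic_spec(study_start = "2010-01-01",
                              study_end = "2000-01-01"),
               class = "odacta_config_error")
})

test_that("generation is fully determined by (spec, seed)", {
  spec <- synthetic_spec(n_subjects = 300)
  b1 <- generate_cohort(spec, seed = 7)
  b2 <- generate_cohort(spec, seed = 7)
  expect_identical(b1$patients, b2$patients)
  expect_identical(b1$prescriptions, b2$prescriptions)
  expect_identical(b1$diagnoses, b2$diagnoses)
  b3 <- generate_cohort(spec, seed = 8)
  expect_false(identical(b1$prescriptions, b3$prescriptions))
})

test_that("exposure_fraction zero means no 5a-RI scripts at all", {
  spec <- synthetic_spec(n_subjects = 200, exposure_fraction = 0)
  b <- generate_cohort(spec, seed = 3)
  expect_equal(sum(b$prescriptions$class == "5ari"), 0L)
})

test_that("empirical prevalences converge to the spec values", {
  spec <- synthetic_spec(n_subjects = 10000, exposure_fraction = 0,
                         ineligible_frac = 0)
  b <- generate_cohort(spec, seed = 12)
  nsaid_ids <- unique(b$prescriptions$patient_id[
    b$prescriptions$class == "nsaid"])
  p_hat <- length(nsaid_ids) / 10000
  expect_lt(abs(p_hat - 0.268), 0.015)
  # a diagnosis attribute, 4-sigma binomial envelope
  ht <- unique(b$diagnoses$patient_id[b$diagnoses$code == "401.9"])
  expect_lt(abs(length(ht) / 10000 - 0.175),
            4 * sqrt(0.175 * 0.825 / 10000))
})

test_that("every exposed subject has a script inside the study window", {
  spec <- synthetic_spec(n_subjects = 500, exposure_fraction = 1)
  b <- generate_cohort(spec, seed = 9)
  ex <- exposure_summary(b$prescriptions, "5ari")
  expect_equal(nrow(ex), 500L)
  expect_true(all(ex$first_exposure_date >= spec$study_start))
  expect_true(all(ex$first_exposure_date < spec$study_end))
})

test_that("zero leaf risks plant zero events", {
  spec <- synthetic_spec(n_subjects = 400, exposure_fraction = 1)
  b <- generate_cohort(spec, seed = 5)
  quiet <- planted_tree_spec(
    tree = list(attribute = "prostate_disease", type = "binary",
                yes = list(leaf = "a", risk = 0),
                no = list(leaf = "b", risk = 0)),
    persistence_given_ed = 0.315, exposed_low_libido = 0,
    unexposed_ed = 0, unexposed_low_libido = 0)
  b0 <- plant_outcome(b, quiet, seed = 6)
  tr <- attr(b0, "truth")
  expect_equal(sum(tr$ped), 0L)
  expect_equal(sum(tr$ed), 0L)
  expect_equal(sum(tr$low_libido), 0L)
})

test_that("planted leaf rates converge to the leaf risks", {
  spec <- synthetic_spec(n_subjects = 20000, exposure_fraction = 1)
  b <- generate_cohort(spec, seed = 41)
  two_leaf <- planted_tree_spec(
    tree = list(attribute = "exposure_days", type = "ordered",
                cutpoint = 200,
                no = list(leaf = "short", risk = 0.002),
                yes = list(leaf = "long", risk = 0.012)))
  b <- plant_outcome(b, two_leaf, seed = 42)
  tr <- attr(b, "truth")
  for (lf in c("short", "long")) {
    sub <- tr[tr$leaf == lf, ]
    p <- if (lf == "short") 0.002 else 0.012
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$ped) - p), 3 * se + 1e-9)
  }
})

test_that("planted persistence matches the target median scale", {
  spec <- synthetic_spec(n_subjects = 4000, exposure_fraction = 1)
  b <- generate_cohort(spec, seed = 51)
  heavy <- planted_tree_spec(
    tree = list(attribute = "prostate_disease", type = "binary",
                yes = list(leaf = "a", risk = 0.5),
                no = list(leaf = "b", risk = 0.5)))
  b <- plant_outcome(b, heavy, seed = 52)
  tr <- attr(b, "truth")
  expect_gt(sum(tr$ped), 1000)
  med <- stats::median(tr$persistence_days[tr$ped], na.rm = TRUE)
  expect_lt(abs(med - 1348) / 1348, 0.10)
  # outcome stream is separate: same cohort, same outcome seed,
  # identical truth
  b2 <- plant_outcome(generate_cohort(spec, seed = 51), heavy, seed = 52)
  expect_identical(attr(b2, "truth"), tr)
})

test_that("unresolvable planted attributes are a configuration error", {
  spec <- synthetic_spec(n_subjects = 100, exposure_fraction = 1)
  b <- generate_cohort(spec, seed = 2)
  bad <- planted_tree_spec(
    tree = list(attribute = "not_an_attribute", type = "binary",
                yes = list(leaf = "a", risk = 0.1),
                no = list(leaf = "b", risk = 0.1)))
  expect_error(plant_outcome(b, bad, seed = 1),
               class = "odacta_config_error")
})

test_that("bundles round-trip through the four-CSV format with truth", {
  spec <- synthetic_spec(n_subjects = 120, exposure_fraction = 0.5)
  b <- plant_outcome(generate_cohort(spec, seed = 13),
                     planted_tree_spec(), seed = 14)
  dir <- withr::local_tempdir()
  write_emr_bundle(b, dir)
  expect_true(all(file.exists(file.path(
    dir, c("patients.csv", "prescriptions.csv", "diagnoses.csv",
           "encounters.csv", "truth.json")))))
  b2 <- read_emr_bundle(dir)
  expect_equal(b2$patients, b$patients)
  expect_equal(nrow(b2$prescriptions), nrow(b$prescriptions))
  expect_equal(attr(b2, "truth")$leaf, attr(b, "truth")$leaf)
})
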
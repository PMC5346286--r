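# End-to-end orchestration: simulate -> build cohort -> univariable
# screen -> classification tree -> prospective validation, with every
# artefact written to disk and a manifest capturing the configuration
# and seeds needed to reproduce the bundle byte-for-byte.

#' Naive exposed-vs-unexposed comparison
#'
#' The crude comparison that motivates the single-group design:
#' subjects with any 5a-RI prescription versus all others, compared on
#' crude effect indicators (any ED code, any PDE5-inhibitor
#' prescription, any low-libido code), with the full 2x2 effect
#' metrics per effect.
#'
#' @param bundle An `odacta_emr` (typically after [select_eligible()]).
#' @param dict Code dictionary.
#' @return Tibble: one row per effect with counts and metrics.
#' @export
naive_analysis <- function(bundle, dict = default_code_sets()) {
  ids <- bundle$patients$patient_id
  exposed_ids <- unique(bundle$prescriptions$patient_id[
    bundle$prescriptions$class == "5ari"])
  exposed <- ids %in% exposed_ids
  effect_ids <- list(
    ed = unique(bundle$diagnoses$patient_id[
      bundle$diagnoses$code %in% dict$diagnoses$ed]),
    pde5i = unique(bundle$prescriptions$patient_id[
      bundle$prescriptions$class == "pde5i"]),
    low_libido = unique(bundle$diagnoses$patient_id[
      bundle$diagnoses$code %in% dict$diagnoses$low_libido]))
  purrr::imap(effect_ids, function(eids, nm) {
    eff <- ids %in% eids
    counts <- counts_2x2(a = sum(exposed & eff), b = sum(exposed & !eff),
                         c = sum(!exposed & eff), d = sum(!exposed & !eff))
    dplyr::bind_cols(tibble::tibble(effect = nm),
                     metrics_from_counts(counts),
                     tibble::tibble(p_value = binary_attribute_p(counts)))
  }) |>
    dplyr::bind_rows()
}

#' Pipeline run configuration
#'
#' @param synthetic An `odacta_synth_spec` describing the cohort to
#'   simulate, or `NULL` when reading `input_dir`.
#' @param planted An `odacta_planted_spec` for the outcome model
#'   (simulation only).
#' @param input_dir Directory holding an EMR bundle to read instead of
#'   simulating.
#' @param outcome `"ed"`, `"low_libido"` or `"ped"`.
#' @param alpha,screen_mode,tree_mode,min_leaf_frac,max_depth,n_mc
#'   Analysis settings (see [univariable_screen()], [fit_cta()]).
#' @param pde5i_window_days,min_persistence_days Case-definition
#'   settings.
#' @param window Study window (length-2 Date).
#' @param holdout_cutoff Cutoff date for the temporal holdout; `NULL`
#'   places it `holdout_days` before the window end.
#' @param holdout_days Validation interval length.
#' @param seed Master seed; stage streams are derived from it.
#' @param output_dir Where [run_pipeline()] writes its artefacts.
#' @return A list of class `odacta_config`.
#' @export
run_config <- function(synthetic = synthetic_spec(),
                       planted = planted_tree_spec(),
                       input_dir = NULL,
                       outcome = "ped", alpha = 0.05,
                       screen_mode = "generalized",
                       tree_mode = "greedy",
                       min_leaf_frac = 0.10, max_depth = 4L,
                       n_mc = 999L,
                       pde5i_window_days = 90L,
                       min_persistence_days = 90L,
                       window = c(as.Date("1992-01-01"),
                                  as.Date("2015-09-30")),
                       holdout_cutoff = NULL, holdout_days = 183L,
                       seed = 1L, output_dir = tempfile("odacta_run_")) {
  structure(list(synthetic = synthetic, planted = planted,
                 input_dir = input_dir, outcome = outcome, alpha = alpha,
                 screen_mode = screen_mode, tree_mode = tree_mode,
                 min_leaf_frac = min_leaf_frac,
                 max_depth = as.integer(max_depth), n_mc = as.integer(n_mc),
                 pde5i_window_days = as.integer(pde5i_window_days),
                 min_persistence_days = as.integer(min_persistence_days),
                 window = as.Date(window),
                 holdout_cutoff = holdout_cutoff,
                 holdout_days = as.integer(holdout_days),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "odacta_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> eligibility -> exposed cohort ->
#' analysis table -> naive comparison -> univariable screen ->
#' classification tree -> temporal-holdout validation, writing
#' `cohort_flow.json`, `analysis_table.csv`, `naive_analysis.csv`, `screen.csv`,
#' `tree.json`, `tree.txt`, `validation.csv` and `manifest.json` to
#' `config$output_dir`. A failure in any stage aborts with the stage
#' name and removes the partial outputs.
#'
#' @param config An [run_config()] object.
#' @return Invisibly, a list with the bundle, tables, screen, model,
#'   validation metrics and the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort_odacta(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   "odacta_stage_error")
    })
  }
  dict <- default_code_sets()

  bundle <- stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_emr_bundle(config$input_dir)
    } else {
      b <- generate_cohort(config$synthetic, seed = config$seed)
      plant_outcome(b, config$planted, seed = config$seed + 1L,
                    study_end = config$window[2])
    }
  })

  eligible <- stage("build-cohort",
                    select_eligible(bundle, window = config$window))
  cohort <- stage("build-cohort",
                  select_exposed_no_prior_dysfunction(eligible, dict = dict))
  flow <- list(eligibility = attr(eligible, "cohort_flow"),
               exposed_no_prior = nrow(cohort$patients))

  table <- stage("build-cohort", build_analysis_table(
    cohort, outcome = config$outcome, dict = dict, window = config$window,
    pde5i_window_days = config$pde5i_window_days,
    min_persistence_days = config$min_persistence_days))

  naive <- stage("naive-analysis", naive_analysis(eligible, dict = dict))

  screen <- stage("screen", univariable_screen(
    table, outcome = "outcome", predictors = analysis_predictors(table),
    alpha = config$alpha, mode = config$screen_mode, n_mc = config$n_mc,
    seed = config$seed + 100L))

  model <- stage("fit-tree", fit_cta(
    table, outcome = "outcome", predictors = analysis_predictors(table),
    alpha = config$alpha, min_leaf_frac = config$min_leaf_frac,
    max_depth = config$max_depth, mode = config$tree_mode,
    n_mc = config$n_mc, seed = config$seed + 200L))

  validation <- stage("validate", {
    cutoff <- config$holdout_cutoff %||%
      (config$window[2] - config$holdout_days - 1L)
    split <- temporal_holdout(cohort, cutoff = cutoff,
                              holdout_days = config$holdout_days,
                              outcome = config$outcome, dict = dict,
                              window = config$window,
                              pde5i_window_days = config$pde5i_window_days,
                              min_persistence_days = config$min_persistence_days)
    if (length(unique(split$holdout$outcome)) < 2L) {
      tibble::tibble(note = "holdout lacks both outcome classes")
    } else {
      validate_holdout(model, split$holdout)
    }
  })

  stage("report", {
    emit("cohort_flow.json", function(p) jsonlite::write_json(
      flow, p, auto_unbox = TRUE, digits = NA))
    emit("analysis_table.csv", function(p) readr::write_csv(table, p))
    emit("naive_analysis.csv", function(p) readr::write_csv(naive, p))
    emit("screen.csv", function(p) readr::write_csv(
      tibble::as_tibble(screen), p))
    emit("tree.json", function(p) cta_to_json(model, p))
    emit("tree.txt", function(p) {
      con <- file(p, "w"); sink(con); print(model); sink(); close(con)
    })
    emit("validation.csv", function(p) readr::write_csv(validation, p))
    emit("manifest.json", function(p) jsonlite::write_json(
      list(package = "odacta",
           version = as.character(utils::packageVersion("odacta")),
           r_version = R.version.string,
           seed = config$seed,
           outcome = config$outcome, alpha = config$alpha,
           screen_mode = config$screen_mode, tree_mode = config$tree_mode,
           min_leaf_frac = config$min_leaf_frac,
           max_depth = config$max_depth, n_mc = config$n_mc,
           pde5i_window_days = config$pde5i_window_days,
           min_persistence_days = config$min_persistence_days,
           window = as.character(config$window),
           synthetic_n = if (is.null(config$input_dir))
             config$synthetic$n_subjects else NA,
           input_dir = config$input_dir %||% NA),
      p, auto_unbox = TRUE, digits = NA, null = "null"))
  })

  invisible(list(bundle = bundle, cohort = cohort, table = table,
                 naive = naive, screen = screen, model = model,
                 validation = validation, output_dir = outdir))
}
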
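# Planted threshold-tree outcome model.  Risks of persistent erectile
# dysfunction (PED) are attached to the leaves of a small decision tree
# over subject attributes; transient erectile dysfunction (ED) and low
# libido are layered on so the full trigger-tool machinery (diagnosis +
# PDE5-inhibitor "antidote" + documented persistence) has events to
# find.  Outcome draws use their own random stream (the `seed` given
# here), so one generated cohort can host several planted models.

#' Specification of a planted outcome tree
#'
#' @param tree Nested list of nodes. An internal node is
#'   `list(attribute =, type = "binary"|"ordered", cutpoint = (ordered
#'   only), yes =, no =)`; a leaf is `list(leaf = "<id>", risk = p)`
#'   with `risk` the per-subject PED probability. The default plants
#'   the three-variable structure the package's tree fitter is
#'   evaluated against: prostate disease; among men without it,
#'   cumulative 5a-RI exposure beyond 208.5 days; and among the
#'   long-exposed, prescription NSAID use. Default leaf risks are
#'   anchored to the emulated cohort's published endpoint rates (2.1%
#'   for the no-prostate-disease/long-exposure/NSAID stratum; a risk
#'   difference of 1/59.8 against short exposure; 2.5% for prostate
#'   disease, its published positive predictive value).
#' @param persistence_meanlog,persistence_sdlog Log-normal parameters
#'   of planted PED persistence (days after stopping); defaults target
#'   the published median 1,348 and IQR 631.5-2,320.5 days.
#' @param persistence_given_ed P(new ED becomes persistent), published
#'   167/530 = 0.315; transient-ED risk per leaf is scaled so the leaf
#'   PED risk divided by total ED risk equals this.
#' @param exposed_low_libido Flat new-low-libido probability for
#'   exposed subjects.
#' @param unexposed_ed,unexposed_low_libido Background event
#'   probabilities for unexposed subjects (naive-comparison scale).
#' @return A validated list of class `odacta_planted_spec`.
#' @export
planted_tree_spec <- function(
    tree = list(
      attribute = "prostate_disease", type = "binary",
      yes = list(leaf = "prostate", risk = 0.025),
      no = list(
        attribute = "exposure_days", type = "ordered", cutpoint = 208.5,
        no = list(leaf = "short_exposure", risk = 0.0043),
        yes = list(
          attribute = "nsaid", type = "binary",
          yes = list(leaf = "long_nsaid", risk = 0.021),
          no = list(leaf = "long_no_nsaid", risk = 0.009)))),
    persistence_meanlog = log(1348),
    persistence_sdlog = 0.4825,
    persistence_given_ed = 0.315,
    exposed_low_libido = 0.013,
    unexposed_ed = 0.021,
    unexposed_low_libido = 0.008) {
  spec <- structure(
    list(tree = tree,
         persistence_meanlog = persistence_meanlog,
         persistence_sdlog = persistence_sdlog,
         persistence_given_ed = persistence_given_ed,
         exposed_low_libido = exposed_low_libido,
         unexposed_ed = unexposed_ed,
         unexposed_low_libido = unexposed_low_libido),
    class = "odacta_planted_spec")
  validate_planted_spec(spec)
  spec
}

validate_planted_spec <- function(spec) {
  risks <- planted_leaves(spec$tree)$risk
  probs <- c(risks, spec$persistence_given_ed, spec$exposed_low_libido,
             spec$unexposed_ed, spec$unexposed_low_libido)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort_odacta("All planted probabilities must lie in [0, 1].",
                 "odacta_config_error")
  }
  walk <- function(node) {
    if (!is.null(node$leaf)) return(invisible())
    if (is.null(node$attribute) || is.null(node$yes) || is.null(node$no)) {
      abort_odacta("Planted tree node needs attribute, yes and no branches.",
                   "odacta_config_error")
    }
    if (identical(node$type, "ordered") && is.null(node$cutpoint)) {
      abort_odacta("Ordered planted node needs a cutpoint.",
                   "odacta_config_error")
    }
    walk(node$yes); walk(node$no)
  }
  walk(spec$tree)
  invisible(spec)
}

planted_leaves <- function(tree) {
  if (!is.null(tree$leaf)) {
    return(tibble::tibble(leaf = tree$leaf, risk = tree$risk))
  }
  dplyr::bind_rows(planted_leaves(tree$yes), planted_leaves(tree$no))
}

#' Planted variable set of a planted-outcome spec
#'
#' @param spec An `odacta_planted_spec`.
#' @return Character vector of attributes used by the planted tree.
#' @export
planted_variables <- function(spec) {
  out <- character()
  walk <- function(node) {
    if (!is.null(node$leaf)) return(invisible())
    out <<- c(out, node$attribute)
    walk(node$yes); walk(node$no)
  }
  walk(spec$tree)
  unique(out)
}

# route subjects (rows of an attribute table) to planted leaves
route_planted <- function(attrs, tree) {
  leaf <- character(nrow(attrs))
  risk <- numeric(nrow(attrs))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (!is.null(node$leaf)) {
      leaf[idx] <<- node$leaf
      risk[idx] <<- node$risk
      return(invisible())
    }
    x <- attrs[[node$attribute]][idx]
    if (is.null(attrs[[node$attribute]])) {
      abort_odacta(sprintf("Planted attribute '%s' cannot be resolved from the cohort.",
                           node$attribute),
                   "odacta_config_error")
    }
    cond <- if (identical(node$type, "ordered")) {
      !is.na(x) & x > node$cutpoint
    } else {
      !is.na(x) & x == 1
    }
    rec(node$yes, idx[cond])
    rec(node$no, idx[!cond])
  }
  rec(tree, seq_len(nrow(attrs)))
  tibble::tibble(leaf = leaf, leaf_risk = risk)
}

#' Plant adverse-event outcomes on a generated cohort
#'
#' Routes every exposed subject through the planted threshold tree
#' (attributes are resolved with the same rules the cohort builder
#' uses: code presence for binary attributes, interval-union covered
#' days for `exposure_days`, age at last encounter for `age`), draws
#' PED at the leaf risk, transient ED so that
#' P(PED | ED) = `persistence_given_ed`, and low libido at a flat
#' rate; unexposed subjects receive background ED/low-libido events.
#' Event records are appended to the bundle's diagnosis, prescription
#' and encounter tables:
#' \itemize{
#'   \item ED: an ED diagnosis shortly after the last supply end, a
#'     contemporaneous PDE5-inhibitor prescription, and an encounter.
#'   \item PED: follow-up ED documentation every ~180 days out to the
#'     planted persistence (clamped to the study window), so the
#'     >= 90-day rule can fire on structured records alone.
#'   \item transient ED: an explicit resolution code 10-80 days after
#'     stopping (persistence below the 90-day criterion).
#' }
#'
#' @param bundle An `odacta_emr` from [generate_cohort()].
#' @param planted An `odacta_planted_spec`.
#' @param seed Integer seed for the outcome stream (separate from the
#'   cohort stream).
#' @param study_end Last date documentation may carry (defaults to the
#'   generator's study end when the bundle records it).
#' @return The bundle with outcome records appended and a `truth`
#'   attribute: per exposed subject, leaf id, leaf risk, planted
#'   `ped`/`ed`/`low_libido` flags and planted `persistence_days`.
#' @export
plant_outcome <- function(bundle, planted = planted_tree_spec(), seed = 1L,
                          study_end = as.Date("2015-09-30")) {
  validate_planted_spec(planted)
  withr::with_seed(seed, plant_outcome_impl(bundle, planted, study_end))
}

plant_outcome_impl <- function(bundle, planted, study_end) {
  dict <- default_code_sets()
  strat <- attr(bundle, "stratum")
  if (is.null(strat)) {
    exp_sum <- exposure_summary(bundle$prescriptions, drug_class = "5ari")
    strat <- tibble::tibble(patient_id = bundle$patients$patient_id,
                            exposed = bundle$patients$patient_id %in%
                              exp_sum$patient_id)
  }
  exposed_ids <- strat$patient_id[strat$exposed]

  new_dx <- list(); new_rx <- list(); new_enc <- list()

  truth <- NULL
  if (length(exposed_ids)) {
    attrs <- planted_attributes(bundle, exposed_ids, dict)
    routed <- route_planted(attrs, planted$tree)
    nE <- length(exposed_ids)
    ped <- stats::runif(nE) < routed$leaf_risk
    p_tr <- routed$leaf_risk *
      (1 / planted$persistence_given_ed - 1)
    transient <- !ped & stats::runif(nE) < pmin(p_tr, 1)
    ll <- stats::runif(nE) < planted$exposed_low_libido
    persistence <- rep(NA_real_, nE)
    persistence[ped] <- pmax(90, round(stats::rlnorm(
      sum(ped), planted$persistence_meanlog, planted$persistence_sdlog)))

    ed_any <- ped | transient
    if (any(ed_any)) {
      stop_d <- attrs$last_supply_end[ed_any]
      onset <- pmin(stop_d + sample(0:60, sum(ed_any), replace = TRUE),
                    study_end - 1L)
      ev <- tibble::tibble(patient_id = exposed_ids[ed_any],
                           onset = onset, stop = stop_d,
                           ped = ped[ed_any],
                           persistence = persistence[ed_any])
      new_dx$ed <- tibble::tibble(patient_id = ev$patient_id,
                                  code = dict$diagnoses$ed[[1]],
                                  date = ev$onset)
      new_rx$pde5i <- tibble::tibble(
        patient_id = ev$patient_id, drug = "sildenafil", class = "pde5i",
        daily_dose_mg = 50,
        start_date = pmax(ev$onset + sample(-14:14, nrow(ev), replace = TRUE),
                          dict$drugs$sildenafil$approval),
        days_supply = 30L)
      new_enc$ed <- tibble::tibble(patient_id = ev$patient_id, date = ev$onset)

      # persistent cases: periodic follow-up documentation of unresolved ED
      pp <- ev[ev$ped, , drop = FALSE]
      if (nrow(pp)) {
        doc <- purrr::pmap(
          list(pp$patient_id, pp$onset, pp$stop, pp$persistence),
          function(pid, onset, stop, pers) {
            last <- stop + pers
            follow <- if (onset + 180L <= last) {
              seq(onset + 180L, last, by = 180L)
            } else {
              numeric(0)
            }
            dates <- unique(pmin(c(follow, last), study_end))
            dates <- dates[dates > onset]
            tibble::tibble(patient_id = pid,
                           date = as.Date(dates, origin = "1970-01-01"))
          })
        doc <- dplyr::bind_rows(doc)
        new_dx$ed_doc <- tibble::tibble(patient_id = doc$patient_id,
                                        code = dict$diagnoses$ed[[1]],
                                        date = doc$date)
        new_enc$ed_doc <- doc
      }
      # transient cases resolve before the 90-day criterion
      tt <- ev[!ev$ped, , drop = FALSE]
      if (nrow(tt)) {
        res_date <- pmin(tt$stop + sample(10:80, nrow(tt), replace = TRUE),
                         study_end)
        res_date <- pmax(res_date, tt$onset + 1L)
        new_dx$ed_res <- tibble::tibble(patient_id = tt$patient_id,
                                        code = dict$diagnoses$ed_resolved[[1]],
                                        date = res_date)
        new_enc$ed_res <- tibble::tibble(patient_id = tt$patient_id,
                                         date = res_date)
      }
    }
    if (any(ll)) {
      ll_date <- pmin(attrs$last_supply_end[ll] +
                        sample(0:120, sum(ll), replace = TRUE),
                      study_end - 1L)
      new_dx$ll <- tibble::tibble(patient_id = exposed_ids[ll],
                                  code = dict$diagnoses$low_libido[[1]],
                                  date = ll_date)
      new_enc$ll <- tibble::tibble(patient_id = exposed_ids[ll],
                                   date = ll_date)
    }
    truth <- tibble::tibble(
      patient_id = exposed_ids, leaf = routed$leaf,
      leaf_risk = routed$leaf_risk, ped = ped, ed = ed_any,
      low_libido = ll, persistence_days = persistence)
  }

  # background events among the unexposed
  unexp <- strat[!strat$exposed, , drop = FALSE]
  if (nrow(unexp)) {
    bg_ed <- stats::runif(nrow(unexp)) < planted$unexposed_ed
    bg_ll <- stats::runif(nrow(unexp)) < planted$unexposed_low_libido
    era <- max(default_code_sets()$drugs$sildenafil$approval,
               min(unexp$entry %||% study_end - 1000L))
    if (any(bg_ed)) {
      d <- pmax(unexp$entry[bg_ed], era) +
        sample(0:900, sum(bg_ed), replace = TRUE)
      d <- pmin(d, study_end - 1L)
      new_dx$bg_ed <- tibble::tibble(patient_id = unexp$patient_id[bg_ed],
                                     code = dict$diagnoses$ed[[1]], date = d)
      new_rx$bg_pde5i <- tibble::tibble(
        patient_id = unexp$patient_id[bg_ed], drug = "sildenafil",
        class = "pde5i", daily_dose_mg = 50,
        start_date = pmax(d + 7L, dict$drugs$sildenafil$approval),
        days_supply = 30L)
    }
    if (any(bg_ll)) {
      d <- pmin(unexp$entry[bg_ll] + sample(0:900, sum(bg_ll), replace = TRUE),
                study_end - 1L)
      new_dx$bg_ll <- tibble::tibble(patient_id = unexp$patient_id[bg_ll],
                                     code = dict$diagnoses$low_libido[[1]],
                                     date = d)
    }
  }

  bundle$diagnoses <- dplyr::arrange(
    dplyr::bind_rows(c(list(bundle$diagnoses), new_dx)),
    .data$patient_id, .data$date)
  if (length(new_rx)) {
    bundle$prescriptions <- dplyr::arrange(
      dplyr::bind_rows(c(list(bundle$prescriptions), new_rx)),
      .data$patient_id, .data$start_date)
  }
  if (length(new_enc)) {
    bundle$encounters <- dplyr::arrange(
      dplyr::bind_rows(c(list(bundle$encounters), new_enc)),
      .data$patient_id, .data$date)
  }
  attr(bundle, "truth") <- truth
  attr(bundle, "planted_params") <- list(
    leaves = planted_leaves(planted$tree),
    variables = planted_variables(planted),
    persistence_median = exp(planted$persistence_meanlog),
    persistence_given_ed = planted$persistence_given_ed)
  bundle
}

# Resolve the attribute table the planted tree may reference, using the
# same rules as the cohort builder.
planted_attributes <- function(bundle, ids, dict) {
  exp_sum <- exposure_summary(
    dplyr::filter(bundle$prescriptions, .data$patient_id %in% ids),
    drug_class = "5ari", dict = dict)
  base <- tibble::tibble(patient_id = ids)
  base <- dplyr::left_join(base, exp_sum, by = "patient_id")
  last_enc <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(bundle$encounters, .data$patient_id %in% ids),
      .data$patient_id),
    last_enc = max(.data$date), .groups = "drop")
  base <- dplyr::left_join(base, last_enc, by = "patient_id")
  born <- stats::setNames(bundle$patients$birth_date,
                          bundle$patients$patient_id)
  base$age <- as.numeric(base$last_enc - born[base$patient_id]) / 365.25
  base$exposure_days <- base$covered_days
  # binary attributes: any qualifying code / prescription, any date
  for (at in setdiff(names(dict$diagnoses),
                     c("ed", "ed_resolved", "low_libido", "wellness"))) {
    with_code <- unique(bundle$diagnoses$patient_id[
      bundle$diagnoses$code %in% dict$diagnoses[[at]]])
    base[[at]] <- as.integer(base$patient_id %in% with_code)
  }
  drug_classes <- unique(purrr::map_chr(dict$drugs, "class"))
  for (cl in setdiff(drug_classes, c("5ari", "pde5i"))) {
    with_rx <- unique(bundle$prescriptions$patient_id[
      bundle$prescriptions$class == cl])
    base[[cl]] <- as.integer(base$patient_id %in% with_rx)
  }
  base
}
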
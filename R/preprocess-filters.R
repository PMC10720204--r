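# Participant and metabolite quality-control filters with auditable
# exclusion logs. Participant missingness uses >= 20% while the metabolite
# rule uses strictly > 20%; the asymmetry is deliberate.

#' Quality-control filter thresholds
#'
#' Sex-specific daily energy-intake plausibility bounds (kcal/day) and
#' missingness thresholds: participants with at least
#' `participant_missing_metabolite_threshold` missing metabolites are
#' excluded, metabolites with strictly more than
#' `metabolite_missing_threshold` missing values are dropped.
#'
#' @param energy_low_female,energy_low_male,energy_high_female,energy_high_male
#'   Bounds in kcal/day (defaults 500, 800, 3500, 4000).
#' @param participant_missing_metabolite_threshold Inclusive threshold
#'   (default 0.20).
#' @param metabolite_missing_threshold Exclusive threshold (default 0.20).
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(energy_low_female = 500, energy_low_male = 800,
                         energy_high_female = 3500, energy_high_male = 4000,
                         participant_missing_metabolite_threshold = 0.20,
                         metabolite_missing_threshold = 0.20) {
  stopifnot(energy_low_female > 0, energy_low_male > 0,
            energy_low_female < energy_low_male,
            energy_high_female < energy_high_male,
            participant_missing_metabolite_threshold > 0,
            metabolite_missing_threshold > 0)
  structure(list(
    energy_low_female = energy_low_female,
    energy_low_male = energy_low_male,
    energy_high_female = energy_high_female,
    energy_high_male = energy_high_male,
    participant_missing_metabolite_threshold = participant_missing_metabolite_threshold,
    metabolite_missing_threshold = metabolite_missing_threshold),
    class = "filter_rules")
}

.log_row <- function(stage, rule, ids) {
  tibble::tibble(stage = stage, rule = rule,
                 ids_removed = list(ids), n_removed = length(ids))
}

#' Apply the participant exclusion flow
#'
#' Removes, in order: participants with missing FFQ intakes; participants
#' whose energy intake falls strictly below the sex-specific lower bound or
#' strictly above the upper bound; and participants with at least 20% missing
#' metabolite values. Each stage is recorded in an exclusion log.
#'
#' @param cohort Participant tibble with `participant_id`, `sex` (1 = female,
#'   0 = male), `energy`, and one or more `intake_*` FFQ columns.
#' @param metabolites Metabolite tibble aligned to `cohort` by
#'   `participant_id` (`NA` = missing).
#' @param rules A [filter_rules()].
#' @return List with `cohort` (retained rows), `metabolites` (same rows), and
#'   `log` (tibble: stage, rule, ids_removed, n_removed).
#' @export
#' @examples
#' r <- simulate_enrollment_roster(n_total = 60, n_ffq_missing = 2,
#'                                 n_energy_outlier = 2, n_high_missing = 1,
#'                                 seed = 3)
#' filter_participants(r$cohort, r$metabolites)$log
filter_participants <- function(cohort, metabolites, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  if (!"sex" %in% names(cohort)) oo_abort("cohort must contain a sex column")
  keep_visit <- if ("visit" %in% names(metabolites)) {
    metabolites$visit == "baseline"
  } else rep(TRUE, nrow(metabolites))
  met_b <- metabolites[keep_visit, , drop = FALSE]
  coh_b <- if ("visit" %in% names(cohort)) {
    cohort[cohort$visit == "baseline", , drop = FALSE]
  } else cohort
  if (!setequal(coh_b$participant_id, met_b$participant_id)) {
    oo_abort("cohort and metabolite participant ids are misaligned")
  }
  met_b <- met_b[match(coh_b$participant_id, met_b$participant_id), , drop = FALSE]

  log <- list()
  intake_cols <- grep("^intake_", names(coh_b), value = TRUE)
  if (length(intake_cols) == 0) oo_abort("no intake_* FFQ columns found")

  # stage 1: missing FFQ
  ffq_missing <- !complete.cases(coh_b[, intake_cols, drop = FALSE])
  log[[1]] <- .log_row("ffq", "missing FFQ intake at baseline",
                       coh_b$participant_id[ffq_missing])
  keep <- !ffq_missing

  # stage 2: sex-specific energy bounds (strict inequalities)
  if (any(keep) && anyNA(coh_b$sex[keep])) {
    oo_abort("sex is required for the energy plausibility rule")
  }
  lo <- ifelse(coh_b$sex == 1, rules$energy_low_female, rules$energy_low_male)
  hi <- ifelse(coh_b$sex == 1, rules$energy_high_female, rules$energy_high_male)
  energy_out <- keep & (coh_b$energy < lo | coh_b$energy > hi)
  log[[2]] <- .log_row("energy", "energy outside sex-specific bounds",
                       coh_b$participant_id[energy_out])
  keep <- keep & !energy_out

  # stage 3: >= 20% missing metabolites
  mm <- metabolite_matrix(met_b)
  frac_missing <- rowMeans(is.na(mm))
  high_missing <- keep &
    frac_missing >= rules$participant_missing_metabolite_threshold
  log[[3]] <- .log_row("metabolite_missingness",
                       ">= 20% missing metabolite values",
                       coh_b$participant_id[high_missing])
  keep <- keep & !high_missing

  kept_ids <- coh_b$participant_id[keep]
  list(cohort = cohort[cohort$participant_id %in% kept_ids, , drop = FALSE],
       metabolites = metabolites[metabolites$participant_id %in% kept_ids, ,
                                 drop = FALSE],
       log = dplyr::bind_rows(log))
}

#' Apply the metabolite quality-control filter
#'
#' Drops, in order: internal-standard metabolites, drug metabolites, and
#' metabolites with strictly more than 20% missing values. Column order of
#' survivors is preserved.
#'
#' @param metabolites Metabolite tibble (`participant_id` plus one column per
#'   metabolite, `NA` = missing).
#' @param annotations Annotation tibble with `metabolite`,
#'   `is_internal_standard`, `is_drug` covering every metabolite column.
#' @param rules A [filter_rules()].
#' @return List with `metabolites` (filtered), `annotations` (rows for
#'   survivors), and `log`.
#' @export
filter_metabolites <- function(metabolites, annotations, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  idcols <- intersect(c("participant_id", "visit"), names(metabolites))
  met_names <- setdiff(names(metabolites), idcols)
  if (!all(met_names %in% annotations$metabolite)) {
    oo_abort("annotations must cover every metabolite column")
  }
  ann <- annotations[match(met_names, annotations$metabolite), , drop = FALSE]

  log <- list()
  drop_is <- ann$is_internal_standard
  log[[1]] <- .log_row("internal_standard", "internal-standard metabolite",
                       met_names[drop_is])
  drop_drug <- !drop_is & ann$is_drug
  log[[2]] <- .log_row("drug", "drug metabolite", met_names[drop_drug])
  mm <- metabolite_matrix(metabolites)
  frac_missing <- colMeans(is.na(mm))
  drop_mm <- !drop_is & !drop_drug &
    frac_missing > rules$metabolite_missing_threshold
  log[[3]] <- .log_row("missingness", "> 20% missing values",
                       met_names[drop_mm])

  keep <- met_names[!(drop_is | drop_drug | drop_mm)]
  list(metabolites = metabolites[, c(idcols, keep), drop = FALSE],
       annotations = ann[ann$metabolite %in% keep, , drop = FALSE],
       log = dplyr::bind_rows(log))
}
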
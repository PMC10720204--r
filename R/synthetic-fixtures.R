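# Small synthetic fixtures shaped like the study's printed QC worked
# examples: an enrollment roster with known exclusion counts and an annotated
# metabolite panel with known flag counts.

#' Synthetic enrollment roster with known exclusion counts
#'
#' Builds a participant roster together with a small metabolite matrix in
#' which a chosen number of participants violate each exclusion rule
#' (missing FFQ data, sex-specific energy-intake outliers, and at least 20%
#' missing metabolites), with the violating groups disjoint. Defaults
#' reproduce the study-sized worked example: 1,882 enrolled, 11 + 30 + 4
#' excluded, 1,837 retained.
#'
#' @param n_total Roster size (default 1882).
#' @param n_ffq_missing Participants with missing FFQ intakes (default 11).
#' @param n_energy_outlier Participants outside the sex-specific energy
#'   bounds (default 30; split between too-low and too-high).
#' @param n_high_missing Participants with >= 20% missing metabolites
#'   (default 4).
#' @param n_metabolites Number of metabolite columns (default 50; enough to
#'   realise the 20% rule exactly).
#' @param seed Seed.
#' @return List with `cohort` and `metabolites` tibbles.
#' @export
simulate_enrollment_roster <- function(n_total = 1882, n_ffq_missing = 11,
                                       n_energy_outlier = 30,
                                       n_high_missing = 4,
                                       n_metabolites = 50, seed = 1L) {
  if (n_ffq_missing + n_energy_outlier + n_high_missing > n_total) {
    oo_abort("exclusion counts exceed roster size")
  }
  set.seed(seed)
  ids <- sprintf("R%05d", seq_len(n_total))
  sex <- rbinom(n_total, 1, 0.57)
  energy <- pmin(pmax(rnorm(n_total, 2280, 420), 900), 3400)
  intake <- pmax(0, rnorm(n_total, 40, 16))
  m <- matrix(rnorm(n_total * n_metabolites), n_total,
              dimnames = list(ids, sprintf("met_%03d", seq_len(n_metabolites))))

  bad <- sample(ids, n_ffq_missing + n_energy_outlier + n_high_missing)
  ffq_bad <- bad[seq_len(n_ffq_missing)]
  en_bad <- bad[n_ffq_missing + seq_len(n_energy_outlier)]
  mm_bad <- bad[n_ffq_missing + n_energy_outlier + seq_len(n_high_missing)]

  intake[ids %in% ffq_bad] <- NA_real_
  # half below the sex-specific lower bound, half above the upper bound
  lo <- en_bad[seq_len(floor(length(en_bad) / 2))]
  hi <- setdiff(en_bad, lo)
  energy[ids %in% lo] <- ifelse(sex[ids %in% lo] == 1, 400, 700)
  energy[ids %in% hi] <- ifelse(sex[ids %in% hi] == 1, 3600, 4100)
  # >= 20% missing metabolites for the flagged participants
  k <- ceiling(0.2 * n_metabolites)
  for (id in mm_bad) m[id, sample(n_metabolites, k)] <- NA_real_

  list(cohort = tibble::tibble(participant_id = ids, sex = sex,
                               energy = energy, intake_total_oo = intake),
       metabolites = dplyr::bind_cols(tibble::tibble(participant_id = ids),
                                      tibble::as_tibble(m)))
}

#' Synthetic annotated metabolite panel with known flag counts
#'
#' Builds a quantified-metabolite table plus annotations in which a chosen
#' number of columns are internal standards, drug metabolites, or carry more
#' than 20% missing values (disjoint groups). Defaults reproduce the
#' study-sized worked example: 400 quantified, 3 internal standards, 7 drugs,
#' 9 high-missing, 381 retained.
#'
#' @param n_metabolites Panel width (default 400).
#' @param n_internal_standard,n_drug,n_high_missing Flag counts
#'   (defaults 3, 7, 9).
#' @param n_participants Number of rows (default 100).
#' @param seed Seed.
#' @return List with `metabolites` and `annotations` tibbles.
#' @export
simulate_qc_panel <- function(n_metabolites = 400, n_internal_standard = 3,
                              n_drug = 7, n_high_missing = 9,
                              n_participants = 100, seed = 1L) {
  set.seed(seed)
  p <- n_metabolites
  nm <- sprintf("met_%03d", seq_len(p))
  ids <- sprintf("Q%04d", seq_len(n_participants))
  m <- matrix(rnorm(n_participants * p), n_participants, dimnames = list(ids, nm))
  flagged <- sample(p, n_internal_standard + n_drug + n_high_missing)
  is_is <- seq_len(p) %in% flagged[seq_len(n_internal_standard)]
  is_drug <- seq_len(p) %in% flagged[n_internal_standard + seq_len(n_drug)]
  hm <- flagged[n_internal_standard + n_drug + seq_len(n_high_missing)]
  k <- ceiling(0.2 * n_participants) + 1L # strictly greater than 20%
  for (j in hm) m[sample(n_participants, k), j] <- NA_real_
  list(metabolites = dplyr::bind_cols(tibble::tibble(participant_id = ids),
                                      tibble::as_tibble(m)),
       annotations = tibble::tibble(metabolite = nm, name = nm,
                                    class = "unknown",
                                    is_internal_standard = is_is,
                                    is_drug = is_drug))
}
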
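#' Simulation configuration for the synthetic cohort generator
#'
#' Collects and validates the parameters that control the synthetic
#' Mediterranean-trial cohort: its size, the sparse metabolite signal planted
#' behind each olive-oil exposure, the one-year repeat-visit autocorrelation,
#' missingness, and the survival process used for the nested case-cohort
#' designs.
#'
#' The planted signal is a linear relation `intake = sum_j w_j m_j + noise`
#' whose population R-squared equals `signal_r2` for each exposure (virgin
#' and common olive oil carry disjoint active sets; total olive oil is their
#' sum, so its active set is the union and its R-squared is again
#' `signal_r2` when the two subtype noises are independent).
#'
#' @param n_participants Number of participants (default 1800).
#' @param n_metabolites Number of annotated metabolites (default 381).
#' @param n_active_per_exposure Number of active metabolites planted behind
#'   each olive-oil subtype (default 20, so the total-olive-oil signal spans
#'   40 metabolites).
#' @param signal_r2 Population fraction of intake variance explained by the
#'   active metabolites, in `[0, 1)` (default 0.16).
#' @param visit_correlation Baseline to year-1 autocorrelation of the
#'   metabolite panel and of the intake reporting noise, in `[0, 1]`
#'   (default 0.82).
#' @param missing_rate Per-cell missingness probability for the metabolite
#'   matrix, in `[0, 0.2]` (default 0: the analysis-ready matrix; raise it to
#'   exercise the QC and imputation stages).
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`, where MAR ties the
#'   missingness rate to the total olive-oil intake tertile.
#' @param log_hr_per_sd True log hazard ratio per SD of the latent metabolite
#'   score in the survival generator (default `log(0.79)`).
#' @param subcohort_fraction Fraction of the cohort sampled into the
#'   case-cohort subcohort, in `(0, 1]` (default 0.4).
#' @param censoring_rate Target fraction of participants censored (default
#'   0.85).
#' @param block_size,block_cor Metabolite correlation structure:
#'   block-diagonal with blocks of `block_size` metabolites sharing pairwise
#'   correlation `block_cor` (defaults 10 and 0.3).
#' @param seed Integer seed; every generator consumes it so identical
#'   configurations reproduce identical tables.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 200, n_metabolites = 40,
#'                   n_active_per_exposure = 4, seed = 1)
sim_config <- function(n_participants = 1800,
                       n_metabolites = 381,
                       n_active_per_exposure = 20,
                       signal_r2 = 0.16,
                       visit_correlation = 0.82,
                       missing_rate = 0,
                       missing_mechanism = c("MCAR", "MAR"),
                       log_hr_per_sd = log(0.79),
                       subcohort_fraction = 0.4,
                       censoring_rate = 0.85,
                       block_size = 10,
                       block_cor = 0.3,
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  chk <- function(ok, what) if (!ok) oo_abort(paste0("invalid sim_config: ", what))
  chk(n_participants >= 10, "n_participants must be >= 10")
  chk(n_metabolites >= 2, "n_metabolites must be >= 2")
  chk(2 * n_active_per_exposure <= n_metabolites,
      "n_active_per_exposure too large: the two subtype active sets are disjoint")
  chk(signal_r2 >= 0 && signal_r2 < 1, "signal_r2 must lie in [0, 1)")
  chk(visit_correlation >= 0 && visit_correlation <= 1,
      "visit_correlation must lie in [0, 1]")
  chk(missing_rate >= 0 && missing_rate <= 0.2,
      "missing_rate must lie in [0, 0.2]")
  chk(is.finite(log_hr_per_sd), "log_hr_per_sd must be finite")
  chk(subcohort_fraction > 0 && subcohort_fraction <= 1,
      "subcohort_fraction must lie in (0, 1]")
  chk(censoring_rate >= 0 && censoring_rate <= 1,
      "censoring_rate must lie in [0, 1]")
  chk(block_cor >= 0 && block_cor < 1, "block_cor must lie in [0, 1)")
  structure(
    list(n_participants = as.integer(n_participants),
         n_metabolites = as.integer(n_metabolites),
         n_active_per_exposure = as.integer(n_active_per_exposure),
         signal_r2 = signal_r2,
         visit_correlation = visit_correlation,
         missing_rate = missing_rate,
         missing_mechanism = missing_mechanism,
         log_hr_per_sd = log_hr_per_sd,
         subcohort_fraction = subcohort_fraction,
         censoring_rate = censoring_rate,
         block_size = as.integer(block_size),
         block_cor = block_cor,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_participants, "participants x", x$n_metabolites,
      "metabolites;", x$n_active_per_exposure, "active/exposure, R2 =",
      x$signal_r2, "\n")
  invisible(x)
}
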
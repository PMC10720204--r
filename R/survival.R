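# Barlow-weighted case-cohort Cox models with robust (sandwich) variance.
# The Barlow construction expands the design into counting-process rows:
# subcohort non-cases carry weight 1/f over full follow-up, cases outside the
# subcohort enter just before their event with weight 1, and subcohort cases
# contribute a weight-1/f row before failure plus a weight-1 row at failure.
# The weighted partial likelihood is maximised by survival::coxph with
# Breslow ties and per-participant cluster robust variance.

#' Barlow weights and counting-process expansion for a case-cohort design
#'
#' @param design An `oo_cch_design` from [draw_case_cohort()] or
#'   [case_cohort_preset()].
#' @return Tibble with one or two rows per participant: `participant_id`,
#'   `tstart`, `tstop`, `event`, `weight`. The attribute
#'   `sampling_fraction` is carried over.
#' @export
barlow_weights <- function(design) {
  f <- attr(design, "sampling_fraction")
  if (is.null(f) || f <= 0) oo_abort("sampling fraction must be positive")
  d <- tibble::as_tibble(design)
  gaps <- diff(sort(unique(d$time)))
  eps <- if (length(gaps) > 0) min(gaps) / 2 else min(d$time) / 2
  eps <- min(eps, min(d$time) / 2)

  rows <- list()
  nc <- d[d$event == 0L, , drop = FALSE] # subcohort non-cases
  if (nrow(nc) > 0) {
    rows[[1]] <- tibble::tibble(participant_id = nc$participant_id,
                                tstart = 0, tstop = nc$time,
                                event = 0L, weight = 1 / f)
  }
  cs_out <- d[d$event == 1L & !d$in_subcohort, , drop = FALSE]
  if (nrow(cs_out) > 0) {
    rows[[2]] <- tibble::tibble(participant_id = cs_out$participant_id,
                                tstart = cs_out$time - eps, tstop = cs_out$time,
                                event = 1L, weight = 1)
  }
  cs_in <- d[d$event == 1L & d$in_subcohort, , drop = FALSE]
  if (nrow(cs_in) > 0) {
    rows[[3]] <- tibble::tibble(participant_id = cs_in$participant_id,
                                tstart = 0, tstop = cs_in$time - eps,
                                event = 0L, weight = 1 / f)
    rows[[4]] <- tibble::tibble(participant_id = cs_in$participant_id,
                                tstart = cs_in$time - eps, tstop = cs_in$time,
                                event = 1L, weight = 1)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, sampling_fraction = f)
}

# covariate sets for the nested model specifications (the conventional epidemiological sequence)
model_covariates <- function(model_id, exposure_intake = NULL) {
  m1 <- c("age", "sex", "ps1", "ps2")
  m2 <- c(m1, "bmi", "smoking", "alcohol", "I(alcohol^2)", "education",
          "physical_activity", "family_history_cvd", "dyslipidemia",
          "hypertension", "dyslipidemia_med", "hypertension_med")
  m3 <- c(m2, "vegetables", "fruits", "cereals", "nuts", "eggs", "legumes",
          "fish", "meat", "dairy")
  m4 <- c(m3, exposure_intake)
  switch(model_id, m1, m2, m3, m4)
}

#' Model specification for the nested covariate sequence
#'
#' Model 1 adjusts for age, sex and propensity scores (stratified by
#' intervention group and recruitment center); model 2 adds lifestyle and
#' clinical covariates including alcohol with a quadratic term; model 3 adds
#' the food groups; model 4 adds the self-reported intake of the exposure the
#' signature was derived from.
#'
#' @param model_id Integer 1-4.
#' @param exposure_intake Column name of the self-reported intake (model 4).
#' @param extra_adjustments Optional additional covariate names (e.g.
#'   `c("coffee", "tea")` for the sensitivity analysis).
#' @return List of class `oo_model_spec`.
#' @export
model_spec <- function(model_id, exposure_intake = NULL,
                       extra_adjustments = NULL) {
  stopifnot(model_id %in% 1:4)
  if (model_id == 4 && is.null(exposure_intake)) {
    oo_abort("model 4 requires the self-reported exposure intake column")
  }
  structure(list(model_id = as.integer(model_id),
                 covariates = c(model_covariates(model_id, exposure_intake),
                                extra_adjustments),
                 strata = c("intervention_group", "center")),
            class = "oo_model_spec")
}

.cch_formula <- function(spec, env = parent.frame()) {
  rhs <- paste(c("score", spec$covariates,
                 sprintf("strata(%s)", paste(spec$strata, collapse = ", "))),
               collapse = " + ")
  stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", rhs),
                    env = env)
}

.cch_data <- function(design, score, cohort, year1_mode = FALSE) {
  d <- tibble::as_tibble(design)
  if (year1_mode) {
    first_year_cases <- d$participant_id[d$event == 1L & d$time <= 1]
    d <- d[!(d$participant_id %in% first_year_cases), , drop = FALSE]
    if (nrow(d) == 0) oo_abort("no participants remain after year-1 exclusion")
  }
  if (sum(d$event) == 0) oo_abort("no events in the analysis sample")
  rows <- barlow_weights(structure(d,
    sampling_fraction = attr(design, "sampling_fraction")))
  if (year1_mode) { # delayed entry at the year-1 visit
    rows <- rows[rows$tstop > 1, , drop = FALSE]
    rows$tstart <- pmax(rows$tstart, 1)
  }
  if ("visit" %in% names(cohort)) {
    cohort <- cohort[cohort$visit == "baseline", , drop = FALSE]
  }
  stopifnot(length(score) == nrow(cohort))
  cov <- cohort
  cov$score_raw <- score
  dat <- dplyr::inner_join(rows, cov, by = "participant_id")
  # per-SD scaling on the analysis participants (one row per participant)
  ids <- !duplicated(dat$participant_id)
  s <- dat$score_raw[ids]
  dat$score <- (dat$score_raw - mean(s)) / sd(s)
  dat
}

#' Fit a Barlow-weighted case-cohort Cox model
#'
#' Maximises the weighted partial likelihood within intervention-group by
#' center strata, with Breslow tie handling and a robust sandwich variance
#' clustered on participant. The score enters per 1 SD (standardized on the
#' analysis sample).
#'
#' @param design An `oo_cch_design`.
#' @param score Signature score aligned to the baseline `cohort` rows.
#' @param cohort Baseline covariate tibble for the full cohort.
#' @param spec An [model_spec()].
#' @param outcome Outcome label.
#' @param year1_mode If `TRUE`, cases in the first year of follow-up are
#'   excluded and remaining participants enter the risk set at year 1.
#' @param ties Tie approximation (default `"breslow"`; `"efron"` available).
#' @return List of class `oo_cch_fit`: the `coxph` fit plus a one-row
#'   `result` tibble (HR per SD, robust 95% CI, p, cases, n, model id).
#' @export
fit_case_cohort_cox <- function(design, score, cohort, spec = model_spec(1),
                                outcome = "CVD", year1_mode = FALSE,
                                ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(spec, "oo_model_spec"))
  dat <- .cch_data(design, score, cohort, year1_mode)
  fit <- survival::coxph(.cch_formula(spec, environment()), data = dat,
                         weights = dat$weight, cluster = dat$participant_id,
                         ties = ties, x = FALSE, y = TRUE,
                         # simulated event times are continuous; do not let
                         # aeqSurv collapse the Barlow time-split intervals
                         control = survival::coxph.control(timefix = FALSE))
  if (!is.finite(fit$coefficients["score"])) {
    oo_abort("case-cohort Cox fit did not converge for the score term")
  }
  b <- fit$coefficients["score"]
  se <- sqrt(diag(fit$var))[which(names(fit$coefficients) == "score")]
  z <- b / se
  result <- tibble::tibble(
    outcome = outcome, model = spec$model_id,
    hr_per_sd = exp(b), ci_lower = exp(b - qnorm(0.975) * se),
    ci_upper = exp(b + qnorm(0.975) * se),
    p_value = 2 * pnorm(abs(z), lower.tail = FALSE),
    log_hr = unname(b), robust_se = se,
    n_cases = sum(dat$event), n_participants = length(unique(dat$participant_id)))
  structure(list(fit = fit, result = result, spec = spec,
                 outcome = outcome, year1_mode = year1_mode),
            class = "oo_cch_fit")
}

#' @export
print.oo_cch_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf("<oo_cch_fit> %s model %d: HR/SD %.3f (%.3f, %.3f), p = %.3g, %d cases / %d participants\n",
              r$outcome, r$model, r$hr_per_sd, r$ci_lower, r$ci_upper,
              r$p_value, r$n_cases, r$n_participants))
  invisible(x)
}

#' @export
tidy.oo_cch_fit <- function(x, ...) x$result

#' @export
glance.oo_cch_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, model = x$spec$model_id,
                 loglik = x$fit$loglik[2], n_events = x$result$n_cases,
                 n = x$result$n_participants, year1_mode = x$year1_mode)
}

#' Likelihood-ratio interaction test between score and intervention group
#'
#' Compares the weighted partial likelihoods of nested fits with and without
#' score-by-intervention-group product terms; the statistic
#' `2 * (logPL_full - logPL_reduced)` is referred to a chi-square with as
#' many degrees of freedom as product terms. With Barlow weights this is an
#' approximate (pseudo-likelihood) test, so a robust Wald test on the product
#' terms is reported alongside.
#'
#' @inheritParams fit_case_cohort_cox
#' @param interaction_factor Column defining the interaction (default
#'   `"intervention_group"`); when it is also a stratification variable it is
#'   removed from the strata of both nested fits so they stay comparable.
#' @return Tibble: `lr_statistic`, `df`, `p_value`, `wald_p`, `approximate`.
#' @export
interaction_lr_test <- function(design, score, cohort, spec = model_spec(1),
                                outcome = "CVD",
                                interaction_factor = "intervention_group") {
  dat <- .cch_data(design, score, cohort)
  if (length(unique(dat[[interaction_factor]])) < 2) {
    # no product terms exist: the nested fits coincide
    return(tibble::tibble(lr_statistic = 0, df = 0L, p_value = 1,
                          wald_p = NA_real_, approximate = TRUE))
  }
  strata <- setdiff(spec$strata, interaction_factor)
  strata_term <- if (length(strata) > 0) {
    sprintf("strata(%s)", paste(strata, collapse = ", "))
  } else NULL
  rhs0 <- paste(c("score", interaction_factor, spec$covariates, strata_term),
                collapse = " + ")
  rhs1 <- paste(c(sprintf("score * %s", interaction_factor), spec$covariates,
                  strata_term), collapse = " + ")
  f0 <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", rhs0),
                          env = environment())
  f1 <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", rhs1),
                          env = environment())
  ctl <- survival::coxph.control(timefix = FALSE)
  fit0 <- survival::coxph(f0, data = dat, weights = dat$weight,
                          cluster = dat$participant_id, ties = "breslow",
                          control = ctl)
  fit1 <- survival::coxph(f1, data = dat, weights = dat$weight,
                          cluster = dat$participant_id, ties = "breslow",
                          control = ctl)
  keep1 <- !is.na(fit1$coefficients)
  df <- sum(keep1) - sum(!is.na(fit0$coefficients))
  lr <- max(0, 2 * (fit1$loglik[2] - fit0$loglik[2]))
  if (df <= 0) {
    return(tibble::tibble(lr_statistic = 0, df = 0L, p_value = 1,
                          wald_p = NA_real_, approximate = TRUE))
  }
  # robust Wald on the product terms
  prod_idx <- which(grepl(":", names(fit1$coefficients)) & keep1)
  wald_p <- tryCatch({
    if (length(prod_idx) == 0) NA_real_ else {
      bb <- fit1$coefficients[prod_idx]
      vv <- fit1$var[prod_idx, prod_idx, drop = FALSE]
      stat <- as.numeric(t(bb) %*% solve(vv, bb))
      pchisq(stat, length(prod_idx), lower.tail = FALSE)
    }
  }, error = function(e) NA_real_)
  tibble::tibble(lr_statistic = lr, df = as.integer(df),
                 p_value = pchisq(lr, df, lower.tail = FALSE),
                 wald_p = wald_p, approximate = TRUE)
}

#' Run the nested model sequence for one outcome and signature
#'
#' Fits the requested nested specifications and returns a per-model
#' result tibble (one row per model).
#'
#' @inheritParams fit_case_cohort_cox
#' @param models Integer vector of model ids (default `1:3`; include 4 only
#'   with `exposure_intake`).
#' @param exposure_intake Self-reported intake column for model 4.
#' @param extra_adjustments Optional extra covariates (e.g. coffee and tea).
#' @return Tibble with one row per model.
#' @export
run_model_sequence <- function(design, score, cohort, outcome = "CVD",
                               models = 1:3, exposure_intake = NULL,
                               extra_adjustments = NULL, year1_mode = FALSE) {
  purrr::map_dfr(models, function(m) {
    sp <- model_spec(m, exposure_intake = exposure_intake,
                     extra_adjustments = extra_adjustments)
    fit_case_cohort_cox(design, score, cohort, sp, outcome = outcome,
                        year1_mode = year1_mode)$result
  })
}
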
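# Barlow-weighted case-cohort Cox models: weight construction, full-cohort
# reduction, brute-force partial-likelihood oracle, model sequence,
# interaction tests, year-1 mode.

# minimal specification: score only, single stratum (constant columns exist
# in the generated cohorts)
bare_spec <- function() {
  structure(list(model_id = 1L, covariates = character(0), strata = "one"),
            class = "oo_model_spec")
}

# spec with the generated cohort's stratification columns
bare_spec2 <- function(cohort) {
  structure(list(model_id = 1L, covariates = c("age", "sex"),
                 strata = c("intervention_group", "center")),
            class = "oo_model_spec")
}

toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(participant_id = sprintf("P%04d", seq_len(n)),
                 one = "all", age = rnorm(n, 67, 6), sex = rbinom(n, 1, 0.5))
}

test_that("Barlow weights follow the time-split construction", {
  d <- tibble::tibble(participant_id = c("a", "b", "c"),
                      time = c(5, 3, 4), event = c(0L, 1L, 1L),
                      in_subcohort = c(TRUE, TRUE, FALSE))
  d <- structure(d, sampling_fraction = 0.5, class = c("oo_cch_design", class(d)))
  w <- barlow_weights(d)
  # non-case in subcohort: one row, full follow-up, weight 1/f = 2
  a <- w[w$participant_id == "a", ]
  expect_equal(c(a$tstart, a$tstop, a$event, a$weight), c(0, 5, 0, 2))
  # subcohort case: weight-2 row before failure plus weight-1 row at failure
  b <- w[w$participant_id == "b", ]
  expect_equal(nrow(b), 2)
  expect_equal(b$weight[order(b$tstart)], c(2, 1))
  expect_equal(sum(b$event), 1)
  expect_equal(max(b$tstop), 3)
  # case outside subcohort: enters just before failure with weight 1
  cc <- w[w$participant_id == "c", ]
  expect_equal(nrow(cc), 1)
  expect_equal(cc$weight, 1)
  expect_lt(cc$tstart, 4)
  expect_true(all(w$weight > 0))
})

test_that("with full sampling the weighted fit equals an ordinary Cox model", {
  n <- 300
  coh <- toy_cohort(n, seed = 51)
  score <- rnorm(n)
  set.seed(52)
  time <- rexp(n, 0.05 * exp(-0.3 * score))
  event <- as.integer(time < quantile(time, 0.7))
  time <- pmin(time, quantile(time, 0.7))
  out <- tibble::tibble(participant_id = coh$participant_id,
                        time = time, event = event, outcome_name = "toy")
  design <- draw_case_cohort(out, 1, seed = 1)
  fit <- fit_case_cohort_cox(design, score, coh, bare_spec(), outcome = "toy")
  plain <- survival::coxph(survival::Surv(time, event) ~ scale(score),
                           ties = "breslow")
  expect_equal(fit$result$log_hr, unname(coef(plain)), tolerance = 1e-6)
})

test_that("the weighted fit maximises the partial likelihood (six-subject brute force)", {
  coh <- tibble::tibble(participant_id = paste0("s", 1:6), one = "all")
  x <- c(1, 0, 1, 0, 1, 0)
  out <- tibble::tibble(participant_id = coh$participant_id,
                        time = c(2, 3, 5, 7, 11, 13),
                        event = c(1L, 1L, 0L, 1L, 1L, 0L),
                        outcome_name = "toy")
  design <- draw_case_cohort(out, 1, seed = 1)
  fit <- fit_case_cohort_cox(design, x, coh, bare_spec(), outcome = "toy")
  # brute force on the standardized score, enumerating risk sets directly
  z <- (x - mean(x)) / sd(x)
  opt <- stats::optimize(function(b) -partial_loglik(b, out$time, out$event, z),
                         c(-10, 10), tol = 1e-10)
  expect_equal(fit$result$log_hr, opt$minimum, tolerance = 1e-6)
})

test_that("the per-SD hazard ratio is invariant to affine rescaling of the score", {
  n <- 250
  coh <- toy_cohort(n, seed = 53)
  score <- rnorm(n)
  cfg <- sim_config(seed = 53, censoring_rate = 0.6)
  out <- generate_outcomes(coh, score, cfg)
  design <- draw_case_cohort(out, 0.6, seed = 2)
  f1 <- fit_case_cohort_cox(design, score, coh, bare_spec())
  f2 <- fit_case_cohort_cox(design, 7 * score + 100, coh, bare_spec())
  expect_equal(f1$result$hr_per_sd, f2$result$hr_per_sd, tolerance = 1e-10)
  expect_equal(f1$result$robust_se, f2$result$robust_se, tolerance = 1e-10)
})

test_that("the nested model sequence runs against a generated case-cohort design", {
  cfg <- sim_config(n_participants = 600, n_metabolites = 20,
                    n_active_per_exposure = 3, seed = 54,
                    censoring_rate = 0.7, subcohort_fraction = 0.5)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  score <- true_score(sim, "total_oo")
  out <- generate_outcomes(b, score, cfg)
  design <- draw_case_cohort(out, cfg)
  res <- run_model_sequence(design, score, b, outcome = "CVD", models = 1:4,
                            exposure_intake = "intake_total_oo")
  expect_equal(res$model, 1:4)
  expect_true(all(res$hr_per_sd > 0))
  expect_true(all(res$ci_lower < res$hr_per_sd & res$hr_per_sd < res$ci_upper))
  expect_true(all(res$n_cases == sum(design$event)))
  # an extra independent noise covariate barely moves the estimate
  b2 <- b
  set.seed(99)
  b2$noise_cov <- rnorm(nrow(b))
  r3 <- fit_case_cohort_cox(design, score, b2, model_spec(3))$result
  r3n <- fit_case_cohort_cox(design, score, b2,
                             model_spec(3, extra_adjustments = "noise_cov"))$result
  expect_lt(abs(r3n$log_hr - r3$log_hr), 2 * r3$robust_se)
  # model 4 requires the intake column
  expect_error(model_spec(4), "intake")
})

test_that("year-1 mode drops first-year cases and matches the counting oracle", {
  cfg <- sim_config(n_participants = 800, n_metabolites = 20,
                    n_active_per_exposure = 3, seed = 55,
                    censoring_rate = 0.5, subcohort_fraction = 0.6)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  score <- rnorm(nrow(b))
  out <- generate_outcomes(b, score, cfg)
  design <- draw_case_cohort(out, cfg)
  f0 <- fit_case_cohort_cox(design, score, b, bare_spec2(b))
  f1 <- fit_case_cohort_cox(design, score, b, bare_spec2(b), year1_mode = TRUE)
  oracle <- sum(design$event == 1 & design$time > 1)
  expect_equal(f1$result$n_cases, oracle)
  expect_lt(f1$result$n_cases, f0$result$n_cases)
})

test_that("interaction likelihood-ratio test behaves at its boundary cases", {
  cfg <- sim_config(n_participants = 700, n_metabolites = 20,
                    n_active_per_exposure = 3, seed = 56,
                    censoring_rate = 0.6, subcohort_fraction = 0.7)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  score <- rnorm(nrow(b))
  out <- generate_outcomes(b, score, cfg)
  design <- draw_case_cohort(out, cfg)
  res <- interaction_lr_test(design, score, b, bare_spec2(b))
  expect_equal(res$df, 2L) # three intervention groups -> two product terms
  expect_gte(res$lr_statistic, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_true(res$approximate)
  # a single-level interaction factor has no product terms: LR = 0, p = 1
  b1 <- b
  b1$intervention_group <- "only"
  res1 <- interaction_lr_test(design, score, b1, bare_spec2(b1))
  expect_equal(res1$lr_statistic, 0)
  expect_equal(res1$p_value, 1)
})

test_that("robust standard errors exceed naive ones on average when f < 1", {
  ratios <- vapply(1:25, function(i) {
    n <- 400
    coh <- toy_cohort(n, seed = 6000 + i)
    score <- rnorm(n)
    time <- rexp(n, 0.05)
    event <- as.integer(runif(n) < 0.35)
    out <- tibble::tibble(participant_id = coh$participant_id,
                          time = time, event = event, outcome_name = "toy")
    design <- draw_case_cohort(out, 0.4, seed = 7000 + i)
    fit <- fit_case_cohort_cox(design, score, coh, bare_spec())$fit
    sqrt(diag(fit$var))[1] / sqrt(diag(fit$naive.var))[1]
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})
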
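# Synthetic cohort generator: determinism, planted-signal calibration,
# intake identities, missingness control, outcomes and case-cohort sampling.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_participants = 150, n_metabolites = 30,
             n_active_per_exposure = 4, seed = seed, ...)
}

test_that("the same seed reproduces bit-identical tables", {
  a <- generate_cohort(small_cfg(seed = 9))
  b <- generate_cohort(small_cfg(seed = 9))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_cfg(seed = 10))
  expect_false(identical(a$metabolites, c$metabolites))
})

test_that("intakes are non-negative and total olive oil is exactly the subtype sum", {
  sim <- generate_cohort(small_cfg(seed = 2))
  expect_true(all(sim$cohort$intake_voo >= 0))
  expect_true(all(sim$cohort$intake_coo >= 0))
  expect_identical(sim$cohort$intake_total_oo,
                   sim$cohort$intake_voo + sim$cohort$intake_coo)
  expect_setequal(unique(sim$cohort$visit), c("baseline", "year1"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_metabolites = 10, n_active_per_exposure = 8),
               "active")
  expect_error(sim_config(signal_r2 = 1), "signal_r2")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(subcohort_fraction = 0), "subcohort")
  expect_error(sim_config(visit_correlation = 1.2), "visit_correlation")
})

test_that("planted signal matches the configured R-squared (closed form r = sqrt(R2))", {
  cfg <- sim_config(n_participants = 10000, n_metabolites = 60,
                    n_active_per_exposure = 10, signal_r2 = 0.25, seed = 3)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  s <- true_score(sim, "total_oo")
  expect_lt(abs(cor(s, b$intake_total_oo)^2 - 0.25), 0.02)
  expect_lt(abs(cor(s, b$intake_total_oo) - 0.5), 0.02)
})

test_that("zero planted signal gives a null correlation", {
  cfg <- sim_config(n_participants = 2000, n_metabolites = 40,
                    n_active_per_exposure = 5, signal_r2 = 0, seed = 4)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  expect_lt(abs(cor(true_score(sim, "voo"), b$intake_voo)), 3 / sqrt(2000))
})

test_that("year-1 visit is autocorrelated at the configured level", {
  cfg <- sim_config(n_participants = 4000, n_metabolites = 30,
                    n_active_per_exposure = 4, visit_correlation = 0.7,
                    seed = 5)
  sim <- generate_cohort(cfg)
  m0 <- metabolite_matrix(sim$metabolites, "baseline")
  m1 <- metabolite_matrix(sim$metabolites, "year1")
  rho <- mean(vapply(1:30, function(j) cor(m0[, j], m1[, j]), numeric(1)))
  expect_lt(abs(rho - 0.7), 0.03)
})

test_that("missingness mask honours rate and mechanism", {
  sim0 <- generate_cohort(small_cfg(seed = 6, missing_rate = 0))
  expect_false(anyNA(sim0$metabolites))
  cfg <- sim_config(n_participants = 900, n_metabolites = 40,
                    n_active_per_exposure = 4, missing_rate = 0.1, seed = 6)
  sim <- generate_cohort(cfg)
  frac <- mean(is.na(metabolite_matrix(sim$metabolites, "baseline")))
  expect_lt(abs(frac - 0.1), 0.01)
  # MAR: missingness rises with total olive-oil intake tertile
  cfg_mar <- sim_config(n_participants = 900, n_metabolites = 40,
                        n_active_per_exposure = 4, missing_rate = 0.1,
                        missing_mechanism = "MAR", seed = 6)
  simm <- generate_cohort(cfg_mar)
  b <- simm$cohort[simm$cohort$visit == "baseline", ]
  m <- metabolite_matrix(simm$metabolites, "baseline")
  ter <- cut(b$intake_total_oo, quantile(b$intake_total_oo, 0:3 / 3),
             include.lowest = TRUE, labels = FALSE)
  by_ter <- tapply(rowMeans(is.na(m)), ter, mean)
  expect_lt(by_ter[1], by_ter[3])
})

test_that("survival outcomes follow the proportional-hazards construction", {
  cfg <- small_cfg(seed = 7, censoring_rate = 0.6)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  out <- generate_outcomes(b, rnorm(nrow(b)), cfg)
  expect_true(all(out$time > 0))
  expect_true(all(out$event %in% 0:1))
  expect_error(generate_outcomes(b, c(NA, rnorm(nrow(b) - 1)), cfg),
               "non-finite")
  # degenerate censoring: no events at all
  allc <- generate_outcomes(b, rnorm(nrow(b)),
                            small_cfg(seed = 7, censoring_rate = 1))
  expect_equal(sum(allc$event), 0)
})

test_that("a full-cohort Cox fit recovers the planted log hazard ratio", {
  cfg <- sim_config(n_participants = 20000, n_metabolites = 20,
                    n_active_per_exposure = 3, seed = 8,
                    log_hr_per_sd = log(0.79), censoring_rate = 0.7)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  score <- rnorm(nrow(b))
  out <- generate_outcomes(b, score, cfg)
  fit <- survival::coxph(survival::Surv(out$time, out$event) ~ scale(score))
  se <- sqrt(diag(fit$var))
  expect_lt(abs(coef(fit) - log(0.79)), 3 * se)
})

test_that("case-cohort sampling has the advertised size, determinism and uniformity", {
  cfg <- small_cfg(seed = 11, censoring_rate = 0.7, subcohort_fraction = 0.5)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  out <- generate_outcomes(b, rnorm(nrow(b)), cfg)
  d1 <- draw_case_cohort(out, cfg)
  expect_equal(sum(d1$in_subcohort), round(0.5 * nrow(out)))
  expect_identical(tibble::as_tibble(d1),
                   tibble::as_tibble(draw_case_cohort(out, cfg)))
  # fraction 1: every participant in the design
  dall <- draw_case_cohort(out, 1, seed = 1)
  expect_equal(nrow(dall), nrow(out))
  expect_true(all(dall$in_subcohort))
  expect_error(draw_case_cohort(out, 0), "\\(0, 1\\]")
  # uniform membership for non-cases over repeated draws
  noncase <- out$participant_id[out$event == 0]
  hits <- setNames(numeric(length(noncase)), noncase)
  n_draws <- 400
  for (i in seq_len(n_draws)) {
    d <- draw_case_cohort(out, 0.5, seed = 5000 + i)
    inside <- noncase %in% d$participant_id[d$in_subcohort]
    hits <- hits + inside
  }
  freq <- hits / n_draws
  band <- 3 * sqrt(0.5 * 0.5 / n_draws)
  expect_true(all(abs(freq - 0.5) <= band + 0.02))
  expect_lt(abs(mean(freq) - 0.5), 0.01)
})

test_that("the T2D emulation preset forces the printed case, subcohort and overlap counts", {
  cfg <- sim_config(seed = 12, censoring_rate = 0.75)
  sim <- generate_cohort(cfg)
  b <- sim$cohort[sim$cohort$visit == "baseline", ]
  out <- generate_outcomes(b, rnorm(nrow(b)), cfg, outcome_name = "T2D")
  d <- case_cohort_preset(out, "PREDIMED-T2D", seed = 13)
  expect_equal(sum(d$event == 1), 251)
  expect_equal(sum(d$in_subcohort), 694)
  expect_equal(sum(d$event == 1 & d$in_subcohort), 53)
  expect_equal(nrow(d), 251 + 694 - 53)
  tiny <- out[1:100, ]
  expect_error(case_cohort_preset(tiny, "PREDIMED-T2D"), "needs")
})
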
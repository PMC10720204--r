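# Participant/metabolite QC filters, pooled-reference standardization,
# Blom transformation, residual energy adjustment, forest imputation.

test_that("participant exclusion flow reproduces the study-sized worked example", {
  r <- simulate_enrollment_roster() # 1882 roster, 11 + 30 + 4 violations
  out <- filter_participants(r$cohort, r$metabolites)
  expect_equal(nrow(out$cohort), 1837)
  expect_equal(out$log$n_removed, c(11, 30, 4))
  expect_equal(sum(out$log$n_removed), nrow(r$cohort) - nrow(out$cohort))
})

test_that("participant filter matches a brute-force sequential scan", {
  r <- simulate_enrollment_roster(n_total = 300, n_ffq_missing = 7,
                                  n_energy_outlier = 12, n_high_missing = 3,
                                  n_metabolites = 25, seed = 7)
  out <- filter_participants(r$cohort, r$metabolites)
  # brute force: apply the three predicates one participant at a time
  keep <- logical(nrow(r$cohort))
  mm <- as.matrix(r$metabolites[, -1])
  for (i in seq_len(nrow(r$cohort))) {
    ffq_ok <- !is.na(r$cohort$intake_total_oo[i])
    lo <- if (r$cohort$sex[i] == 1) 500 else 800
    hi <- if (r$cohort$sex[i] == 1) 3500 else 4000
    en_ok <- r$cohort$energy[i] >= lo && r$cohort$energy[i] <= hi
    mm_ok <- mean(is.na(mm[i, ])) < 0.20
    keep[i] <- ffq_ok && en_ok && mm_ok
  }
  expect_equal(sort(out$cohort$participant_id),
               sort(r$cohort$participant_id[keep]))
})

test_that("participant filter is idempotent and the clean case is identity", {
  r <- simulate_enrollment_roster(n_total = 120, n_ffq_missing = 0,
                                  n_energy_outlier = 0, n_high_missing = 0,
                                  seed = 2)
  out <- filter_participants(r$cohort, r$metabolites)
  expect_identical(out$cohort, r$cohort)
  expect_true(all(out$log$n_removed == 0))

  r2 <- simulate_enrollment_roster(n_total = 200, seed = 3,
                                   n_ffq_missing = 5, n_energy_outlier = 4,
                                   n_high_missing = 2)
  once <- filter_participants(r2$cohort, r2$metabolites)
  twice <- filter_participants(once$cohort, once$metabolites)
  expect_true(all(twice$log$n_removed == 0))
  expect_equal(twice$cohort, once$cohort)
})

test_that("participant filter rejects malformed input", {
  r <- simulate_enrollment_roster(n_total = 50, n_ffq_missing = 1,
                                  n_energy_outlier = 1, n_high_missing = 1)
  bad_met <- r$metabolites
  bad_met$participant_id[1] <- "STRANGER"
  expect_error(filter_participants(r$cohort, bad_met), "misaligned")
  no_sex <- r$cohort[, setdiff(names(r$cohort), "sex")]
  expect_error(filter_participants(no_sex, r$metabolites), "sex")
})

test_that("metabolite QC filter reproduces the study-sized worked example", {
  panel <- simulate_qc_panel() # 400 columns: 3 IS + 7 drugs + 9 high-missing
  out <- filter_metabolites(panel$metabolites, panel$annotations)
  expect_equal(ncol(out$metabolites) - 1L, 381)
  expect_equal(out$log$n_removed, c(3, 7, 9))
  # survivors keep their original order
  expect_identical(setdiff(names(out$metabolites), "participant_id"),
                   intersect(setdiff(names(panel$metabolites), "participant_id"),
                             names(out$metabolites)))
})

test_that("metabolite missingness rule is strictly greater than 20%", {
  m <- rand_met(10, 3)
  m[1:2, 1] <- NA # exactly 20% -> retained
  m[1:3, 2] <- NA # 30% -> dropped
  tbl <- dplyr::bind_cols(tibble::tibble(participant_id = sprintf("P%02d", 1:10)),
                          tibble::as_tibble(m))
  ann <- tibble::tibble(metabolite = colnames(m), is_internal_standard = FALSE,
                        is_drug = FALSE)
  out <- filter_metabolites(tbl, ann)
  expect_setequal(setdiff(names(out$metabolites), "participant_id"),
                  c("met_001", "met_003"))
})

test_that("pooled-reference standardization follows the stated formula", {
  # constant references: identity
  out <- pooled_reference_standardize(c(5, 7), c(1, 2), c(3, 3, 3), c(0, 5, 10))
  expect_equal(out$value, c(5, 7))
  # hand computation: 12 / 10 * median(10, 20) = 18
  out <- pooled_reference_standardize(12, 2, c(10, 20), c(0, 10))
  expect_equal(out$value, 18)
  expect_equal(out$ref_position, 0)
  # equidistant sample uses the earlier reference
  out <- pooled_reference_standardize(12, 5, c(10, 20), c(0, 10))
  expect_equal(out$ref_position, 0)
  expect_equal(out$value, 12 / 10 * 15)
  # zero nearest reference: flagged unquantifiable, not an error
  out <- pooled_reference_standardize(12, 1, c(0, 20), c(0, 10))
  expect_true(out$unquantifiable)
  expect_true(is.na(out$value))
  expect_error(pooled_reference_standardize(1, 1, numeric(0), numeric(0)),
               "pooled reference")
})

test_that("Blom transformation maps ranks to normal quantiles", {
  out <- blom_transform(c(5, 1, 9))
  expect_equal(out[1], 0) # middle rank of 3: (2 - 3/8) / 3.25 = 0.5
  expect_equal(out[2], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(out[3], -out[2]) # symmetry
  # rank invariance under strictly monotone transforms
  set.seed(4)
  x <- rexp(200)
  expect_equal(blom_transform(x), blom_transform(log(x)))
  expect_equal(blom_transform(x), blom_transform(x^3))
  # ties get midranks
  out <- blom_transform(c(2, 2, 5))
  expect_equal(out[1], out[2])
  expect_error(blom_transform(rep(1, 10)), "constant")
})

test_that("Blom output converges to a standard normal and tracks normal scores", {
  set.seed(9)
  n <- 10000
  z <- blom_transform(rlnorm(n))
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(var(z) - 1), 0.01)
  scores <- qnorm((rank(z) - 0.5) / n) # independent normal-scores construction
  expect_gt(cor(z, scores), 0.999)
})

test_that("residual-method energy adjustment preserves units and kills the energy correlation", {
  # zero sample covariance: output equals input
  intake <- c(10, 20, 30)
  energy <- c(2000, 2500, 2000)
  expect_equal(energy_adjust_residual(intake, energy), intake)
  # collinear case: constant at the mean intake
  expect_equal(energy_adjust_residual(2 * energy, energy), rep(mean(2 * energy), 3))
  # brute-force normal-equations oracle
  set.seed(11)
  intake <- rnorm(80, 40, 10)
  energy <- rnorm(80, 2300, 400)
  got <- energy_adjust_residual(intake, energy)
  co <- ols_oracle(intake, energy)
  expect_equal(got, intake - co[1] - co[2] * energy + mean(intake),
               tolerance = 1e-10)
  expect_lt(abs(cor(got, energy)), 1e-10)
  # invariance to affine rescaling of energy units (kcal -> kJ)
  expect_equal(got, energy_adjust_residual(intake, energy * 4.184),
               tolerance = 1e-10)
  expect_error(energy_adjust_residual(intake, rep(2000, 80)), "constant")
  expect_error(energy_adjust_residual(1:2, 1:2), "at least 3")
})

test_that("forest imputation completes the matrix without touching observed cells", {
  m <- rand_met(60, 5, seed = 5)
  expect_identical(impute_missing(m), m) # nothing missing: identity
  miss <- m
  set.seed(6)
  holes <- cbind(sample(60, 12, replace = TRUE), sample(5, 12, replace = TRUE))
  miss[holes] <- NA
  out1 <- impute_missing(miss, seed = 42)
  out2 <- impute_missing(miss, seed = 42)
  expect_identical(out1, out2) # deterministic
  obs <- !is.na(miss)
  expect_identical(out1[obs], m[obs]) # observed cells bit-identical
  for (j in 1:5) { # imputations inside the observed range
    rng <- range(miss[, j], na.rm = TRUE)
    expect_true(all(out1[, j] >= rng[1] & out1[, j] <= rng[2]))
  }
})

test_that("forest imputation exploits an exact linear relation", {
  set.seed(8)
  a <- rnorm(200)
  m <- cbind(met_a = a, met_b = 2 * a, met_c = rnorm(200))
  m[7, "met_b"] <- NA
  out <- impute_missing(m, seed = 3)
  expect_lt(abs(out[7, "met_b"] - 2 * a[7]), abs(2 * a[7]) * 0.10 + 0.05)
  all_gone <- m
  all_gone[, "met_c"] <- NA
  expect_error(impute_missing(all_gone), "entirely missing")
})
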
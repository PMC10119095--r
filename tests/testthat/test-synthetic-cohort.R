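test_that("reference generation is deterministic and sits on its lines", {
  cfg <- reference_config(n = 500, seed = 71)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  # near-zero noise: every biomarker lies on its configured line
  cfg0 <- reference_config(n = 500, seed = 71,
                           biomarker_params = tiny_noise_params())
  r0 <- generate_reference(cfg0)
  p <- cfg0$biomarker_params
  for (sx in c("male", "female")) {
    rows <- r0$sex == sx
    for (bm in c("fev1", "sbp", "albumin")) {
      pr <- p[p$sex == sx & p$biomarker == bm, ]
      expect_equal(r0[[bm]][rows], pr$q + pr$k * r0$age[rows],
                   tolerance = 1e-4)
    }
    pr <- p[p$sex == sx & p$biomarker == "crp", ]
    expect_equal(log(r0$crp[rows]), pr$q + pr$k * r0$age[rows],
                 tolerance = 1e-4)
  }
})

test_that("refitting the generated reference recovers configured (q, k) within 3 SE", {
  p <- default_biomarker_params()
  p$k[p$biomarker == "bun"] <- 0.5
  p$q[p$biomarker == "bun"] <- 10
  ref <- generate_reference(reference_config(n = 5000, seed = 73,
                                             biomarker_params = p))
  for (sx in c("male", "female")) {
    d <- ref[ref$sex == sx, ]
    fit <- summary(lm(bun ~ age, data = d))$coefficients
    expect_lt(abs(fit["age", 1] - 0.5) / fit["age", 2], 3)
    expect_lt(abs(fit["(Intercept)", 1] - 10) / fit["(Intercept)", 2], 3)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(reference_config(n = 100), class = "bioagemh_error")
  expect_error(reference_config(age_range = c(70, 30)),
               class = "bioagemh_error")
  expect_error(cohort_config(prop_male = 1.2), class = "bioagemh_error")
  expect_error(cohort_config(baseline_hazard = 0), class = "bioagemh_error")
  expect_error(cohort_config(lambda_shared = 1), class = "bioagemh_error")
})

test_that("cohort generation is deterministic given seed and config", {
  cfg <- cohort_config(n = 1500, seed = 75)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  attr(c1, "config") <- attr(c2, "config") <- NULL
  expect_identical(c1, c2)
})

test_that("covariate prevalences calibrate to the configured fractions", {
  coh <- generate_cohort(cohort_config(n = 50000, seed = 77))
  expect_equal(mean(coh$sex == "male"), 0.462, tolerance = 0.01 / 0.462)
  expect_equal(mean(coh$hypertension), 0.540, tolerance = 0.01 / 0.540)
  expect_equal(mean(coh$bmi_cat == "obese"), 0.237, tolerance = 0.01 / 0.237)
  expect_equal(mean(coh$smoking == "never"), 0.548, tolerance = 0.01 / 0.548)
  expect_equal(mean(coh$healthy_activity), 0.714, tolerance = 0.01 / 0.714)
  expect_equal(mean(coh$age), 56.47, tolerance = 0.01)
  expect_equal(mean(coh$townsend), -1.43, tolerance = 0.05 / 1.43)
})

test_that("latent-factor loading controls the AA cross-correlation", {
  aa_cor_at <- function(lam, n = 20000, seed = 79) {
    cfg <- cohort_config(n = n, seed = seed, lambda_shared = lam)
    kp <- fit_kdm(generate_reference(reference_config(
      biomarker_params = cfg$biomarker_params, seed = seed + 1L)))
    set.seed(seed)
    age <- runif(n, 37, 73)
    sex <- ifelse(runif(n) < 0.5, "male", "female")
    panel <- generate_biomarkers(age, sex, cfg)
    cor(compute_aa(kdm_ba(panel, age, kp, sex), age)$aa_raw,
        compute_aa(phenoage(panel, age), age)$aa_raw)
  }
  r <- vapply(c(0, 0.221, 0.5), aa_cor_at, numeric(1))
  expect_lt(abs(r[1]), 0.03)                   # independent at lambda = 0
  expect_equal(r[2], 0.23, tolerance = 0.03 / 0.23)  # calibrated default
  expect_true(all(diff(r) > 0))                # strictly increasing in lambda
})

test_that("outcome simulation honors the exponential closed form and contract", {
  set.seed(81)
  n <- 50000
  aa <- scale(rnorm(n))[, 1]
  prs <- rnorm(n)
  cfg <- cohort_config(n = n, beta_incident = 0, beta_baseline = 0,
                       prs_beta = 0, baseline_hazard = 0.006)
  sim <- simulate_outcomes(aa, prs, cfg)
  # fixed 8.7-year horizon at null: incidence = 1 - exp(-8.7 h)
  expect_equal(mean(sim$onset_years <= 8.7), 1 - exp(-8.7 * 0.006),
               tolerance = 0.05)
  # prevalence near the configured fraction at null
  expect_equal(mean(sim$prevalent_true), 0.129, tolerance = 0.03)
  # contract: AAs must arrive standardized
  expect_error(simulate_outcomes(aa * 3, prs, cfg), class = "bioagemh_error")
  expect_error(simulate_outcomes(aa + 1, prs, cfg), class = "bioagemh_error")
})

test_that("questionnaire simulation round-trips through the scorers", {
  set.seed(83)
  n <- 1000
  for (combo in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                     c(TRUE, TRUE))) {
    status <- data.frame(phq4_dep = rep(combo[1], n),
                         phq4_anx = rep(combo[2], n),
                         surveyed = rep(TRUE, n),
                         survey_dep = rep(combo[1], n),
                         survey_anx = rep(combo[2], n))
    qs <- simulate_questionnaires(status)
    sc4 <- score_phq4(qs$phq4)
    expect_equal(sc4$dep_pos, status$phq4_dep)
    expect_equal(sc4$anx_pos, status$phq4_anx)
    if (!combo[1] && !combo[2]) expect_true(all(!sc4$either_pos))
    expect_equal(score_phq9(qs$phq9)$positive, status$survey_dep)
    expect_equal(score_gad7(qs$gad7)$positive, status$survey_anx)
  }
})

test_that("scored status agrees with generator-assigned truth", {
  sc <- scored_cohort(n = 4000, seed = 85)
  expect_equal(sc$prevalent_either, sc$true_prevalent)
  free <- !sc$prevalent_either
  expect_equal(sc$incident_either[free], sc$true_incident[free])
})

test_that("uniform missingness leads to downstream exclusion", {
  coh <- generate_cohort(cohort_config(n = 2000, seed = 87,
                                       missing_rate = 0.02))
  sc <- score_cohort(coh)
  expect_lt(nrow(sc), 2000)
  expect_true(all(complete.cases(sc[, c("kdm_ba", "phenoage")])))
})
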
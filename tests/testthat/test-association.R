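# One moderately sized scored cohort shared across blocks.
SC <- scored_cohort(n = 12000, seed = 91,
                    beta_baseline = log(1.5), beta_incident = log(1.3))

test_that("reported CIs reproduce from estimate and SE on the log scale", {
  res <- rbind(fit_incidence(SC, "incident_either", "aa_kdm_std"),
               fit_cross_sectional(SC, "prevalent_either", "aa_kdm_std"),
               fit_incidence(SC, "incident_either", "aa_kdm",
                             exposure_type = "quartile"))
  z <- qnorm(0.975)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$ci_low[i], exp(log(res$estimate[i]) - z * res$se[i]),
                 tolerance = 1e-4)
    expect_equal(res$ci_high[i], exp(log(res$estimate[i]) + z * res$se[i]),
                 tolerance = 1e-4)
    expect_true(res$ci_low[i] <= res$estimate[i] &&
                  res$estimate[i] <= res$ci_high[i])
  }
  lin <- fit_cross_sectional(SC, "phq4_score", "aa_kdm_std")
  expect_equal(lin$ci_low, lin$estimate - z * lin$se, tolerance = 1e-6)
})

test_that("injected cross-sectional and incidence effects are recovered", {
  # true OR = 1.5 and HR = 1.3 per SD of KDM-BA acceleration; recovery
  # asserted within 3 Monte-Carlo standard errors of the fit
  or <- fit_cross_sectional(SC, "prevalent_either", "aa_kdm_std")
  expect_lt(abs(log(or$estimate) - log(1.5)), 3 * or$se)
  hr <- fit_incidence(SC, "incident_either", "aa_kdm_std")
  expect_lt(abs(log(hr$estimate) - log(1.3)), 3 * hr$se)
  # covariate ladder never changes the analysis rows
  for (lv in 1:3) {
    r <- fit_incidence(SC, "incident_either", "aa_kdm_std", level = lv)
    expect_equal(r$n_case, hr$n_case)
    expect_equal(r$n_total, hr$n_total)
  }
})

test_that("quartile contrasts are monotone under a linear log-odds trend", {
  q <- fit_cross_sectional(SC, "prevalent_either", "aa_kdm",
                           exposure_type = "quartile")
  expect_equal(q$term, c("Q2", "Q3", "Q4"))
  expect_true(all(diff(log(q$estimate)) > 0))
  expect_true(all(q$estimate > 1))
  # quartile sizes differ by at most 1
  expect_lte(diff(range(q$n_total)), 1)
})

test_that("Cox fits are invariant to rescaling all times", {
  d <- SC
  d$event_time_years <- d$event_time_years * 2
  r1 <- fit_incidence(SC, "incident_either", "aa_kdm_std")
  r2 <- fit_incidence(d, "incident_either", "aa_kdm_std")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_equal(r1$se, r2$se, tolerance = 1e-8)
})

test_that("Cox estimate matches a hand-coded partial likelihood on 6 subjects", {
  d <- data.frame(
    event_time_years = c(1, 2, 3, 4, 5, 6),
    event = c(1L, 0L, 1L, 1L, 0L, 1L),
    aa_kdm_std = c(0.5, -0.2, 1.1, -0.9, 0.3, -0.4),
    center_id = 1L, age = 50, sex = "male", bmi_cat = "normal",
    race = "white", smoking = "never", healthy_alcohol = 1L,
    healthy_activity = 1L, townsend = 0, hypertension = 0L, chd = 0L,
    diabetes = 0L)
  fit <- fit_incidence(d, "incident_either", "aa_kdm_std", center = "none")
  # independent oracle: maximize the Breslow partial likelihood numerically
  x <- d$aa_kdm_std
  score <- function(b) {
    s <- 0
    for (i in which(d$event == 1)) {
      risk <- which(d$event_time_years >= d$event_time_years[i])
      s <- s + x[i] - sum(x[risk] * exp(b * x[risk])) / sum(exp(b * x[risk]))
    }
    s
  }
  b_hat <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  expect_equal(log(fit$estimate), b_hat, tolerance = 1e-6)
})

test_that("restricted-cubic-spline exposures fit and reduce to linear tails", {
  r <- fit_cross_sectional(SC, "phq4_score", "aa_kdm_std",
                           exposure_type = "rcs")
  expect_equal(nrow(r), 2)
  expect_equal(length(attr(r, "knots")), 3)
  ri <- fit_incidence(SC, "incident_either", "aa_kdm_std",
                      exposure_type = "rcs")
  expect_equal(nrow(ri), 2)
  expect_true(all(is.finite(ri$estimate)))
})

test_that("joint PRS categories have balanced occupancy and additive effects", {
  jp <- joint_prs_analysis(SC, "aa_kdm_std")
  expect_equal(nrow(jp$joint), 14)  # 7 non-reference per model
  base <- jp$joint[jp$joint$analysis_id == "joint_baseline", ]
  n_free <- sum(!is.na(SC$prevalent_either))
  expect_true(all(abs(base$n_total - n_free / 8) < n_free * 0.015))
  expect_true(all(jp$interaction$p_interaction >= 0 &
                    jp$interaction$p_interaction <= 1))
  # top joint category ~ product of the marginal effects on the log scale:
  # beta_inc * (E[AA|Q4] - E[AA|Q1]) + prs_beta * (E[PRS|hi] - E[PRS|lo])
  top <- jp$joint[jp$joint$analysis_id == "joint_incidence" &
                    jp$joint$term == "Q4_high", ]
  gap_q <- 2 * dnorm(qnorm(0.75)) / 0.25
  gap_p <- 2 * dnorm(0) / 0.5
  expected <- log(1.3) * gap_q + 0.4 * gap_p
  expect_gt(expected, log(top$ci_low))
  expect_lt(expected, log(top$ci_high) + 0.15)  # quartile-mean approximation
})

test_that("center handling modes agree closely when center variance is small", {
  r_str <- fit_incidence(SC, "incident_either", "aa_kdm_std",
                         center = "strata")
  r_non <- fit_incidence(SC, "incident_either", "aa_kdm_std", center = "none")
  expect_equal(log(r_str$estimate), log(r_non$estimate), tolerance = 0.05)
  g_rand <- fit_cross_sectional(SC, "prevalent_either", "aa_kdm_std")
  g_fix <- fit_cross_sectional(SC, "prevalent_either", "aa_kdm_std",
                               center = "fixed")
  expect_equal(log(g_rand$estimate), log(g_fix$estimate), tolerance = 0.02)
})

test_that("sensitivity variants behave as designed", {
  # restrict to >2y follow-up so the exclusion variant is a strict no-op
  keep <- is.na(SC$event_time_years) | SC$event_time_years > 2
  d <- SC[keep, ]
  sens <- sensitivity_suite(d, "incident_either", "aa_kdm_std")
  est <- sens$estimates
  expect_equal(est$estimate[est$variant == "exclude_le_2y"],
               est$estimate[est$variant == "primary"], tolerance = 1e-10)
  # chronic-disease flags independent of exposure and outcome: adjusted HR
  # within Monte-Carlo error of the primary
  expect_equal(
    log(est$estimate[est$variant == "adjust_chronic_disease"]),
    log(est$estimate[est$variant == "primary"]), tolerance = 0.05)
  expect_true("adjust_adversity" %in% est$variant)
  expect_equal(nrow(sens$interaction_p), 2)
})

test_that("a disease-mediated effect attenuates under chronic-disease adjustment", {
  sc <- scored_cohort(n = 20000, seed = 93, beta_incident = log(1.3),
                      disease_aa_effect = 1.2, disease_effect_loghr = 1.2)
  primary <- fit_incidence(sc, "incident_either", "aa_kdm_std")
  adjusted <- fit_incidence(sc, "incident_either", "aa_kdm_std",
                            extra_adjustments = "incident_chronic_disease")
  expect_lt(adjusted$estimate, primary$estimate)
})

test_that("degenerate analysis inputs raise diagnostic errors", {
  d <- SC[1:200, ]
  d$event <- 0L
  expect_error(fit_incidence(d, "incident_either", "aa_kdm_std"),
               "no incident events", class = "bioagemh_error")
  expect_error(fit_cross_sectional(SC, "phq4_score", "aa_kdm_std", level = 4),
               class = "bioagemh_error")
  expect_error(fit_cross_sectional(SC[, setdiff(names(SC), "aa_kdm_std")],
                                   "phq4_score", "aa_kdm_std"),
               "aa_kdm_std", class = "bioagemh_error")
})
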
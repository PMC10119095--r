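## Association models: cross-sectional (mixed linear / logistic with an
## examination-center random intercept), Cox proportional hazards for
## incident outcomes (center as stratum by default), restricted-cubic-spline
## dose-response, quartile contrasts, sensitivity variants, and joint
## polygenic-risk stratification.

MODEL_COVARIATES <- list(
  `1` = c("age", "sex"),
  `2` = c("age", "sex", "bmi_cat", "race", "smoking", "healthy_alcohol",
          "healthy_activity"),
  `3` = c("age", "sex", "bmi_cat", "race", "smoking", "healthy_alcohol",
          "healthy_activity", "townsend", "hypertension", "chd", "diabetes")
)

covariate_terms <- function(level, data) {
  covs <- MODEL_COVARIATES[[as.character(level)]]
  if (is.null(covs)) {
    stop_bioagemh("model level must be 1, 2 or 3", "bioagemh_input_error")
  }
  ## drop covariates that are constant in the analysis subset
  keep <- vapply(covs, function(cl) length(unique(data[[cl]])) > 1, logical(1))
  covs[keep]
}

outcome_column <- function(outcome) {
  switch(outcome,
         phq4_score = "phq4_total", phq9_score = "phq9_total",
         gad7_score = "gad7_total",
         prevalent_either = "prevalent_either", prevalent_dep = "prevalent_dep",
         prevalent_anx = "prevalent_anx",
         incident_either = "incident_either", incident_dep = "incident_dep",
         incident_anx = "incident_anx", incident_both = "incident_both",
         outcome)
}

effect_row <- function(analysis_id, outcome, exposure, term, log_estimate, se,
                       exp_scale, n_case, n_total, level = 0.95) {
  z <- log_estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- log_estimate
  lo <- log_estimate - zq * se
  hi <- log_estimate + zq * se
  if (exp_scale) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(analysis_id = analysis_id, outcome = outcome, exposure = exposure,
             term = term, estimate = est, se = se, ci_low = lo, ci_high = hi,
             p = p, n_case = n_case, n_total = n_total,
             stringsAsFactors = FALSE)
}

## Extract named fixed-effect terms from lm/glm/lmer/glmer/coxph fits.
fixed_effects <- function(fit) {
  if (inherits(fit, "merMod")) {
    b <- lme4::fixef(fit)
    v <- as.matrix(stats::vcov(fit))
  } else {
    b <- stats::coef(fit)
    v <- as.matrix(stats::vcov(fit))
  }
  se <- sqrt(diag(v))
  names(se) <- names(b)
  list(b = b, se = se)
}

exposure_design <- function(data, exposure, exposure_type) {
  if (exposure_type == "continuous") {
    list(rhs = exposure, terms = exposure)
  } else if (exposure_type == "quartile") {
    ## quartiles computed in the analysis subset
    data$.expq <- factor(paste0("Q", quartile_cut(data[[exposure]])),
                         levels = paste0("Q", 1:4))
    list(rhs = ".expq", terms = paste0(".expqQ", 2:4), data = data)
  } else if (exposure_type == "rcs") {
    kn <- rcs_knots(data[[exposure]])
    basis <- rcs_basis(data[[exposure]], kn)
    data$.rcs1 <- basis[, "x"]
    data$.rcs2 <- basis[, "x1"]
    list(rhs = ".rcs1 + .rcs2", terms = c(".rcs1", ".rcs2"), data = data,
         knots = kn)
  } else {
    stop_bioagemh("exposure_type must be continuous, quartile or rcs",
                  "bioagemh_input_error")
  }
}

term_case_counts <- function(data, exposure_type, y) {
  if (exposure_type != "quartile") {
    return(list(n_case = sum(y == 1, na.rm = TRUE), n_total = nrow(data)))
  }
  NULL
}

#' Cross-sectional association models
#'
#' Fits the score and prevalence models: linear mixed regression for
#' questionnaire scores and logistic regression for binary status, each with
#' the examination center as a random intercept (or fixed effects via
#' `center = "fixed"`). The covariate ladder is Model 1 (age, sex), Model 2
#' (+ BMI category, race, smoking, healthy alcohol, healthy activity),
#' Model 3 (+ Townsend index, hypertension, CHD, diabetes). Continuous
#' exposures are per SD of age acceleration; quartile exposures contrast
#' Q2-Q4 against Q1 with quartiles computed in the analysis subset; `rcs`
#' uses a 3-knot restricted cubic spline (knots at the 5th/50th/95th
#' percentiles).
#'
#' @param cohort a scored cohort (see [score_cohort()])
#' @param outcome one of `phq4_score`, `phq9_score`, `gad7_score`,
#'   `prevalent_either`, `prevalent_dep`, `prevalent_anx`, an incident flag
#'   (logistic, for survey-based prospective analysis), or a symptom column
#' @param exposure `"aa_kdm_std"` or `"aa_pheno_std"` (or the raw `aa_*`
#'   column for quartile/rcs)
#' @param level covariate ladder level 1, 2 or 3
#' @param exposure_type `"continuous"`, `"quartile"` or `"rcs"`
#' @param center `"random"` (default) or `"fixed"`
#' @param nagq integer passed to [lme4::glmer()] (`nAGQ`); 0 uses the fast
#'   penalized least-squares step, adequate for small center variance
#' @param subset optional logical vector restricting the analysis rows
#' @return data.frame of effect estimates (one row per exposure term);
#'   coefficient scale for score outcomes, odds-ratio scale for binary ones
#' @export
fit_cross_sectional <- function(cohort, outcome = "phq4_score",
                                exposure = "aa_kdm_std", level = 3,
                                exposure_type = c("continuous", "quartile",
                                                  "rcs"),
                                center = c("random", "fixed"), nagq = 0,
                                subset = NULL) {
  exposure_type <- match.arg(exposure_type)
  center <- match.arg(center)
  ycol <- outcome_column(outcome)
  assert_columns(cohort, c(ycol, exposure, "center_id"), "scored cohort")
  data <- if (is.null(subset)) cohort else cohort[subset, , drop = FALSE]
  data <- data[!is.na(data[[ycol]]) & !is.na(data[[exposure]]), , drop = FALSE]
  binary <- is.logical(data[[ycol]]) ||
    all(data[[ycol]] %in% c(0, 1, NA))
  if (grepl("score", outcome)) binary <- FALSE
  data$.y <- as.numeric(data[[ycol]])
  ed <- exposure_design(data, exposure, exposure_type)
  if (!is.null(ed$data)) data <- ed$data
  covs <- covariate_terms(level, data)
  rhs <- paste(c(ed$rhs, covs), collapse = " + ")
  n_total <- nrow(data)
  n_case <- if (binary) sum(data$.y == 1) else NA_integer_

  if (center == "random" && length(unique(data$center_id)) > 1) {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | center_id)"))
    fit <- if (binary) {
      lme4::glmer(fml, data = data, family = stats::binomial(), nAGQ = nagq)
    } else {
      lme4::lmer(fml, data = data, REML = TRUE)
    }
  } else {
    fml <- stats::as.formula(paste(
      ".y ~", rhs,
      if (length(unique(data$center_id)) > 1) "+ factor(center_id)" else ""))
    fit <- if (binary) {
      stats::glm(fml, data = data, family = stats::binomial())
    } else {
      stats::lm(fml, data = data)
    }
  }
  fe <- fixed_effects(fit)
  rows <- lapply(ed$terms, function(tm) {
    nc <- n_case
    nt <- n_total
    if (exposure_type == "quartile") {
      qlab <- sub(".expq", "", tm, fixed = TRUE)
      in_q <- data$.expq == qlab
      nt <- sum(in_q)
      nc <- if (binary) sum(data$.y[in_q] == 1) else NA_integer_
    }
    effect_row(paste0("cross_sectional_m", level), outcome, exposure,
               sub(".expq", "", tm, fixed = TRUE), fe$b[[tm]], fe$se[[tm]],
               exp_scale = binary, n_case = nc, n_total = nt)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  if (!is.null(ed$knots)) attr(out, "knots") <- ed$knots
  out
}

#' Cox proportional-hazards models for incident depression/anxiety
#'
#' Time-to-event association of baseline age acceleration with incident
#' outcomes among participants free of depression/anxiety at baseline.
#' The examination center enters as a stratification factor by default
#' (`center = "frailty"` fits a gamma shared-frailty term instead).
#'
#' @inheritParams fit_cross_sectional
#' @param outcome `incident_either`, `incident_dep`, `incident_anx`, or
#'   `incident_both`
#' @param extra_adjustments character vector: `"incident_chronic_disease"`
#'   adds the three incident chronic-disease flags, `"adversity"` adds the
#'   childhood-adversity score
#' @param exclude_followup_le_2y drop participants with <= 2 years at risk
#' @return data.frame of hazard-ratio rows (plus attribute `"fit"`)
#' @export
fit_incidence <- function(cohort, outcome = "incident_either",
                          exposure = "aa_kdm_std", level = 3,
                          exposure_type = c("continuous", "quartile", "rcs"),
                          center = c("strata", "frailty", "none"),
                          extra_adjustments = character(),
                          exclude_followup_le_2y = FALSE, subset = NULL) {
  exposure_type <- match.arg(exposure_type)
  center <- match.arg(center)
  tcol <- switch(outcome, incident_either = "event_time_years",
                 incident_dep = "time_dep", incident_anx = "time_anx",
                 incident_both = "time_both",
                 stop_bioagemh("unknown incident outcome",
                               "bioagemh_input_error"))
  ecol <- switch(outcome, incident_either = "event", incident_dep = "event_dep",
                 incident_anx = "event_anx", incident_both = "event_both")
  assert_columns(cohort, c(tcol, ecol, exposure, "center_id"), "scored cohort")
  data <- if (is.null(subset)) cohort else cohort[subset, , drop = FALSE]
  data <- data[!is.na(data[[ecol]]) & !is.na(data[[exposure]]), , drop = FALSE]
  data$.time <- pmax(data[[tcol]], 0.5 / 365.25)  # guard same-day events
  data$.event <- data[[ecol]]
  if (exclude_followup_le_2y) data <- data[data$.time > 2, , drop = FALSE]
  if (sum(data$.event) == 0) {
    stop_bioagemh("no incident events in the analysis subset",
                  "bioagemh_input_error")
  }
  ed <- exposure_design(data, exposure, exposure_type)
  if (!is.null(ed$data)) data <- ed$data
  covs <- covariate_terms(level, data)
  if ("incident_chronic_disease" %in% extra_adjustments) {
    covs <- c(covs, "incident_diabetes", "incident_cvd", "incident_cancer")
  }
  if ("adversity" %in% extra_adjustments) {
    if (!"adversity_score" %in% names(data) ||
        all(is.na(data$adversity_score))) {
      warning("adversity_score unavailable; variant skipped")
      return(NULL)
    }
    covs <- c(covs, "adversity_score")
  }
  center_term <- switch(center,
                        strata = "strata(center_id)",
                        frailty = "frailty(center_id)",
                        none = NULL)
  rhs <- paste(c(ed$rhs, covs, center_term), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(fml, data = data)
  fe <- fixed_effects(fit)
  n_total <- nrow(data)
  rows <- lapply(ed$terms, function(tm) {
    nc <- sum(data$.event)
    nt <- n_total
    if (exposure_type == "quartile") {
      qlab <- sub(".expq", "", tm, fixed = TRUE)
      in_q <- data$.expq == qlab
      nt <- sum(in_q)
      nc <- sum(data$.event[in_q])
    }
    effect_row(paste0("incidence_m", level), outcome, exposure,
               sub(".expq", "", tm, fixed = TRUE), fe$b[[tm]], fe$se[[tm]],
               exp_scale = TRUE, n_case = nc, n_total = nt)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  if (!is.null(ed$knots)) attr(out, "knots") <- ed$knots
  out
}

#' Joint analysis of age acceleration and polygenic risk
#'
#' Tests multiplicative interaction between the standardized AA and the
#' standardized polygenic score (product term in the baseline logistic and
#' incidence Cox models), and estimates joint-category effects: AA quartile
#' crossed with dichotomized PRS (median split), reference = lowest quartile
#' and low PRS (8 categories).
#'
#' @inheritParams fit_incidence
#' @param exposure `"aa_kdm_std"` or `"aa_pheno_std"`
#' @return list with `interaction` (data.frame: model, p_interaction) and
#'   `joint` (effect rows per category: OR for baseline, HR for incidence)
#' @export
joint_prs_analysis <- function(cohort, exposure = "aa_kdm_std", level = 3,
                               center = c("strata", "frailty", "none")) {
  center <- match.arg(center)
  assert_columns(cohort, c("prs", exposure), "scored cohort")
  data <- cohort[!is.na(cohort[[exposure]]) & !is.na(cohort$prs), ,
                 drop = FALSE]
  covs <- covariate_terms(level, data)

  ## (i) interaction terms
  fml_b <- stats::as.formula(paste(
    "prevalent_either ~", exposure, "* prs +", paste(covs, collapse = " + "),
    "+ factor(center_id)"))
  fit_b <- stats::glm(fml_b, data = data, family = stats::binomial())
  pb <- summary(fit_b)$coefficients[paste0(exposure, ":prs"), 4]
  inc <- data[!is.na(data$event), , drop = FALSE]
  fml_c <- stats::as.formula(paste(
    "survival::Surv(pmax(event_time_years, 0.5/365.25), event) ~", exposure,
    "* prs +", paste(covs, collapse = " + "), "+ strata(center_id)"))
  fit_c <- survival::coxph(fml_c, data = inc)
  pc <- summary(fit_c)$coefficients[paste0(exposure, ":prs"), "Pr(>|z|)"]
  interaction <- data.frame(model = c("baseline_logistic", "incidence_cox"),
                            p_interaction = c(pb, pc))

  ## (ii) joint categories
  make_joint <- function(d) {
    q <- quartile_cut(d[[exposure]])
    prs_high <- d$prs > stats::median(d$prs)
    factor(paste0("Q", q, ifelse(prs_high, "_high", "_low")),
           levels = as.vector(t(outer(paste0("Q", 1:4), c("_low", "_high"),
                                      paste0))))
  }
  data$.joint <- make_joint(data)
  fml_jb <- stats::as.formula(paste(
    "prevalent_either ~ .joint +", paste(covs, collapse = " + "),
    "+ factor(center_id)"))
  fit_jb <- stats::glm(fml_jb, data = data, family = stats::binomial())
  inc$.joint <- make_joint(inc)
  fml_jc <- stats::as.formula(paste(
    "survival::Surv(pmax(event_time_years, 0.5/365.25), event) ~ .joint +",
    paste(covs, collapse = " + "), "+ strata(center_id)"))
  fit_jc <- survival::coxph(fml_jc, data = inc)

  joint_rows <- function(fit, d, yfun, analysis_id, outcome) {
    fe <- fixed_effects(fit)
    terms <- grep("^\\.joint", names(fe$b), value = TRUE)
    do.call(rbind, lapply(terms, function(tm) {
      lab <- sub(".joint", "", tm, fixed = TRUE)
      in_cat <- d$.joint == lab
      effect_row(analysis_id, outcome, exposure, lab, fe$b[[tm]], fe$se[[tm]],
                 exp_scale = TRUE, n_case = sum(yfun(d)[in_cat], na.rm = TRUE),
                 n_total = sum(in_cat))
    }))
  }
  joint <- rbind(
    joint_rows(fit_jb, data, function(d) d$prevalent_either,
               "joint_baseline", "prevalent_either"),
    joint_rows(fit_jc, inc, function(d) d$event, "joint_incidence",
               "incident_either"))
  list(interaction = interaction, joint = joint)
}

#' Sensitivity-analysis suite for the incidence models
#'
#' Re-runs the primary fully-adjusted Cox fit under four variants:
#' exclusion of participants with <= 2 years of follow-up; age-by-AA and
#' sex-by-AA interaction terms; additional adjustment for incident chronic
#' disease (diabetes, cardiovascular disease, cancer); additional adjustment
#' for the childhood-adversity score (skipped with a warning when
#' unavailable).
#'
#' @inheritParams fit_incidence
#' @return list with `estimates` (side-by-side effect rows, one `variant`
#'   column) and `interaction_p` (age and sex interaction p-values)
#' @export
sensitivity_suite <- function(cohort, outcome = "incident_either",
                              exposure = "aa_kdm_std", level = 3) {
  variants <- list(
    primary = list(),
    exclude_le_2y = list(exclude_followup_le_2y = TRUE),
    adjust_chronic_disease =
      list(extra_adjustments = "incident_chronic_disease"),
    adjust_adversity = list(extra_adjustments = "adversity"))
  rows <- list()
  for (nm in names(variants)) {
    args <- c(list(cohort = cohort, outcome = outcome, exposure = exposure,
                   level = level), variants[[nm]])
    est <- do.call(fit_incidence, args)
    if (is.null(est)) next
    est$variant <- nm
    rows[[nm]] <- est
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL

  ## interaction variants: AA x age and AA x sex
  inc <- cohort[!is.na(cohort$event), , drop = FALSE]
  covs <- covariate_terms(level, inc)
  p_int <- vapply(c("age", "sex"), function(v) {
    fml <- stats::as.formula(paste(
      "survival::Surv(pmax(event_time_years, 0.5/365.25), event) ~",
      exposure, "*", v, "+", paste(setdiff(covs, v), collapse = " + "),
      "+ strata(center_id)"))
    fit <- survival::coxph(fml, data = inc)
    co <- summary(fit)$coefficients
    itn <- grep(paste0("^", exposure, ":"), rownames(co), value = TRUE)
    co[itn[1], "Pr(>|z|)"]
  }, numeric(1))
  list(estimates = estimates,
       interaction_p = data.frame(modifier = c("age", "sex"),
                                  p_interaction = unname(p_int)))
}
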
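#' Configuration for the synthetic study cohort generator
#'
#' Defaults reproduce the study conditions of a large midlife biobank
#' cohort: mean age 56.47 (SD 8.07, range 37-73), 46.2% male, covariate
#' prevalences of the baseline characteristics table, Townsend index
#' -1.43 (SD 3.02), ~54% hypertension, a median potential follow-up of 8.7
#' years with administrative censoring at 2018-12-31, ~1/3 follow-up-survey
#' participation, a baseline depression/anxiety prevalence of 12.9%, and an
#' incident fraction of 4.47% among the baseline-free. The injected effect
#' sizes default to the fully-adjusted continuous KDM-BA estimates
#' (PHQ-4 coefficient 0.0516 per SD, OR 1.123, HR 1.059); `exposure` selects
#' which standardized age acceleration carries them. `lambda_shared` is the
#' loading of a per-participant latent aging factor on the biomarker noise
#' and is calibrated so the two age accelerations correlate ~0.23.
#'
#' @param n cohort size
#' @param seed integer RNG seed
#' @param mean_age,sd_age,age_range age distribution (years; truncated normal)
#' @param prop_male fraction male
#' @param covariates named list of prevalences: `race_white`, `bmi`
#'   (underweight/normal, overweight, obese), `smoking` (current, former,
#'   never), `healthy_alcohol`, `healthy_activity`, `hypertension`, `chd`,
#'   `diabetes`
#' @param townsend_mean,townsend_sd Townsend deprivation index moments
#' @param n_centers number of examination centers
#' @param center_sd SD of the center random intercept on each linear predictor
#' @param biomarker_params generating parameters, see
#'   [default_biomarker_params()]
#' @param lambda_shared latent aging-factor loading in [0, 1)
#' @param exposure which AA carries the injected effects: `"aa_kdm_std"` or
#'   `"aa_pheno_std"`
#' @param baseline_model `"logistic"` (binary prevalence model first, PHQ-4
#'   items drawn conditional on status) or `"linear_score"` (PHQ-4 total
#'   drawn with exactly linear conditional mean `phq4_mean + beta_phq4 *
#'   AA_std`, status then derived by scoring)
#' @param beta_phq4 true per-SD mean shift in PHQ-4 score (linear_score mode)
#' @param phq4_mean population mean PHQ-4 score (linear_score mode)
#' @param beta_baseline true log-odds of prevalent disorder per SD of AA
#' @param beta_incident true log-hazard of incident disorder per SD of AA
#' @param prs_beta true log-odds / log-hazard per SD of the polygenic score
#' @param baseline_prevalence target prevalence of depression/anxiety at
#'   baseline
#' @param baseline_hazard incident-event exponential hazard (per year) at the
#'   reference level; calibrated so ~4.47% of the baseline-free become cases
#' @param baseline_window recruitment dates (start, end), uniform
#' @param survey_window follow-up mental-health survey dates (start, end)
#' @param survey_participation fraction completing the follow-up survey
#' @param censor_date administrative censoring date
#' @param prob_hospital_record probability an incident onset generates a
#'   hospital record (survey positivity is simulated regardless)
#' @param prob_phq4_channel,prob_icd_channel detection-channel probabilities
#'   for prevalent cases (logistic mode); a case missing both is forced onto
#'   the questionnaire channel
#' @param chronic_rates incident chronic-disease probabilities (diabetes,
#'   cvd, cancer) at AA = 0
#' @param disease_aa_effect log-odds of incident chronic disease per SD of AA
#'   (mediation knob, default 0)
#' @param disease_effect_loghr additional log-hazard of depression/anxiety
#'   for participants with any incident chronic disease (default 0)
#' @param missing_rate optional uniform missingness applied to biomarker
#'   columns (records with missing values are excluded downstream)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n = 20000, seed = 1L,
                          mean_age = 56.47, sd_age = 8.07,
                          age_range = c(37, 73),
                          prop_male = 0.462,
                          covariates = list(
                            race_white = 0.957,
                            bmi = c(normal = 0.336, overweight = 0.427,
                                    obese = 0.237),
                            smoking = c(current = 0.102, former = 0.350,
                                        never = 0.548),
                            healthy_alcohol = 0.496,
                            healthy_activity = 0.714,
                            hypertension = 0.540, chd = 0.055,
                            diabetes = 0.049),
                          townsend_mean = -1.43, townsend_sd = 3.02,
                          n_centers = 22, center_sd = 0.05,
                          biomarker_params = default_biomarker_params(),
                          lambda_shared = 0.221,
                          exposure = c("aa_kdm_std", "aa_pheno_std"),
                          baseline_model = c("logistic", "linear_score"),
                          beta_phq4 = 0.0516, phq4_mean = 1.58,
                          beta_baseline = log(1.123),
                          beta_incident = log(1.059),
                          prs_beta = 0.4,
                          baseline_prevalence = 0.129,
                          baseline_hazard = 0.00512,
                          baseline_window = as.Date(c("2008-06-01",
                                                      "2010-12-01")),
                          survey_window = as.Date(c("2016-01-01",
                                                    "2017-06-30")),
                          survey_participation = 1 / 3,
                          censor_date = as.Date("2018-12-31"),
                          prob_hospital_record = 1,
                          prob_phq4_channel = 0.8, prob_icd_channel = 0.35,
                          chronic_rates = c(diabetes = 0.030, cvd = 0.060,
                                            cancer = 0.080),
                          disease_aa_effect = 0, disease_effect_loghr = 0,
                          missing_rate = 0) {
  exposure <- match.arg(exposure)
  baseline_model <- match.arg(baseline_model)
  for (nm in c("prop_male", "survey_participation", "baseline_prevalence",
               "prob_hospital_record", "prob_phq4_channel",
               "prob_icd_channel", "missing_rate")) {
    assert_fraction(get(nm), nm)
  }
  assert_fraction(unlist(covariates), "covariates")
  assert_fraction(chronic_rates, "chronic_rates")
  if (baseline_hazard <= 0) {
    stop_bioagemh("baseline_hazard must be > 0", "bioagemh_config_error")
  }
  if (n_centers < 1) stop_bioagemh("n_centers must be >= 1",
                                   "bioagemh_config_error")
  if (lambda_shared < 0 || lambda_shared >= 1) {
    stop_bioagemh("lambda_shared must be in [0, 1)", "bioagemh_config_error")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate per-participant biomarker panels with a shared latent aging factor
#'
#' `biomarker_i = q_i + k_i * age + lambda_shared * w_i * Z +
#' sqrt(1 - lambda_shared^2) * e_i`, with `Z ~ N(0,1)` a per-participant
#' latent aging factor, loadings `w_i = dir_i * s_i`, and `e_i ~ N(0, s_i^2)`,
#' so each marker's marginal noise SD stays `s_i` as `lambda_shared` varies.
#' Uses the current RNG state (seed upstream).
#'
#' @param age,sex participant vectors
#' @param config a [cohort_config()] (uses `biomarker_params`,
#'   `lambda_shared`)
#' @return data.frame of the 14 biomarker columns, with the latent factor in
#'   attribute `"latent_z"`
#' @export
generate_biomarkers <- function(age, sex, config) {
  params <- config$biomarker_params
  lam <- config$lambda_shared
  z <- stats::rnorm(length(age))
  out <- data.frame(row.names = seq_along(age))
  for (bm in unique(params$biomarker)) {
    w <- numeric(length(age))
    for (sx in c("male", "female")) {
      p <- params[params$sex == sx & params$biomarker == bm, ]
      w[sex == sx] <- p$dir * p$s
    }
    out[[bm]] <- draw_biomarker(age, sex, params, bm,
                                extra = lam * w * z,
                                noise_scale = sqrt(1 - lam^2))
  }
  attr(out, "latent_z") <- z
  out
}

#' Simulate baseline status and incident event times from computed AAs
#'
#' Baseline prevalence follows a logistic model
#' `logit(p) = alpha + beta_baseline * AA_std + prs_beta * PRS + center`;
#' incident onsets (relevant among the baseline-negative) are exponential
#' proportional-hazards times with log-hazard
#' `beta_incident * AA_std + prs_beta * PRS + disease_effect_loghr * chronic
#' + center`. AAs must already be standardized (two-pass design: the clocks
#' and residualization run before outcome simulation, so the injected
#' coefficient is exactly the estimand the pipeline recovers).
#'
#' @param aa_std standardized age acceleration carrying the injected effect
#' @param prs standardized polygenic score
#' @param config a [cohort_config()]
#' @param center_effect per-participant center intercept (default 0)
#' @param chronic_any logical; any incident chronic disease (mediation path)
#' @return data.frame with `prevalent_true` (logical) and `onset_years`
#'   (exponential onset time from baseline, for all rows)
#' @export
simulate_outcomes <- function(aa_std, prs, config, center_effect = 0,
                              chronic_any = FALSE) {
  if (abs(mean(aa_std)) > 0.05 || abs(stats::sd(aa_std) - 1) > 0.05) {
    stop_bioagemh("aa_std is not standardized (mean 0, SD 1) within tolerance",
                  "bioagemh_contract_error")
  }
  n <- length(aa_std)
  alpha <- stats::qlogis(config$baseline_prevalence)
  lp <- alpha + config$beta_baseline * aa_std + config$prs_beta * prs +
    center_effect
  prevalent_true <- stats::runif(n) < stats::plogis(lp)
  loghaz <- log(config$baseline_hazard) + config$beta_incident * aa_std +
    config$prs_beta * prs + config$disease_effect_loghr * chronic_any +
    center_effect
  onset_years <- stats::rexp(n, rate = exp(loghaz))
  data.frame(prevalent_true = prevalent_true, onset_years = onset_years)
}

## -- questionnaire item simulation ------------------------------------------

## Draw n iid items from a categorical distribution on 0:3.
draw_items <- function(n, k, probs) {
  matrix(sample(0:3, n * k, replace = TRUE, prob = probs), ncol = k)
}

## Rejection-sample item matrices until predicate rows are all TRUE.
reject_until <- function(items, ok_fun, redraw_fun, max_iter = 1000) {
  bad <- which(!ok_fun(items))
  iter <- 0
  while (length(bad)) {
    iter <- iter + 1
    if (iter > max_iter) {
      stop_bioagemh("questionnaire rejection sampling failed to converge",
                    "bioagemh_internal_error")
    }
    items[bad, ] <- redraw_fun(length(bad))
    bad <- bad[!ok_fun(items[bad, , drop = FALSE])]
  }
  items
}

PHQ4_BASE <- c(0.66, 0.22, 0.08, 0.04)
PHQ4_ELEVATED <- c(0.15, 0.25, 0.30, 0.30)
SURVEY_BASE <- c(0.82, 0.12, 0.04, 0.02)
SURVEY_ELEVATED <- c(0.20, 0.30, 0.30, 0.20)

## PHQ-4 items consistent with an assigned (dep, anx) questionnaire status:
## positive subscales must reach >= 3; negative ones stay <= 2 and, when both
## are negative, the total stays <= 5.
sim_phq4_items <- function(dep, anx) {
  n <- length(dep)
  items <- matrix(0L, n, 4)
  draw_half <- function(m, pos) {
    if (!m) return(matrix(integer(0), 0, 2))
    probs <- if (pos) PHQ4_ELEVATED else PHQ4_BASE
    h <- draw_items(m, 2, probs)
    ok <- if (pos) function(x) rowSums(x) >= 3 else function(x) rowSums(x) <= 2
    reject_until(h, ok, function(mm) draw_items(mm, 2, probs))
  }
  for (d in c(FALSE, TRUE)) for (a in c(FALSE, TRUE)) {
    idx <- which(dep == d & anx == a)
    if (!length(idx)) next
    items[idx, 1:2] <- draw_half(length(idx), d)
    items[idx, 3:4] <- draw_half(length(idx), a)
  }
  ## negative records must also stay below the total threshold
  neg <- which(!dep & !anx)
  if (length(neg)) {
    bad <- neg[rowSums(items[neg, , drop = FALSE]) >= 6]
    while (length(bad)) {
      items[bad, 1:2] <- draw_half(length(bad), FALSE)
      items[bad, 3:4] <- draw_half(length(bad), FALSE)
      bad <- bad[rowSums(items[bad, , drop = FALSE]) >= 6]
    }
  }
  items
}

## Survey instrument (PHQ-9 or GAD-7) items with total >= 10 (positive) or
## <= 9 (negative).
sim_survey_items <- function(pos, k) {
  n <- length(pos)
  items <- matrix(0L, n, k)
  for (p in c(FALSE, TRUE)) {
    idx <- which(pos == p)
    if (!length(idx)) next
    probs <- if (p) SURVEY_ELEVATED else SURVEY_BASE
    h <- draw_items(length(idx), k, probs)
    ok <- if (p) function(x) rowSums(x) >= 10 else function(x) rowSums(x) <= 9
    items[idx, ] <- reject_until(h, ok, function(m) draw_items(m, k, probs))
  }
  items
}

## Split integer totals 0..12 uniformly into 4 items of capacity 3 each
## (uniform over the 12 unit "slots"), so scoring the items returns the
## total exactly.
split_phq4_total <- function(total) {
  t(vapply(total, function(tt) {
    slots <- sample.int(12, tt)
    as.integer(tabulate((slots - 1L) %/% 3L + 1L, nbins = 4L))
  }, integer(4)))
}

#' Simulate questionnaire item matrices consistent with assigned status
#'
#' Items are rejection-sampled conditional on status so that scoring them
#' with the package scorers reproduces the assigned flags exactly.
#'
#' @param status data.frame with logical columns `phq4_dep`, `phq4_anx`
#'   (baseline questionnaire-channel flags), `surveyed`, `survey_dep`,
#'   `survey_anx` (follow-up survey positivity)
#' @return list with `phq4` (n x 4), `phq9` (n x 9, NA for non-surveyed),
#'   `gad7` (n x 7, NA for non-surveyed)
#' @export
simulate_questionnaires <- function(status) {
  n <- nrow(status)
  phq4 <- sim_phq4_items(status$phq4_dep, status$phq4_anx)
  phq9 <- matrix(NA_integer_, n, 9)
  gad7 <- matrix(NA_integer_, n, 7)
  sv <- which(status$surveyed)
  if (length(sv)) {
    phq9[sv, ] <- sim_survey_items(status$survey_dep[sv], 9)
    gad7[sv, ] <- sim_survey_items(status$survey_anx[sv], 7)
  }
  list(phq4 = phq4, phq9 = phq9, gad7 = gad7)
}

## -- helpers for code / item assignment --------------------------------------

DEP_CODES <- c("F329", "F320", "F331", "F339", "3119", "311")
ANX_CODES <- c("F411", "F410", "F419", "F400", "F401", "30000", "3000")

sample_codes <- function(dep, anx) {
  n <- length(dep)
  out <- character(n)
  has_d <- which(dep)
  has_a <- which(anx)
  d <- character(n); a <- character(n)
  d[has_d] <- sample(DEP_CODES, length(has_d), replace = TRUE)
  a[has_a] <- sample(ANX_CODES, length(has_a), replace = TRUE)
  out <- ifelse(dep & anx, paste(d, a, sep = ";"), ifelse(dep, d, a))
  out[!dep & !anx] <- ""
  out
}

ADVERSITY_PROBS <- list(
  physical_neglect = c(0.05, 0.05, 0.07, 0.08, 0.75),
  emotional_neglect = c(0.03, 0.05, 0.12, 0.25, 0.55),
  sexual_abuse = c(0.90, 0.05, 0.03, 0.015, 0.005),
  physical_abuse = c(0.80, 0.10, 0.06, 0.03, 0.01),
  emotional_abuse = c(0.80, 0.10, 0.06, 0.03, 0.01)
)

sim_adversity_items <- function(n) {
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(ADVERSITY_PROBS)) {
    out[[nm]] <- sample(ADVERSITY_LEVELS, n, replace = TRUE,
                        prob = ADVERSITY_PROBS[[nm]])
  }
  out
}

## Split an incident "either" case into depression / anxiety / both, using
## the observed subtype mixture among incident cases (dep-only 0.487,
## anx-only 0.332, both 0.181).
INCIDENT_TYPE_PROBS <- c(dep = 8051 / 16523, anx = 5481 / 16523,
                         both = 2991 / 16523)
## Baseline mixture: dep 26424, anx 43544, either 54554 -> both 15414.
BASELINE_TYPE_PROBS <- c(dep = 11010 / 54554, anx = 28130 / 54554,
                         both = 15414 / 54554)

sample_type <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a full synthetic study cohort
#'
#' Two-pass design: demographics, covariates and biomarkers are generated
#' first; KDM-BA is trained on a freshly generated reference population and
#' both clocks plus standardized age accelerations are computed with the real
#' estimators; outcomes are then simulated conditional on those computed AAs,
#' so the injected effect size is exactly the estimand the analysis pipeline
#' recovers. Questionnaire items, ICD code lists, dates, polygenic score,
#' incident chronic-disease flags and adversity items complete the table.
#'
#' @param config a [cohort_config()]
#' @return data.frame with one row per participant; trained KDM parameters in
#'   attribute `"kdm_parameters"`, the config in attribute `"config"`.
#'   Columns prefixed `true_` record generator-assigned status for
#'   verification and are not used by the analysis stages.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_bioagemh("config must be a cohort_config", "bioagemh_config_error")
  }
  ref_cfg <- reference_config(biomarker_params = config$biomarker_params,
                              seed = config$seed + 1L)
  reference <- generate_reference(ref_cfg)
  kdm_params <- fit_kdm(reference)

  set.seed(config$seed)
  n <- config$n
  cv <- config$covariates

  age <- stats::rnorm(n, config$mean_age, config$sd_age)
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  race <- ifelse(stats::runif(n) < cv$race_white, "white",
                 sample(c("black", "asian", "other"), n, replace = TRUE))
  bmi_cat <- sample(names(cv$bmi), n, replace = TRUE, prob = cv$bmi)
  smoking <- sample(names(cv$smoking), n, replace = TRUE, prob = cv$smoking)
  healthy_alcohol <- as.integer(stats::runif(n) < cv$healthy_alcohol)
  healthy_activity <- as.integer(stats::runif(n) < cv$healthy_activity)
  townsend <- stats::rnorm(n, config$townsend_mean, config$townsend_sd)
  hypertension <- as.integer(stats::runif(n) < cv$hypertension)
  chd <- as.integer(stats::runif(n) < cv$chd)
  diabetes <- as.integer(stats::runif(n) < cv$diabetes)
  center_id <- sample.int(config$n_centers, n, replace = TRUE)
  center_re <- stats::rnorm(config$n_centers, 0, config$center_sd)
  center_effect <- center_re[center_id]

  panel <- generate_biomarkers(age, sex, config)

  ba_kdm <- kdm_ba(panel, age, kdm_params, sex)
  ba_pheno <- phenoage(panel, age)
  aa_k <- compute_aa(ba_kdm, age)
  aa_p <- compute_aa(ba_pheno, age)

  prs <- stats::rnorm(n)

  aa_std <- if (config$exposure == "aa_kdm_std") aa_k$aa_std else aa_p$aa_std

  ## incident chronic diseases (optional mediation path)
  cr <- config$chronic_rates
  m <- config$disease_aa_effect
  inc_diabetes <- as.integer(stats::runif(n) <
                               stats::plogis(stats::qlogis(cr["diabetes"]) + m * aa_std))
  inc_cvd <- as.integer(stats::runif(n) <
                          stats::plogis(stats::qlogis(cr["cvd"]) + m * aa_std))
  inc_cancer <- as.integer(stats::runif(n) <
                             stats::plogis(stats::qlogis(cr["cancer"]) + m * aa_std))
  chronic_any <- (inc_diabetes | inc_cvd | inc_cancer)

  out_sim <- simulate_outcomes(aa_std, prs, config, center_effect, chronic_any)

  baseline_date <- config$baseline_window[1] +
    floor(stats::runif(n) *
            (as.numeric(config$baseline_window[2] -
                          config$baseline_window[1]) + 1))
  survey_participant <- stats::runif(n) < config$survey_participation
  survey_date <- as.Date(rep(NA, n))
  survey_date[survey_participant] <- config$survey_window[1] +
    floor(stats::runif(sum(survey_participant)) *
            (as.numeric(config$survey_window[2] -
                          config$survey_window[1]) + 1))

  ## ----- baseline status, detection channels, PHQ-4 items -----
  phq4_dep <- phq4_anx <- logical(n)
  icd_baseline <- character(n)
  if (config$baseline_model == "logistic") {
    prevalent <- out_sim$prevalent_true
    type <- rep("none", n)
    type[prevalent] <- sample_type(sum(prevalent), BASELINE_TYPE_PROBS)
    q_channel <- prevalent & (stats::runif(n) < config$prob_phq4_channel)
    icd_channel <- prevalent & (stats::runif(n) < config$prob_icd_channel)
    q_channel[prevalent & !q_channel & !icd_channel] <- TRUE
    phq4_dep <- q_channel & type %in% c("dep", "both")
    phq4_anx <- q_channel & type %in% c("anx", "both")
    ## a questionnaire-channel case whose subtype draw leaves both subscales
    ## negative cannot exist; force the drawn subtype onto the subscale
    icd_baseline <- sample_codes(icd_channel & type %in% c("dep", "both"),
                                 icd_channel & type %in% c("anx", "both"))
    phq4_items <- sim_phq4_items(phq4_dep, phq4_anx)
    phq4_total <- rowSums(phq4_items)
  } else {
    ## linear_score mode: E[PHQ-4 total | AA] is exactly linear in AA_std
    p_tot <- (config$phq4_mean + config$beta_phq4 * aa_std + center_effect) / 12
    p_tot <- pmin(pmax(p_tot, 0), 1)
    phq4_total <- stats::rbinom(n, 12, p_tot)
    phq4_items <- split_phq4_total(phq4_total)
    sc <- score_phq4(phq4_items)
    prevalent <- sc$either_pos
    phq4_dep <- sc$dep_pos
    phq4_anx <- sc$anx_pos
    type <- ifelse(phq4_dep & phq4_anx, "both",
                   ifelse(phq4_dep, "dep", ifelse(phq4_anx, "anx",
                                                  ifelse(prevalent, "both", "none"))))
  }

  ## ----- incident events among the baseline-negative -----
  potential_end <- pmin(as.numeric(survey_date), as.numeric(config$censor_date),
                        na.rm = TRUE)
  potential_years <- (potential_end - as.numeric(baseline_date)) / 365.25
  onset <- out_sim$onset_years
  incident <- !prevalent & onset <= potential_years
  inc_type <- rep("none", n)
  inc_type[incident] <- sample_type(sum(incident), INCIDENT_TYPE_PROBS)
  hospital <- incident & (stats::runif(n) < config$prob_hospital_record)
  event_date <- as.Date(rep(NA, n))
  event_date[hospital] <- baseline_date[hospital] +
    round(onset[hospital] * 365.25)
  ## guard: record date may not pass the observation window end
  over <- which(hospital & as.numeric(event_date) > potential_end)
  if (length(over)) event_date[over] <- as.Date(potential_end[over],
                                                origin = "1970-01-01")
  icd_followup <- rep("", n)
  icd_followup[hospital] <- sample_codes(
    inc_type[hospital] %in% c("dep", "both"),
    inc_type[hospital] %in% c("anx", "both"))

  ## ----- follow-up survey instruments -----
  ## Surveyed participants whose onset precedes the survey screen positive
  ## for their incident subtype; everyone else surveyed screens negative.
  survey_case <- incident & survey_participant &
    onset <= (as.numeric(survey_date) - as.numeric(baseline_date)) / 365.25
  status <- data.frame(
    phq4_dep = phq4_dep, phq4_anx = phq4_anx,
    surveyed = survey_participant,
    survey_dep = survey_case & inc_type %in% c("dep", "both"),
    survey_anx = survey_case & inc_type %in% c("anx", "both"))
  qs <- simulate_questionnaires(status)
  ## baseline-logistic mode drew PHQ-4 above conditional on channel flags;
  ## keep those items (simulate_questionnaires re-drew them identically
  ## distributed, but the binomial-mean construction of linear_score mode
  ## must be preserved exactly)
  qs$phq4 <- phq4_items

  adversity <- sim_adversity_items(n)

  out <- data.frame(
    id = seq_len(n), baseline_date = baseline_date,
    age = age, sex = sex, race = race, bmi_cat = bmi_cat, smoking = smoking,
    healthy_alcohol = healthy_alcohol, healthy_activity = healthy_activity,
    townsend = townsend, hypertension = hypertension, chd = chd,
    diabetes = diabetes, center_id = center_id)
  out <- cbind(out, panel)
  out$prs <- prs
  colnames(qs$phq4) <- paste0("phq4_", 1:4)
  out <- cbind(out, qs$phq4)
  out$icd_baseline <- icd_baseline
  out$icd_followup <- icd_followup
  out$event_date <- event_date
  out$survey_date <- survey_date
  colnames(qs$phq9) <- paste0("phq9_", 1:9)
  colnames(qs$gad7) <- paste0("gad7_", 1:7)
  out <- cbind(out, qs$phq9, qs$gad7)
  names(adversity) <- paste0("adversity_", names(adversity))
  out <- cbind(out, adversity)
  out$incident_diabetes <- inc_diabetes
  out$incident_cvd <- inc_cvd
  out$incident_cancer <- inc_cancer
  out$true_prevalent <- prevalent
  out$true_baseline_type <- type
  out$true_incident <- incident & !prevalent
  out$true_incident_type <- inc_type
  out$true_onset_years <- onset

  if (config$missing_rate > 0) {
    for (bm in ALL_BIOMARKERS) {
      out[[bm]][stats::runif(n) < config$missing_rate] <- NA_real_
    }
  }

  attr(out, "kdm_parameters") <- kdm_params
  attr(out, "config") <- config
  out
}

#' Append clock, age-acceleration and derived mental-health columns
#'
#' Computes KDM-BA and PhenoAge, residualizes both on chronological age
#' (pooled, sex as a downstream model covariate), standardizes, assigns
#' quartiles, and derives prevalent/incident status and time at risk with
#' the package scorers. Records with missing biomarkers are excluded.
#'
#' @param cohort a cohort table (from [generate_cohort()] or read from disk)
#' @param kdm_params trained [fit_kdm()] parameters; defaults to the
#'   attribute attached by [generate_cohort()]
#' @param censor_date administrative censoring date
#' @return the cohort with columns `kdm_ba`, `phenoage`, `aa_kdm`,
#'   `aa_kdm_std`, `aa_kdm_q`, `aa_pheno`, `aa_pheno_std`, `aa_pheno_q`,
#'   prevalence/incidence flags, `event`, `event_time_years`,
#'   `adversity_score`, and survey scores
#' @export
score_cohort <- function(cohort, kdm_params = attr(cohort, "kdm_parameters"),
                         censor_date = as.Date("2018-12-31")) {
  cohort <- add_bioage(cohort, kdm_params)
  add_mental_health(cohort, censor_date = censor_date)
}

#' Append biological ages and age accelerations to a cohort table
#'
#' @inheritParams score_cohort
#' @return the cohort (complete-case rows only) with clock and AA columns
#' @export
add_bioage <- function(cohort, kdm_params = attr(cohort, "kdm_parameters")) {
  if (is.null(kdm_params)) {
    stop_bioagemh("kdm_params is required (train with fit_kdm)",
                  "bioagemh_input_error")
  }
  assert_columns(cohort, c("age", "sex", ALL_BIOMARKERS), "cohort table")
  complete <- stats::complete.cases(cohort[, c("age", ALL_BIOMARKERS)])
  cohort <- cohort[complete, , drop = FALSE]

  cohort$kdm_ba <- kdm_ba(cohort[, KDM_BIOMARKERS], cohort$age, kdm_params,
                          cohort$sex)
  cohort$phenoage <- phenoage(cohort[, PHENOAGE_BIOMARKERS], cohort$age)
  aa_k <- compute_aa(cohort$kdm_ba, cohort$age)
  aa_p <- compute_aa(cohort$phenoage, cohort$age)
  cohort$aa_kdm <- aa_k$aa_raw
  cohort$aa_kdm_std <- aa_k$aa_std
  cohort$aa_kdm_q <- aa_k$quartile
  cohort$aa_pheno <- aa_p$aa_raw
  cohort$aa_pheno_std <- aa_p$aa_std
  cohort$aa_pheno_q <- aa_p$quartile
  cohort
}

#' Append derived mental-health status columns to a cohort table
#'
#' @inheritParams score_cohort
#' @return the cohort with prevalence/incidence flags, times and scores
#' @export
add_mental_health <- function(cohort, censor_date = as.Date("2018-12-31")) {
  assert_columns(cohort, c("baseline_date", "icd_baseline", "icd_followup",
                           paste0("phq4_", 1:4)), "cohort table")
  prev <- define_prevalent(as.matrix(cohort[, paste0("phq4_", 1:4)]),
                           cohort$icd_baseline)
  cohort <- cbind(cohort, prev)
  inc <- define_incident(prev$prevalent_either, cohort$baseline_date,
                         cohort$event_date, cohort$survey_date,
                         cohort$icd_followup,
                         cohort[, paste0("phq9_", 1:9)],
                         cohort[, paste0("gad7_", 1:7)],
                         censor_date = censor_date)
  cohort <- cbind(cohort, inc)

  surveyed <- stats::complete.cases(cohort[, paste0("phq9_", 1:9)])
  cohort$phq9_total <- NA_real_
  cohort$gad7_total <- NA_real_
  if (any(surveyed)) {
    cohort$phq9_total[surveyed] <-
      score_phq9(as.matrix(cohort[surveyed, paste0("phq9_", 1:9)]))$total
    cohort$gad7_total[surveyed] <-
      score_gad7(as.matrix(cohort[surveyed, paste0("gad7_", 1:7)]))$total
  }
  adv_cols <- paste0("adversity_", names(ADVERSITY_PROBS))
  if (all(adv_cols %in% names(cohort))) {
    adv <- cohort[, adv_cols]
    names(adv) <- names(ADVERSITY_PROBS)
    cohort$adversity_score <- score_adversity(adv)
  }
  cohort
}
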
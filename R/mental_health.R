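## Questionnaire scoring, ICD case definitions, childhood adversity, and
## prevalent/incident status with follow-up time. All scorers are pure
## functions of their inputs.

PHQ9_SYMPTOMS <- c("suicidal_ideation", "sleeping_problems",
                   "psychomotor_changes", "feelings_of_inadequacy", "fatigue",
                   "depressed_mood", "cognitive_problems", "appetite_changes",
                   "anhedonia")
GAD7_SYMPTOMS <- c("worrying_control", "restlessness", "lack_of_relaxation",
                   "irritability", "generalized_worrying", "foreboding",
                   "anxiety_feeling")

check_items <- function(items, n, name) {
  items <- as.matrix(items)
  if (ncol(items) == 1 && n > 1) items <- matrix(items, ncol = n, byrow = TRUE)
  if (ncol(items) != n) {
    stop_bioagemh(sprintf("%s requires %d items per record", name, n),
                  "bioagemh_validation_error")
  }
  if (any(is.na(items)) || any(items < 0) || any(items > 3) ||
      any(items != round(items))) {
    stop_bioagemh(sprintf("%s items must be integers in 0-3", name),
                  "bioagemh_validation_error")
  }
  items
}

#' Score the PHQ-4 screener
#'
#' Items (0-3 each): 1 depressed mood, 2 anhedonia/disinterest,
#' 3 tenseness/restlessness, 4 tiredness/lethargy. Total >= 6 is positive
#' for depression/anxiety disorders; items 1+2 >= 3 positive for depression;
#' items 3+4 >= 3 positive for anxiety.
#'
#' @param items 4-column matrix (or length-4 vector) of item scores 0-3
#' @return data.frame: `total` (0-12), `either_pos`, `dep_pos`, `anx_pos`
#' @export
score_phq4 <- function(items) {
  items <- check_items(items, 4, "PHQ-4")
  total <- rowSums(items)
  dep <- items[, 1] + items[, 2]
  anx <- items[, 3] + items[, 4]
  data.frame(total = total,
             either_pos = total >= 6 | dep >= 3 | anx >= 3,
             dep_pos = dep >= 3,
             anx_pos = anx >= 3)
}

#' Score the PHQ-9 depression questionnaire
#'
#' Total >= 10 is positive; any item >= 1 flags that symptom.
#'
#' @param items 9-column matrix (or length-9 vector) of item scores 0-3
#' @return data.frame: `total` (0-27), `positive`, and one logical column per
#'   symptom (suicidal ideation ... anhedonia)
#' @export
score_phq9 <- function(items) {
  items <- check_items(items, 9, "PHQ-9")
  out <- data.frame(total = rowSums(items), positive = rowSums(items) >= 10)
  for (j in seq_along(PHQ9_SYMPTOMS)) out[[PHQ9_SYMPTOMS[j]]] <- items[, j] >= 1
  out
}

#' Score the GAD-7 anxiety questionnaire
#'
#' Total >= 10 is positive; any item >= 1 flags that symptom.
#'
#' @param items 7-column matrix (or length-7 vector) of item scores 0-3
#' @return data.frame: `total` (0-21), `positive`, and one logical column per
#'   symptom (worrying control ... anxiety feeling)
#' @export
score_gad7 <- function(items) {
  items <- check_items(items, 7, "GAD-7")
  out <- data.frame(total = rowSums(items), positive = rowSums(items) >= 10)
  for (j in seq_along(GAD7_SYMPTOMS)) out[[GAD7_SYMPTOMS[j]]] <- items[, j] >= 1
  out
}

#' Classify ICD-9/ICD-10 codes into depression / anxiety flags
#'
#' Depression: ICD-9 311, ICD-10 F32-F33; anxiety: ICD-9 300, ICD-10
#' F40-F41; primary or secondary diagnoses alike, sub-codes match by prefix
#' after normalization (uppercase, dots stripped). Unrecognized codes are
#' ignored.
#'
#' @param codes character vector of ICD codes, or a single semicolon-
#'   delimited string per record via [classify_icd_strings()]
#' @return list with logical scalars `depression`, `anxiety`
#' @export
classify_icd <- function(codes) {
  codes <- toupper(gsub(".", "", as.character(codes), fixed = TRUE))
  codes <- codes[nzchar(codes)]
  dep <- any(startsWith(codes, "311") | startsWith(codes, "F32") |
               startsWith(codes, "F33"))
  anx <- any(startsWith(codes, "300") | startsWith(codes, "F40") |
               startsWith(codes, "F41"))
  list(depression = dep, anxiety = anx)
}

#' Vectorized ICD classification over semicolon-delimited code strings
#'
#' @param x character vector; each element a semicolon-delimited ICD code
#'   list (empty string = no codes)
#' @return data.frame with logical columns `depression`, `anxiety`
#' @export
classify_icd_strings <- function(x) {
  x[is.na(x)] <- ""
  parts <- strsplit(x, ";", fixed = TRUE)
  res <- vapply(parts, function(cc) {
    f <- classify_icd(cc)
    c(f$depression, f$anxiety)
  }, logical(2))
  data.frame(depression = res[1, ], anxiety = res[2, ])
}

ADVERSITY_LEVELS <- c("never true", "rarely true", "sometimes true",
                      "often true", "very often true")

#' Childhood adversity score (0-5)
#'
#' Five Childhood Trauma Screener items, each dichotomized on its own
#' response set: physical neglect = 1 for never/rarely/sometimes/often true;
#' emotional neglect = 1 for never/rarely/sometimes true; sexual, physical
#' and emotional abuse = 1 for rarely/sometimes/often/very often true. The
#' score is the sum of the five indicators.
#'
#' @param items data.frame or matrix with columns `physical_neglect`,
#'   `emotional_neglect`, `sexual_abuse`, `physical_abuse`,
#'   `emotional_abuse`, entries among `"never true"`, `"rarely true"`,
#'   `"sometimes true"`, `"often true"`, `"very often true"`
#' @return integer vector of adversity scores 0-5
#' @export
score_adversity <- function(items) {
  items <- as.data.frame(items)
  cols <- c("physical_neglect", "emotional_neglect", "sexual_abuse",
            "physical_abuse", "emotional_abuse")
  assert_columns(items, cols, "adversity items")
  for (cl in cols) {
    bad <- !(items[[cl]] %in% ADVERSITY_LEVELS)
    if (any(bad)) {
      stop_bioagemh(sprintf("unknown response label in '%s': %s", cl,
                            paste(unique(items[[cl]][bad]), collapse = ", ")),
                    "bioagemh_validation_error")
    }
  }
  pn <- items$physical_neglect %in% ADVERSITY_LEVELS[1:4]
  en <- items$emotional_neglect %in% ADVERSITY_LEVELS[1:3]
  abuse_set <- ADVERSITY_LEVELS[2:5]
  sa <- items$sexual_abuse %in% abuse_set
  pa <- items$physical_abuse %in% abuse_set
  ea <- items$emotional_abuse %in% abuse_set
  as.integer(pn + en + sa + pa + ea)
}

#' Prevalent depression/anxiety at baseline
#'
#' Union of the baseline PHQ-4 screen (total >= 6 or either subscale >= 3)
#' and baseline hospital-record ICD flags; component flags are exposed.
#'
#' @param phq4_items 4-column matrix of baseline PHQ-4 items
#' @param icd_baseline character vector of semicolon-delimited baseline ICD
#'   code strings
#' @return data.frame with `prevalent_either`, `prevalent_dep`,
#'   `prevalent_anx` plus the questionnaire and hospital component flags
#' @export
define_prevalent <- function(phq4_items, icd_baseline) {
  q <- score_phq4(phq4_items)
  h <- classify_icd_strings(icd_baseline)
  data.frame(
    phq4_total = q$total,
    phq4_either = q$either_pos, phq4_dep = q$dep_pos, phq4_anx = q$anx_pos,
    icd_dep = h$depression, icd_anx = h$anxiety,
    prevalent_dep = q$dep_pos | h$depression,
    prevalent_anx = q$anx_pos | h$anxiety,
    prevalent_either = q$either_pos | h$depression | h$anxiety
  )
}

#' Incident depression/anxiety and time at risk
#'
#' For participants free of depression/anxiety at baseline, incident cases
#' are hospital records of depression/anxiety during follow-up OR positivity
#' at the follow-up survey (PHQ-9 >= 10 for depression, GAD-7 >= 10 for
#' anxiety, dated at survey completion). Follow-up ends at the earliest of
#' the incident event, the follow-up survey, and administrative censoring.
#'
#' @param prevalent logical vector of baseline prevalence (from
#'   [define_prevalent()]); incident flags are `NA` for prevalent rows
#' @param baseline_date,event_date,survey_date Date vectors (`NA` where
#'   absent); `event_date` is the hospital-record date of the first
#'   depression/anxiety episode during follow-up
#' @param icd_followup semicolon-delimited ICD codes attached to the
#'   follow-up hospital record
#' @param phq9_items,gad7_items follow-up survey item matrices (rows of `NA`
#'   for non-participants)
#' @param censor_date administrative censoring date (default 2018-12-31)
#' @return data.frame with `incident_dep`, `incident_anx`, `incident_either`,
#'   `incident_both`, `event` (0/1 for either disorder), `event_time_years`
#'   (time at risk), and `end_date`
#' @export
define_incident <- function(prevalent, baseline_date, event_date, survey_date,
                            icd_followup, phq9_items, gad7_items,
                            censor_date = as.Date("2018-12-31")) {
  n <- length(prevalent)
  baseline_date <- as.Date(baseline_date)
  event_date <- as.Date(event_date)
  survey_date <- as.Date(survey_date)
  if (any(!is.na(event_date) & event_date < baseline_date)) {
    stop_bioagemh("hospital event date precedes baseline date",
                  "bioagemh_data_error")
  }
  hosp <- classify_icd_strings(icd_followup)
  ## Hospital records only count while under observation: on or before the
  ## earlier of the follow-up survey and administrative censoring.
  window_end <- pmin(as.numeric(survey_date), as.numeric(censor_date),
                     na.rm = TRUE)
  hosp_valid <- !is.na(event_date) & as.numeric(event_date) <= window_end
  hosp$depression <- hosp$depression & hosp_valid
  hosp$anxiety <- hosp$anxiety & hosp_valid

  ## Survey positivity, dated at survey completion; rows with any NA item are
  ## treated as not surveyed for that instrument.
  survey_dep <- survey_anx <- rep(FALSE, n)
  ok9 <- stats::complete.cases(phq9_items) & !is.na(survey_date)
  if (any(ok9)) {
    survey_dep[ok9] <- score_phq9(as.matrix(phq9_items)[ok9, , drop = FALSE])$positive
  }
  ok7 <- stats::complete.cases(gad7_items) & !is.na(survey_date)
  if (any(ok7)) {
    survey_anx[ok7] <- score_gad7(as.matrix(gad7_items)[ok7, , drop = FALSE])$positive
  }

  ## Event date per channel; when both channels fire, the earlier date wins.
  dep_date <- ifelse(hosp$depression, as.numeric(event_date), NA_real_)
  dep_date <- pmin(dep_date, ifelse(survey_dep, as.numeric(survey_date), NA_real_),
                   na.rm = TRUE)
  anx_date <- ifelse(hosp$anxiety, as.numeric(event_date), NA_real_)
  anx_date <- pmin(anx_date, ifelse(survey_anx, as.numeric(survey_date), NA_real_),
                   na.rm = TRUE)
  either_date <- pmin(dep_date, anx_date, na.rm = TRUE)

  incident_dep <- hosp$depression | survey_dep
  incident_anx <- hosp$anxiety | survey_anx
  incident_either <- incident_dep | incident_anx

  end_num <- pmin(ifelse(incident_either, either_date, NA_real_),
                  as.numeric(survey_date),
                  as.numeric(censor_date), na.rm = TRUE)
  time_years <- (end_num - as.numeric(baseline_date)) / 365.25
  if (any(time_years < 0, na.rm = TRUE)) {
    stop_bioagemh("negative time at risk; check dates", "bioagemh_data_error")
  }

  ## Subtype-specific time at risk: follow-up for depression ends at the
  ## depression event, the survey, or censoring (an anxiety-only event does
  ## not end depression follow-up), and symmetrically for anxiety. The
  ## co-incident outcome fires at the later of the two events.
  admin_end <- pmin(as.numeric(survey_date), as.numeric(censor_date),
                    na.rm = TRUE)
  time_dep <- (pmin(dep_date, admin_end, na.rm = TRUE) -
                 as.numeric(baseline_date)) / 365.25
  time_anx <- (pmin(anx_date, admin_end, na.rm = TRUE) -
                 as.numeric(baseline_date)) / 365.25
  both_date <- pmax(dep_date, anx_date)  # NA unless both occurred
  incident_both <- incident_dep & incident_anx
  time_both <- (pmin(ifelse(incident_both, both_date, NA_real_), admin_end,
                     na.rm = TRUE) - as.numeric(baseline_date)) / 365.25

  out <- data.frame(
    incident_dep = incident_dep, incident_anx = incident_anx,
    incident_either = incident_either,
    incident_both = incident_both,
    event = as.integer(incident_either),
    event_time_years = time_years,
    event_dep = as.integer(incident_dep), time_dep = time_dep,
    event_anx = as.integer(incident_anx), time_anx = time_anx,
    event_both = as.integer(incident_both), time_both = time_both,
    end_date = as.Date(end_num, origin = "1970-01-01")
  )
  ## Incidence is only defined among baseline-free participants.
  na_cols <- c("incident_dep", "incident_anx", "incident_either",
               "incident_both", "event", "event_time_years", "event_dep",
               "time_dep", "event_anx", "time_anx", "event_both", "time_both")
  out[prevalent, na_cols] <- NA
  out
}
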
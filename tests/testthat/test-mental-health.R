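test_that("PHQ-4 thresholds match an exhaustive enumeration oracle", {
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3))
  sc <- score_phq4(grid)
  # brute-force oracle over all 256 item vectors
  tot <- unname(rowSums(grid))
  dep <- unname(grid[, 1] + grid[, 2] >= 3)
  anx <- unname(grid[, 3] + grid[, 4] >= 3)
  expect_equal(sc$total, tot)
  expect_equal(sc$dep_pos, dep)
  expect_equal(sc$anx_pos, anx)
  expect_equal(sc$either_pos, tot >= 6 | dep | anx)
  # boundary examples
  b <- score_phq4(rbind(c(3, 3, 0, 0), c(1, 1, 1, 1)))
  expect_equal(b$total, c(6, 4))
  expect_equal(b$either_pos, c(TRUE, FALSE))
  expect_equal(b$dep_pos, c(TRUE, FALSE))
  expect_equal(b$anx_pos, c(FALSE, FALSE))
  expect_error(score_phq4(c(4, 0, 0, 0)), class = "bioagemh_error")
})

test_that("PHQ-9 / GAD-7 positivity equals a re-summation oracle", {
  set.seed(51)
  m9 <- matrix(sample(0:3, 9 * 10000, TRUE), ncol = 9)
  s9 <- score_phq9(m9)
  expect_identical(s9$positive, rowSums(m9) >= 10)
  expect_identical(s9$total, rowSums(m9))
  m7 <- matrix(sample(0:3, 7 * 10000, TRUE), ncol = 7)
  s7 <- score_gad7(m7)
  expect_identical(s7$positive, rowSums(m7) >= 10)
  # boundaries and symptom flags
  all1 <- score_phq9(matrix(1, 1, 9))
  expect_equal(all1$total, 9)
  expect_false(all1$positive)
  expect_true(all(unlist(all1[1, -(1:2)])))  # all 9 symptom flags on
  g <- score_gad7(matrix(c(3, 3, 3, 1, 0, 0, 0), 1))
  expect_equal(g$total, 10)
  expect_true(g$positive)
  expect_error(score_phq9(matrix(0, 1, 7)), class = "bioagemh_error")
})

test_that("ICD prefix classification follows the code ranges", {
  expect_true(classify_icd("F33.2")$depression)
  expect_false(classify_icd("F33.2")$anxiety)
  expect_true(classify_icd("3000")$anxiety)      # ICD-9 300.0
  expect_false(classify_icd("F31")$depression)   # bipolar: out of set
  expect_false(classify_icd("F31")$anxiety)
  expect_true(classify_icd(c("I10", "f410"))$anxiety)  # case-insensitive
  expect_false(classify_icd("F300")$anxiety)     # F30.0 mania, not ICD-9 300
  x <- classify_icd_strings(c("F32;F41", "", NA, "311"))
  expect_equal(x$depression, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(x$anxiety, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("adversity dichotomization matches a lookup oracle on all 3125 grids", {
  lv <- c("never true", "rarely true", "sometimes true", "often true",
          "very often true")
  grid <- expand.grid(physical_neglect = lv, emotional_neglect = lv,
                      sexual_abuse = lv, physical_abuse = lv,
                      emotional_abuse = lv, stringsAsFactors = FALSE)
  got <- score_adversity(grid)
  # independent lookup tables keyed by response rank 1..5
  pn_tab <- c(1, 1, 1, 1, 0)  # never..often -> 1
  en_tab <- c(1, 1, 1, 0, 0)  # never..sometimes -> 1
  ab_tab <- c(0, 1, 1, 1, 1)  # rarely..very often -> 1
  oracle <- pn_tab[match(grid$physical_neglect, lv)] +
    en_tab[match(grid$emotional_neglect, lv)] +
    ab_tab[match(grid$sexual_abuse, lv)] +
    ab_tab[match(grid$physical_abuse, lv)] +
    ab_tab[match(grid$emotional_abuse, lv)]
  expect_identical(got, as.integer(oracle))
  # printed-rule spot checks
  all_never <- grid[grid$physical_neglect == lv[1] &
                      grid$emotional_neglect == lv[1] &
                      grid$sexual_abuse == lv[1] & grid$physical_abuse == lv[1] &
                      grid$emotional_abuse == lv[1], ]
  expect_equal(score_adversity(all_never), 2L)
  all_vot <- data.frame(physical_neglect = lv[5], emotional_neglect = lv[5],
                        sexual_abuse = lv[5], physical_abuse = lv[5],
                        emotional_abuse = lv[5])
  expect_equal(score_adversity(all_vot), 3L)
  expect_error(score_adversity(transform(all_vot, sexual_abuse = "maybe")),
               class = "bioagemh_error")
})

test_that("prevalence is the union of questionnaire and hospital channels", {
  phq4 <- rbind(c(3, 3, 0, 0),  # questionnaire depression
                c(0, 0, 0, 0),  # hospital anxiety only
                c(0, 0, 0, 0),  # clean
                c(2, 2, 2, 2))  # total 8 >= 6
  icd <- c("", "F401", "", "")
  pr <- define_prevalent(phq4, icd)
  expect_equal(pr$prevalent_either, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(pr$prevalent_dep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(pr$prevalent_anx, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("follow-up time follows the min-date rule (brute force, 1000 triples)", {
  set.seed(53)
  n <- 1000
  baseline <- as.Date("2008-06-01") + sample(0:800, n, TRUE)
  event <- baseline + sample(100:3500, n, TRUE)
  has_event <- runif(n) < 0.5
  event[!has_event] <- NA
  survey <- as.Date("2016-01-01") + sample(0:500, n, TRUE)
  surveyed <- runif(n) < 0.4
  survey[!surveyed] <- NA
  censor <- as.Date("2018-12-31")
  phq9 <- matrix(0L, n, 9); phq9[!surveyed, ] <- NA
  gad7 <- matrix(0L, n, 7); gad7[!surveyed, ] <- NA
  icd <- ifelse(has_event, "F32", "")
  inc <- define_incident(rep(FALSE, n), baseline, event, survey, icd,
                         phq9, gad7, censor)
  for (i in seq_len(n)) {
    # brute-force: enumerate candidate end dates and take the minimum
    window_end <- min(c(survey[i], censor), na.rm = TRUE)
    cand <- c(survey[i], censor)
    if (has_event[i] && !is.na(event[i]) && event[i] <= window_end) {
      cand <- c(cand, event[i])
    }
    expect_equal(inc$event_time_years[i],
                 as.numeric(min(cand, na.rm = TRUE) - baseline[i]) / 365.25)
  }
  # time at risk never exceeds the administrative maximum
  expect_true(all(inc$event_time_years <=
                    as.numeric(censor - baseline) / 365.25 + 1e-12))
})

test_that("worked date examples follow the earliest-date rule", {
  inc <- define_incident(
    prevalent = c(FALSE, FALSE),
    baseline_date = as.Date(c("2008-06-01", "2008-06-01")),
    event_date = as.Date(c("2012-06-01", NA)),
    survey_date = as.Date(c("2016-09-01", "2016-09-01")),
    icd_followup = c("F329", ""),
    phq9_items = matrix(0L, 2, 9), gad7_items = matrix(0L, 2, 7))
  expect_equal(inc$event, c(1L, 0L))
  expect_equal(inc$event_time_years[1], 4.0, tolerance = 1e-9)
  # censored at survey date when survey-negative and no hospital record
  expect_equal(inc$end_date[2], as.Date("2016-09-01"))
  expect_error(define_incident(FALSE, as.Date("2010-01-01"),
                               as.Date("2009-01-01"), as.Date(NA), "F32",
                               matrix(NA_integer_, 1, 9),
                               matrix(NA_integer_, 1, 7)),
               class = "bioagemh_error")
})

test_that("incident flags never fire for prevalent participants", {
  sc <- scored_cohort(n = 3000, seed = 55)
  expect_true(all(is.na(sc$incident_either[sc$prevalent_either])))
  expect_true(all(is.na(sc$event_time_years[sc$prevalent_either])))
  free <- !sc$prevalent_either
  expect_true(all(!is.na(sc$incident_either[free])))
  expect_true(all(sc$event_time_years[free] >= 0))
  # survey positivity without a hospital record is detected as incident
  srv <- define_incident(FALSE, as.Date("2009-01-01"), as.Date(NA),
                         as.Date("2016-06-01"), "",
                         matrix(2L, 1, 9), matrix(0L, 1, 7))
  expect_true(srv$incident_dep)
  expect_false(srv$incident_anx)
  expect_equal(srv$end_date, as.Date("2016-06-01"))
})
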
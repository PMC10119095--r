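#' Default sex-specific biomarker-on-age generating parameters
#'
#' One row per sex and biomarker: intercept `q` (biomarker units), slope `k`
#' (units/year), residual SD `s`, the latent aging-factor direction `dir`
#' (+1 if the marker rises with biological aging, -1 if it falls), and
#' `log_scale` (TRUE for CRP, whose age-linear quantity is ln(CRP) so the
#' marker stays positive). Values are chosen so that the mean trajectory at
#' age 56.5 matches a large midlife population cohort (FEV1 ~2.8 L, SBP ~140
#' mm Hg, total cholesterol ~220 mg/dL, HbA1c ~5.4 %, BUN ~15 mg/dL, albumin
#' ~4.5 g/dL, creatinine ~0.8 mg/dL, CRP ~0.2 mg/dL, ALP ~83 U/L, glucose
#' ~92 mg/dL, lymphocytes ~29 %, MCV ~83 fL, RDW ~13.5 %, WBC ~6.8 10^3/uL).
#' The four markers shared by the two clocks (albumin, creatinine, CRP, ALP)
#' carry small age slopes, as clinically observed.
#'
#' @return data.frame with columns `sex`, `biomarker`, `q`, `k`, `s`, `dir`,
#'   `log_scale`
#' @export
default_biomarker_params <- function() {
  ## mean value at age 56.5, slope per year, residual SD, aging direction
  spec <- list(
    #                   male                      female
    fev1            = list(m = c(3.20, -0.025, 0.55), f = c(2.50, -0.022, 0.45), dir = -1),
    sbp             = list(m = c(142.0, 0.55, 17.5),  f = c(137.0, 0.60, 17.5),  dir = +1),
    total_cholesterol = list(m = c(215, 0.40, 41.0),  f = c(225, 0.60, 40.0),    dir = +1),
    hba1c           = list(m = c(5.46, 0.012, 0.50),  f = c(5.42, 0.012, 0.50),  dir = +1),
    bun             = list(m = c(15.6, 0.080, 3.50),  f = c(14.6, 0.080, 3.40),  dir = +1),
    albumin         = list(m = c(4.55, -2.5e-4, 0.23), f = c(4.49, -2.5e-4, 0.23), dir = -1),
    creatinine      = list(m = c(0.92, 1.2e-4, 0.12), f = c(0.72, 1.2e-4, 0.11), dir = +1),
    crp             = list(m = c(-1.90, 0.001, 1.00), f = c(-1.90, 0.001, 1.00), dir = +1),
    alp             = list(m = c(85.0, 0.025, 24.0),  f = c(81.0, 0.025, 24.0),  dir = +1),
    glucose         = list(m = c(92.5, 0.30, 18.0),   f = c(91.0, 0.30, 18.0),   dir = +1),
    lymphocyte_pct  = list(m = c(28.5, -0.05, 7.20),  f = c(29.2, -0.05, 7.20),  dir = -1),
    mcv             = list(m = c(83.2, 0.060, 5.00),  f = c(82.6, 0.060, 5.00),  dir = +1),
    rdw             = list(m = c(13.50, 0.010, 0.92), f = c(13.46, 0.010, 0.92), dir = +1),
    wbc             = list(m = c(6.90, 0.010, 1.90),  f = c(6.80, 0.010, 1.90),  dir = +1)
  )
  rows <- lapply(names(spec), function(bm) {
    sp <- spec[[bm]]
    do.call(rbind, lapply(c(male = "m", female = "f"), function(sx) {
      v <- sp[[sx]]
      data.frame(sex = if (sx == "m") "male" else "female",
                 biomarker = bm,
                 q = v[1] - v[2] * 56.5, k = v[2], s = v[3],
                 dir = sp$dir, log_scale = bm == "crp")
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the KDM reference population generator
#'
#' @param n number of reference individuals (>= 200)
#' @param age_range age span in years (default 30-75, a nonpregnant
#'   reference-population convention for training clinical-biomarker clocks)
#' @param biomarker_params data.frame as in [default_biomarker_params()]
#' @param prop_male fraction male
#' @param seed integer RNG seed
#' @return a `reference_config` list
#' @export
reference_config <- function(n = 10000, age_range = c(30, 75),
                             biomarker_params = default_biomarker_params(),
                             prop_male = 0.5, seed = 1L) {
  if (n < 200) stop_bioagemh("reference n must be >= 200", "bioagemh_config_error")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop_bioagemh("age_range must be (min, max) with min < max",
                  "bioagemh_config_error")
  }
  if (any(biomarker_params$s <= 0)) {
    stop_bioagemh("biomarker noise SDs must be > 0", "bioagemh_config_error")
  }
  assert_fraction(prop_male, "prop_male")
  structure(list(n = as.integer(n), age_range = age_range,
                 biomarker_params = biomarker_params,
                 prop_male = prop_male, seed = as.integer(seed)),
            class = "reference_config")
}

## Draw one biomarker column: q + k*age + noise (exponentiated if the
## age-linear quantity lives on the log scale). `extra` adds latent-factor
## noise on the linear-quantity scale.
draw_biomarker <- function(age, sex, params, bm, extra = 0, noise_scale = 1) {
  x <- numeric(length(age))
  for (sx in c("male", "female")) {
    idx <- which(sex == sx)
    if (!length(idx)) next
    p <- params[params$sex == sx & params$biomarker == bm, ]
    ex <- if (length(extra) == 1) extra else extra[idx]
    x[idx] <- p$q + p$k * age[idx] + ex +
      stats::rnorm(length(idx), 0, p$s * noise_scale)
  }
  if (params$log_scale[params$biomarker == bm][1]) x <- exp(x)
  x
}

#' Generate a reference population for KDM training
#'
#' Sex-stratified linear biomarker-on-age trajectories with Gaussian noise:
#' `biomarker_i = q_i + k_i * age + N(0, s_i^2)` (ln CRP for the CRP column).
#' Deterministic given the config seed.
#'
#' @param config a [reference_config()]
#' @return data.frame with `sex`, `age`, and the 14 biomarker columns
#' @export
generate_reference <- function(config) {
  if (!inherits(config, "reference_config")) {
    stop_bioagemh("config must be a reference_config", "bioagemh_config_error")
  }
  set.seed(config$seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  out <- data.frame(sex = sex, age = age)
  for (bm in unique(config$biomarker_params$biomarker)) {
    out[[bm]] <- draw_biomarker(age, sex, config$biomarker_params, bm)
  }
  out
}
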
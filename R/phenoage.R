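#' PhenoAge model constants
#'
#' Fixed coefficients of the published PhenoAge algorithm: a Gompertz
#' proportional-hazards model of mortality trained on nine blood chemistries
#' plus chronological age, converted to an age scale via the mortality-risk
#' CDF over a 120-month horizon. The weights are only meaningful in the
#' original unit system (albumin g/L, creatinine umol/L, glucose mmol/L,
#' CRP natural-logged in mg/dL, lymphocytes %, MCV fL, RDW %, ALP U/L,
#' WBC 10^3 cells/uL); [phenoage()] converts from panel units internally.
#'
#' @format A list with elements `intercept`, `weights` (named numeric),
#'   `gamma`, `horizon_months`, and the age-mapping constants `a`, `b`, `c`.
#' @export
phenoage_constants <- function() {
  list(
    intercept = -19.907,
    weights = c(
      albumin            = -0.0336,   # per g/L
      creatinine         =  0.0095,   # per umol/L
      glucose            =  0.1953,   # per mmol/L
      log_crp            =  0.0954,   # per ln(mg/dL)
      lymphocyte_pct     = -0.012,    # per %
      mcv                =  0.0268,   # per fL
      rdw                =  0.3306,   # per %
      alp                =  0.00188,  # per U/L
      wbc                =  0.0554,   # per 10^3 cells/uL
      chronological_age  =  0.0804    # per year
    ),
    gamma = 0.0076927,
    horizon_months = 120,
    a = 0.00553,
    b = 0.090165,
    c = 141.50225
  )
}

## Unit conversions from panel (Table-1) units to PhenoAge model units.
phenoage_unit_convert <- function(panel) {
  list(
    albumin        = panel$albumin * 10,           # g/dL -> g/L
    creatinine     = panel$creatinine * 88.4017,   # mg/dL -> umol/L
    glucose        = panel$glucose / 18.016,       # mg/dL -> mmol/L
    log_crp        = log(panel$crp),               # ln(mg/dL)
    lymphocyte_pct = panel$lymphocyte_pct,
    mcv            = panel$mcv,
    rdw            = panel$rdw,
    alp            = panel$alp,
    wbc            = panel$wbc
  )
}

#' PhenoAge linear predictor
#'
#' @param panel data.frame with the nine PhenoAge biomarkers in panel units
#'   (albumin g/dL, creatinine mg/dL, glucose mg/dL, crp mg/dL,
#'   lymphocyte_pct %, mcv fL, rdw %, alp U/L, wbc 10^3 cells/uL)
#' @param ca chronological age in years
#' @return numeric vector, the Gompertz linear predictor xb
#' @export
phenoage_xb <- function(panel, ca) {
  assert_columns(panel, PHENOAGE_BIOMARKERS, "PhenoAge panel")
  if (any(!is.na(panel$crp) & panel$crp <= 0)) {
    stop_bioagemh("crp must be strictly positive (it is log-transformed)",
                  "bioagemh_domain_error")
  }
  k <- phenoage_constants()
  u <- phenoage_unit_convert(panel)
  xb <- k$intercept + k$weights["chronological_age"] * ca
  for (nm in setdiff(names(k$weights), "chronological_age")) {
    xb <- xb + k$weights[nm] * u[[nm]]
  }
  unname(xb)
}

#' Ten-year mortality risk from the PhenoAge Gompertz model
#'
#' `1 - exp(-exp(xb) * (exp(gamma * 120) - 1) / gamma)`: the Gompertz CDF
#' over a 120-month horizon for a subject with linear predictor `xb`.
#'
#' @param xb linear predictor from [phenoage_xb()]
#' @return mortality risk in (0, 1) for finite xb
#' @export
phenoage_mortality_risk <- function(xb) {
  k <- phenoage_constants()
  -expm1(-exp(xb) * (exp(k$gamma * k$horizon_months) - 1) / k$gamma)
}

#' PhenoAge (years)
#'
#' Maps the nine-biomarker mortality risk to the chronological age with the
#' same expected risk in the training population:
#' `PhenoAge = 141.50225 + ln(0.00553 * (-ln(1 - risk))) / 0.090165`.
#'
#' @inheritParams phenoage_xb
#' @return PhenoAge in years
#' @export
phenoage <- function(panel, ca) {
  xb <- phenoage_xb(panel, ca)
  k <- phenoage_constants()
  risk <- phenoage_mortality_risk(xb)
  ## -log(1 - risk) re-expands to exp(xb)*(exp(120 gamma)-1)/gamma; evaluate
  ## through log1p for numerical stability at small risk.
  k$c + log(k$a * (-log1p(-risk))) / k$b
}
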
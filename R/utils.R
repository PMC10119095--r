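#' @keywords internal
"_PACKAGE"

## Canonical biomarker column names (Table-1 units).
## KDM-BA inputs: fev1, sbp, total_cholesterol, hba1c, bun, albumin,
## creatinine, crp, alp.  PhenoAge inputs: albumin, creatinine, glucose, crp,
## lymphocyte_pct, mcv, rdw, alp, wbc.  Union = 14 columns.
KDM_BIOMARKERS <- c("fev1", "sbp", "total_cholesterol", "hba1c", "bun",
                    "albumin", "creatinine", "crp", "alp")
PHENOAGE_BIOMARKERS <- c("albumin", "creatinine", "glucose", "crp",
                         "lymphocyte_pct", "mcv", "rdw", "alp", "wbc")
ALL_BIOMARKERS <- union(KDM_BIOMARKERS, PHENOAGE_BIOMARKERS)

stop_bioagemh <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bioagemh_error")))
}

assert_columns <- function(df, cols, where = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_bioagemh(
      sprintf("%s is missing required column(s): %s", where,
              paste(missing, collapse = ", ")),
      "bioagemh_schema_error")
  }
  invisible(df)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_bioagemh(sprintf("'%s' must be a fraction in [0, 1]", name),
                  "bioagemh_config_error")
  }
  invisible(x)
}

#' Wald confidence bounds on the log scale
#'
#' @param est log-scale estimate
#' @param se standard error of the log-scale estimate
#' @param level confidence level
#' @return list with exp-scale estimate, ci_low, ci_high
#' @keywords internal
wald_exp_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = exp(est), ci_low = exp(est - z * se),
       ci_high = exp(est + z * se))
}
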
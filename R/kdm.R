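#' Train Klemera-Doubal biological age parameters on a reference table
#'
#' Each biomarker is regressed on chronological age, separately by sex
#' (`x_i = q_i + k_i * CA + e`, OLS), yielding intercept `q_i`, slope `k_i`
#' and root-mean-squared error `s_i`. CRP enters as `ln(CRP)`, matching its
#' use in both clocks. The scaling factor `s_ba` is the square root of the
#' variance in chronological age explained by the biomarker set: by default
#' `s_ba^2 = R^2 * Var(CA)` from the multivariable OLS of CA on the nine
#' biomarkers within the sex stratum (`sba_method = "explained_variance"`);
#' `sba_method = "kd"` instead uses the original Klemera-Doubal corrected
#' estimator based on the dispersion of per-biomarker age estimates.
#'
#' @param reference data.frame with columns `sex` ("male"/"female"), `age`
#'   (years) and the nine KDM biomarkers (`fev1`, `sbp`, `total_cholesterol`,
#'   `hba1c`, `bun`, `albumin`, `creatinine`, `crp`, `alp`) in panel units
#' @param sba_method `"explained_variance"` (default) or `"kd"`
#' @param min_n minimum rows required per sex stratum
#' @return an object of class `kdm_parameters`: a list with one entry per
#'   sex, each holding `q`, `k`, `s` (named by biomarker, CRP as `log_crp`)
#'   and `s_ba`
#' @export
fit_kdm <- function(reference, sba_method = c("explained_variance", "kd"),
                    min_n = 30) {
  sba_method <- match.arg(sba_method)
  assert_columns(reference, c("sex", "age", KDM_BIOMARKERS),
                 "KDM reference table")
  sexes <- c("male", "female")
  if (!all(sexes %in% reference$sex)) {
    stop_bioagemh("reference must contain both 'male' and 'female' rows",
                  "bioagemh_training_error")
  }
  out <- list(sba_method = sba_method)
  for (sx in sexes) {
    ref <- reference[reference$sex == sx, , drop = FALSE]
    ref <- ref[stats::complete.cases(ref[, c("age", KDM_BIOMARKERS)]), ,
               drop = FALSE]
    if (nrow(ref) < min_n) {
      stop_bioagemh(
        sprintf("sex stratum '%s' has %d complete rows; >= %d required",
                sx, nrow(ref), min_n),
        "bioagemh_training_error")
    }
    feats <- kdm_feature_matrix(ref)
    q <- k <- s <- stats::setNames(numeric(ncol(feats)), colnames(feats))
    for (nm in colnames(feats)) {
      x <- feats[, nm]
      if (stats::var(x) == 0) {
        stop_bioagemh(sprintf("biomarker '%s' has zero variance in stratum '%s'",
                              nm, sx), "bioagemh_training_error")
      }
      fit <- stats::lm(x ~ ref$age)
      q[nm] <- stats::coef(fit)[1]
      k[nm] <- stats::coef(fit)[2]
      s[nm] <- sqrt(mean(stats::residuals(fit)^2))
    }
    mfit <- stats::lm(ref$age ~ feats)
    r2 <- summary(mfit)$r.squared
    ## population moment: invariant to duplicating reference rows
    var_ca <- mean((ref$age - mean(ref$age))^2)
    s_ba2 <- r2 * var_ca
    if (sba_method == "kd") {
      ## Klemera-Doubal corrected estimator: dispersion of the biomarker-only
      ## age estimate around CA, minus the expected estimation noise.
      ba_e <- kdm_ba_biomarkers_only(feats, q, k, s)
      m <- length(k)
      rchar <- sqrt(r2)
      noise <- (1 - rchar^2) / rchar^2 *
        (max(ref$age) - min(ref$age))^2 / (12 * m)
      s_ba2 <- mean((ba_e - ref$age)^2) - noise
      if (!is.finite(s_ba2) || s_ba2 <= 0) s_ba2 <- r2 * var_ca
    }
    out[[sx]] <- list(q = q, k = k, s = s, s_ba = sqrt(s_ba2))
  }
  class(out) <- "kdm_parameters"
  out
}

## Feature matrix for the KDM regressions: panel units, CRP log-transformed.
kdm_feature_matrix <- function(df) {
  feats <- as.matrix(df[, KDM_BIOMARKERS])
  colnames(feats) <- KDM_BIOMARKERS
  feats[, "crp"] <- log(feats[, "crp"])
  colnames(feats)[colnames(feats) == "crp"] <- "log_crp"
  feats
}

## Biomarker-only KDM estimate (the s_ba -> Inf limit).
kdm_ba_biomarkers_only <- function(feats, q, k, s) {
  num <- rep(0, nrow(feats))
  den <- 0
  for (nm in colnames(feats)) {
    num <- num + (feats[, nm] - q[nm]) * k[nm] / s[nm]^2
    den <- den + (k[nm] / s[nm])^2
  }
  num / den
}

#' Klemera-Doubal biological age
#'
#' `KDM-BA = [sum_i (x_i - q_i) k_i / s_i^2 + CA / s_ba^2] /
#'           [sum_i (k_i / s_i)^2 + 1 / s_ba^2]`,
#' the precision-weighted average of the per-biomarker age estimates
#' `(x_i - q_i)/k_i` and chronological age.
#'
#' @param panel data.frame with the nine KDM biomarkers in panel units
#' @param ca chronological age vector (years)
#' @param params `kdm_parameters` from [fit_kdm()]
#' @param sex character vector ("male"/"female"), recycled if length 1
#' @return biological age in years
#' @export
kdm_ba <- function(panel, ca, params, sex) {
  stopifnot(inherits(params, "kdm_parameters"))
  assert_columns(panel, KDM_BIOMARKERS, "KDM panel")
  if (length(sex) == 1) sex <- rep(sex, length(ca))
  feats <- kdm_feature_matrix(panel)
  if (any(!stats::complete.cases(feats)) || any(is.na(ca))) {
    stop_bioagemh("missing biomarker or age values; exclude incomplete records upstream",
                  "bioagemh_missing_data_error")
  }
  ba <- rep(NA_real_, length(ca))
  for (sx in c("male", "female")) {
    idx <- which(sex == sx)
    if (!length(idx)) next
    p <- params[[sx]]
    num <- ca[idx] / p$s_ba^2
    den <- 1 / p$s_ba^2
    for (nm in colnames(feats)) {
      num <- num + (feats[idx, nm] - p$q[nm]) * p$k[nm] / p$s[nm]^2
      den <- den + (p$k[nm] / p$s[nm])^2
    }
    ba[idx] <- num / den
  }
  ba
}
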
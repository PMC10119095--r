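#' Age acceleration from biological and chronological age
#'
#' Regresses biological age on chronological age within the analysis cohort
#' (OLS) and takes the residuals as "age acceleration" (AA): positive values
#' mean biologically older than peers of the same chronological age. AAs are
#' standardized to mean 0 / SD 1 in-cohort, and cut at the empirical
#' quartiles for dose-response analysis (values equal to a cut-point go to
#' the lower quartile).
#'
#' @param ba biological age vector (years)
#' @param ca chronological age vector (years), same length, length >= 4
#' @return data.frame with columns `aa_raw` (years), `aa_std` (unitless;
#'   `NA` with a warning when the residuals are degenerate, SD = 0) and
#'   `quartile` (integer 1-4)
#' @export
compute_aa <- function(ba, ca) {
  if (length(ba) != length(ca) || length(ba) < 4) {
    stop_bioagemh("ba and ca must have equal length >= 4",
                  "bioagemh_input_error")
  }
  if (any(!is.finite(ba)) || any(!is.finite(ca))) {
    stop_bioagemh("ba and ca must be finite", "bioagemh_input_error")
  }
  if (stats::var(ca) == 0) {
    stop_bioagemh("chronological age has zero variance; regression is degenerate",
                  "bioagemh_degenerate_error")
  }
  fit <- stats::lm(ba ~ ca)
  aa_raw <- unname(stats::residuals(fit))
  sd_aa <- stats::sd(aa_raw)
  if (sd_aa < .Machine$double.eps^0.5) {
    warning("age-acceleration residuals are degenerate (SD = 0); aa_std set to NA")
    aa_std <- rep(NA_real_, length(aa_raw))
    quartile <- rep(NA_integer_, length(aa_raw))
  } else {
    aa_std <- (aa_raw - mean(aa_raw)) / sd_aa
    quartile <- quartile_cut(aa_raw)
  }
  data.frame(aa_raw = aa_raw, aa_std = aa_std, quartile = quartile)
}

#' Quartile assignment with ties to the lower quartile
#'
#' @param x numeric vector
#' @return integer vector in 1..4; `x <= Q1` maps to 1, `Q1 < x <= Q2` to 2, etc.
#' @export
quartile_cut <- function(x) {
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  as.integer(1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3]))
}
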
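#' Restricted cubic spline basis (natural spline, truncated-power form)
#'
#' Harrell's restricted cubic spline: piecewise cubic in x, constrained to be
#' linear beyond the outer knots. With k knots the basis has k - 1 columns:
#' x itself plus k - 2 nonlinear terms
#' \deqn{X_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' for j = 1..k-2. Knots default to the 5th, 50th and 95th percentiles when
#' constructed through [rcs_knots()].
#'
#' @param x numeric vector
#' @param knots strictly increasing knot locations (length >= 3)
#' @return numeric matrix with columns `x`, `x1`, ... (`length(knots) - 1`
#'   columns)
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  if (length(knots) < 3 || any(diff(knots) <= 0)) {
    stop_bioagemh("knots must be >= 3 strictly increasing values",
                  "bioagemh_input_error")
  }
  k <- length(knots)
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  out <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    col <- (pos3(x - tj) -
              pos3(x - tk1) * (tk - tj) / (tk - tk1) +
              pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
    out <- cbind(out, col)
    colnames(out)[ncol(out)] <- paste0("x", j)
  }
  out
}

#' Default dose-response knots: 5th, 50th and 95th percentiles
#'
#' @param x numeric vector
#' @return numeric vector of 3 knots
#' @export
rcs_knots <- function(x) {
  stats::quantile(x, c(0.05, 0.50, 0.95), names = FALSE)
}
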
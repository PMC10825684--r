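#' NTCP model parameters
#'
#' Container for the parameters of the logistic NTCP model
#' \deqn{NTCP(D) = \frac{1}{1 + e^{s(D_{50} - D)}},\qquad s = \frac{4\gamma}{D_{50}},}
#' where \eqn{D_{50}} is the dose-parameter value at which the complication
#' probability is 0.5 and \eqn{\gamma} is the normalized slope of the curve at
#' \eqn{D_{50}}, i.e. \eqn{\gamma = D_{50}\, dNTCP/dD} evaluated at
#' \eqn{D_{50}}.  After cohort normalization (see [normalize_cohort()]) doses
#' are dimensionless and `D50 = 1` corresponds to the cohort mean of the
#' ground-truth parameter; the constructor accepts arbitrary positive `D50`
#' for use on unnormalized scales (Gy or %).
#'
#' @param D50 positive scalar, dose-parameter value at 50% complication
#'   probability (dimensionless after normalization, otherwise in the dose
#'   parameter's own units).
#' @param gamma positive scalar, normalized slope at `D50` (dimensionless per
#'   normalized-dose unit; per Gy on an unnormalized scale).
#' @return An object of class `ntcp_params`: a list with elements `D50`,
#'   `gamma` and the derived logistic slope `s = 4 * gamma / D50`.
#' @examples
#' p <- ntcp_params(D50 = 1, gamma = 1)
#' p$s  # 4
#' @seealso [ntcp()], [slope_from_gamma()], [gamma_from_lkb_m()]
#' @export
ntcp_params <- function(D50, gamma) {
  stopifnot(is.numeric(D50), length(D50) == 1L, is.numeric(gamma),
            length(gamma) == 1L)
  if (!is.finite(D50) || D50 <= 0)
    stop("'D50' must be a finite positive scalar")
  if (!is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a finite positive scalar")
  structure(list(D50 = D50, gamma = gamma,
                 s = slope_from_gamma(gamma, D50)),
            class = "ntcp_params")
}

#' @export
print.ntcp_params <- function(x, digits = 4, ...) {
  cat("Logistic NTCP parameters\n")
  cat(sprintf("  D50   = %.*g\n  gamma = %.*g\n  s     = %.*g  (= 4*gamma/D50)\n",
              digits, x$D50, digits, x$gamma, digits, x$s))
  invisible(x)
}

#' Convert between normalized slope gamma and logistic slope s
#'
#' The logistic slope is `s = 4 * gamma / D50`; equivalently
#' `gamma = s * D50 / 4`.  `gamma` is the normalized slope of the NTCP curve
#' at its midpoint: the derivative of [ntcp()] at `D = D50` equals
#' `gamma / D50 = s / 4`.
#'
#' @param gamma positive normalized slope.
#' @param s positive logistic slope.
#' @param D50 positive midpoint dose.
#' @return The converted slope (scalar or vector, recycled elementwise).
#' @examples
#' slope_from_gamma(1, 1)        # 4
#' gamma_from_slope(4, 1)        # 1
#' @export
slope_from_gamma <- function(gamma, D50) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be positive and finite")
  if (any(!is.finite(D50)) || any(D50 <= 0))
    stop("'D50' must be positive and finite")
  4 * gamma / D50
}

#' @rdname slope_from_gamma
#' @export
gamma_from_slope <- function(s, D50) {
  if (any(!is.finite(s)) || any(s <= 0))
    stop("'s' must be positive and finite")
  if (any(!is.finite(D50)) || any(D50 <= 0))
    stop("'D50' must be positive and finite")
  s * D50 / 4
}

#' Normalized slope gamma from the LKB probit slope parameter m
#'
#' The Lyman–Kutcher–Burman (LKB) model writes the dose–response as a probit
#' curve with slope parameter `m`; its normalized slope at the midpoint is
#' \deqn{\gamma_{50} = \frac{1}{m\sqrt{2\pi}}.}
#' For example, `m = 1.21` converts to `gamma = 0.33` (two decimals).
#'
#' @param m positive LKB slope parameter.
#' @return The normalized slope `gamma`.
#' @examples
#' gamma_from_lkb_m(1.21)          # ~0.33
#' lkb_m_from_gamma(gamma_from_lkb_m(1.21))  # 1.21, round trip
#' @export
gamma_from_lkb_m <- function(m) {
  if (any(!is.finite(m)) || any(m <= 0)) stop("'m' must be positive and finite")
  1 / (m * sqrt(2 * pi))
}

#' @rdname gamma_from_lkb_m
#' @param gamma positive normalized slope.
#' @export
lkb_m_from_gamma <- function(gamma) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be positive and finite")
  1 / (gamma * sqrt(2 * pi))
}

#' Evaluate the logistic NTCP model
#'
#' Computes `1 / (1 + exp(s * (D50 - D)))` elementwise, with
#' `s = 4 * gamma / D50`.  The evaluation branches on the sign of the
#' exponent (via [stats::plogis()]) so it is numerically stable for
#' arbitrarily large `|s * (D50 - D)|` — no overflow, probabilities saturate
#' at 0 and 1.
#'
#' @param D numeric vector of dose-parameter values (same scale as
#'   `params$D50`).
#' @param params an [ntcp_params()] object.
#' @return Numeric vector of complication probabilities in `[0, 1]`,
#'   strictly increasing in `D`.
#' @examples
#' p <- ntcp_params(D50 = 1, gamma = 1)
#' ntcp(1, p)      # 0.5 (midpoint)
#' ntcp(1.25, p)   # 1 / (1 + exp(-1)) ~ 0.731
#' @export
ntcp <- function(D, params) {
  stopifnot(inherits(params, "ntcp_params"))
  if (!is.numeric(D)) stop("'D' must be numeric")
  bad <- which(!is.finite(D))
  if (length(bad))
    stop(sprintf("non-finite dose value(s) at index %s",
                 paste(head(bad, 5L), collapse = ", ")))
  # logistic in D: NTCP = plogis(s * (D - D50)), stable for both tails
  plogis(params$s * (D - params$D50))
}
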
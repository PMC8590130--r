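#' Recode clock time into cosinor rhythm regressors
#'
#' The single-component cosinor model
#' \deqn{Y(t) = M + A \cos(2\pi t/\tau + \phi) + e(t)}
#' is nonlinear in the amplitude \eqn{A} and acrophase \eqn{\phi}, but becomes
#' linear after recoding time into the pair of regressors
#' \eqn{x = \cos(2\pi t/\tau)} and \eqn{z = \sin(2\pi t/\tau)}:
#' \deqn{Y(t) = M + \beta x_t + \gamma z_t + e(t).}
#' This function performs that recoding. It is periodic, so times outside
#' \eqn{[0, \tau)} are allowed.
#'
#' @param t numeric vector of times in hours.
#' @param period rhythm period \eqn{\tau} in hours (default 24, circadian).
#' @return a data.frame with columns `x` and `z`; every row satisfies
#'   \eqn{x^2 + z^2 = 1}.
#' @examples
#' recode_time(c(0, 6, 12, 18), period = 24)
#' @export
recode_time <- function(t, period = 24) {
  check_period(period)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  ang <- 2 * pi * t / period
  data.frame(x = cos(ang), z = sin(ang))
}

check_period <- function(period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("`period` must be a single positive number (hours)", call. = FALSE)
  invisible(period)
}

#' Convert linear cosinor coefficients to rhythm parameters
#'
#' Inverts the linearization: given the fitted coefficients
#' \eqn{(M, \beta, \gamma)} of \eqn{Y = M + \beta x + \gamma z}, recovers
#' \itemize{
#'   \item amplitude \eqn{A = \sqrt{\beta^2 + \gamma^2}},
#'   \item acrophase \eqn{\phi}, the unique angle in \eqn{(-2\pi, 0]} with
#'     \eqn{\beta = A\cos\phi} and \eqn{\gamma = -A\sin\phi},
#'   \item peak time \eqn{-\phi\tau/(2\pi) \bmod \tau}, the clock time at
#'     which the fitted curve attains its maximum \eqn{M + A}.
#' }
#' The acrophase range \eqn{(-2\pi, 0]} follows the standard cosinor-literature
#' convention so that peak time is nonnegative. When \eqn{A = 0} the acrophase
#' is undefined; it is set to 0 and flagged in the `degenerate` column.
#'
#' @param mesor,beta,gamma numeric vectors (recycled) of linear coefficients.
#' @param period rhythm period in hours.
#' @return a data.frame with columns `mesor`, `amplitude`, `acrophase`
#'   (radians in \eqn{(-2\pi, 0]}), `peak_time` (hours in \eqn{[0, period)})
#'   and logical `degenerate`.
#' @examples
#' linear_to_cosinor(mesor = 2, beta = 3, gamma = 4)   # A = 5
#' @export
linear_to_cosinor <- function(mesor, beta, gamma, period = 24) {
  check_period(period)
  n <- max(length(mesor), length(beta), length(gamma))
  mesor <- rep_len(mesor, n); beta <- rep_len(beta, n); gamma <- rep_len(gamma, n)
  if (anyNA(c(mesor, beta, gamma)) || any(!is.finite(c(mesor, beta, gamma))))
    stop("linear coefficients must be finite", call. = FALSE)
  amplitude <- sqrt(beta^2 + gamma^2)
  degenerate <- amplitude == 0
  phi <- atan2(-gamma, beta)        # in (-pi, pi]
  phi <- ifelse(phi > 0, phi - 2 * pi, phi)  # map to (-2*pi, 0]
  phi[degenerate] <- 0
  peak_time <- (-phi * period / (2 * pi)) %% period
  data.frame(mesor = mesor, amplitude = amplitude, acrophase = phi,
             peak_time = peak_time, degenerate = degenerate)
}

#' Convert rhythm parameters to linear cosinor coefficients
#'
#' Exact inverse of [linear_to_cosinor()]: maps \eqn{(M, A, \phi)} to
#' \eqn{\beta = A\cos\phi}, \eqn{\gamma = -A\sin\phi}. Used by the data
#' simulator to generate responses on the linear scale.
#'
#' @param mesor,amplitude,acrophase numeric vectors (recycled); `amplitude`
#'   must be nonnegative, `acrophase` in radians (any branch).
#' @return a data.frame with columns `mesor`, `beta`, `gamma`.
#' @examples
#' cosinor_to_linear(mesor = 5, amplitude = 1, acrophase = -pi / 2)
#' @export
cosinor_to_linear <- function(mesor, amplitude, acrophase) {
  n <- max(length(mesor), length(amplitude), length(acrophase))
  mesor <- rep_len(mesor, n); amplitude <- rep_len(amplitude, n)
  acrophase <- rep_len(acrophase, n)
  if (any(amplitude < 0)) stop("`amplitude` must be >= 0", call. = FALSE)
  data.frame(mesor = mesor,
             beta = amplitude * cos(acrophase),
             gamma = -amplitude * sin(acrophase))
}

#' Minimal circular difference between two acrophases
#'
#' Acrophase is an angle, so raw differences can land on any branch of
#' \eqn{2\pi}. This returns the representative of \eqn{\phi_1 - \phi_2}
#' (mod \eqn{2\pi}) lying in \eqn{(-\pi, \pi]}, i.e. the signed minimal
#' circular distance. The boundary case of an exact half-cycle difference
#' maps to \eqn{+\pi}.
#'
#' @param phi1,phi2 numeric vectors of angles in radians (recycled).
#' @return numeric vector of wrapped differences in \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_phase_difference(-0.1, -6.1)  # ~ -0.283, not 6.0
#' @export
wrap_phase_difference <- function(phi1, phi2) {
  if (anyNA(c(phi1, phi2)) || any(!is.finite(c(phi1, phi2))))
    stop("phases must be finite", call. = FALSE)
  d <- (phi1 - phi2) %% (2 * pi)  # in [0, 2*pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Wrap a time-of-day difference to the shortest half-period branch
#'
#' Peak-time differences are circular with period \eqn{\tau}; this maps a
#' difference in hours into \eqn{(-\tau/2, \tau/2]}.
#'
#' @param dt numeric vector of time differences in hours.
#' @param period rhythm period in hours.
#' @return wrapped differences in hours.
#' @export
wrap_time_difference <- function(dt, period = 24) {
  check_period(period)
  d <- dt %% period
  ifelse(d > period / 2, d - period, d)
}

#' @rdname wrap_phase_difference
#' @param phi numeric vector of acrophases in radians.
#' @param period rhythm period in hours.
#' @details `acrophase_to_peak_time()` converts an acrophase to the clock
#'   time of the fitted peak, \eqn{-\phi\tau/(2\pi) \bmod \tau}.
#' @export
acrophase_to_peak_time <- function(phi, period = 24) {
  check_period(period)
  (-phi * period / (2 * pi)) %% period
}
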
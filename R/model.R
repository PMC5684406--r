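#' Feedback coupling parameters
#'
#' Bundles the parameters of the time-delayed system--bath interaction: the
#' coupling rate `gamma0`, the feedback loop delay `tau`, the feedback phase
#' `phi` (twice the single-arm phase `phi0`), and an optional detuning
#' `delta0`. The site transition rate `omega0` is informational only: the
#' dynamics is written in the frame rotating at the site frequency, which
#' absorbs it.
#'
#' @param gamma0 Coupling rate, >= 0. In fs^-1 unless `gamma0_unit = "cm-1"`,
#'   in which case it is converted with [wavenumber_to_rate()].
#' @param tau Feedback delay in fs, >= 0.
#' @param phi Feedback phase in radians; stored reduced to `[0, 2*pi)`.
#' @param delta0 Detuning rate in fs^-1 (default 0, the undetuned case).
#' @param omega0 Site transition rate in fs^-1 (informational).
#' @param gamma0_unit Unit of `gamma0`: `"fs-1"` (default) or `"cm-1"`.
#' @param convention Wavenumber conversion convention, see
#'   [wavenumber_to_rate()].
#' @return Object of class `"feedback_coupling"`: a list with elements
#'   `gamma0`, `tau`, `phi`, `delta0`, `omega0` (all in fs / fs^-1 / rad).
#' @examples
#' feedback_coupling(gamma0 = 530, tau = 50, phi = pi, gamma0_unit = "cm-1")
#' @export
feedback_coupling <- function(gamma0, tau, phi = 0, delta0 = 0, omega0 = 0,
                              gamma0_unit = c("fs-1", "cm-1"),
                              convention = c("angular", "linear")) {
  gamma0_unit <- match.arg(gamma0_unit)
  convention <- match.arg(convention)
  for (nm in c("gamma0", "tau", "phi", "delta0", "omega0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(nm, " must be a finite numeric scalar", call. = FALSE)
    }
  }
  if (gamma0_unit == "cm-1") gamma0 <- wavenumber_to_rate(gamma0, convention)
  if (gamma0 < 0) stop("gamma0 must be non-negative", call. = FALSE)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  structure(
    list(gamma0 = gamma0, tau = tau, phi = phi %% (2 * pi),
         delta0 = delta0, omega0 = omega0),
    class = "feedback_coupling"
  )
}

#' @export
print.feedback_coupling <- function(x, ...) {
  cat("Feedback coupling (two-point bath coupling with delay)\n")
  cat(sprintf("  gamma0 = %.6g fs^-1  (%.6g cm^-1)\n",
              x$gamma0, rate_to_wavenumber(x$gamma0)))
  cat(sprintf("  tau    = %.6g fs\n", x$tau))
  cat(sprintf("  phi    = %.6g rad (= %.6g pi)\n", x$phi, x$phi / pi))
  cat(sprintf("  delta0 = %.6g fs^-1\n", x$delta0))
  invisible(x)
}

as_feedback_coupling <- function(x) {
  if (!inherits(x, "feedback_coupling")) {
    stop("expected a 'feedback_coupling' object; see feedback_coupling()",
         call. = FALSE)
  }
  x
}

#' Feedback bath spectral density
#'
#' The continuum spectral density of a bath coupled to the system at two
#' spatial points separated by travel time `tau`:
#' `J(omega) = (gamma0 / pi) * (1 + cos(omega * tau + phi))`, defined for
#' `omega > 0`. It oscillates between 0 and `2 * gamma0 / pi` with period
#' `2 * pi / tau`.
#'
#' @param omega Positive rates in fs^-1.
#' @param coupling A [feedback_coupling()].
#' @return Non-negative densities, same length as `omega`.
#' @export
spectral_density <- function(omega, coupling) {
  coupling <- as_feedback_coupling(coupling)
  if (!is.numeric(omega) || any(!is.finite(omega))) {
    stop("omega must be finite numeric", call. = FALSE)
  }
  if (any(omega <= 0)) {
    stop("the feedback spectral density is defined for omega > 0",
         call. = FALSE)
  }
  feedback_density(omega, coupling)
}

# Analytic continuation of the spectral density formula to any omega.
# Used internally by the Fourier-pair machinery; the user-facing
# spectral_density() enforces omega > 0.
feedback_density <- function(omega, coupling) {
  (coupling$gamma0 / pi) * (1 + cos(omega * coupling$tau + coupling$phi))
}

#' Discrete system--bath coupling coefficient
#'
#' Coupling of the two-level system to the discrete bath mode `xi` before the
#' continuum limit: `sqrt(2 * gamma0 / M) * cos(sign(xi) * (omega_xi * tau / 2
#' + phi0))`, where `M` is the quantization time interval. Modes come in
#' signed pairs per frequency; binning `|kappa_xi|^2` over a dense mode grid
#' converges to [spectral_density()].
#'
#' @param xi Signed mode index (only its sign enters).
#' @param omega_xi Mode frequency in fs^-1.
#' @param M Quantization time interval in fs, > 0.
#' @param coupling A [feedback_coupling()].
#' @param phi0 Single-arm phase in rad; defaults to `coupling$phi / 2`.
#' @return Coupling amplitudes (units fs^-1/2), vectorized over `xi` and
#'   `omega_xi`.
#' @export
coupling_coefficient <- function(xi, omega_xi, M, coupling,
                                 phi0 = coupling$phi / 2) {
  coupling <- as_feedback_coupling(coupling)
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0) {
    stop("M must be a positive time interval", call. = FALSE)
  }
  sqrt(2 * coupling$gamma0 / M) *
    cos(sign(xi) * (omega_xi * coupling$tau / 2 + phi0))
}

#' Dissipation kernel weights
#'
#' The dissipation kernel of the feedback bath is a three-delta comb in the
#' time difference `t - t'`:
#' `f(t - t') = gamma0 * (e^{i phi} delta(t - tau - t') + 2 delta(t - t') +
#' e^{-i phi} delta(t + tau - t'))`,
#' the inverse Fourier transform of the spectral density. The returned table
#' lists each delta's lag and complex weight and flags the causal entries
#' (lag >= 0), which are the ones that survive in the memory integral from 0
#' to `t` and generate the delay differential equation.
#'
#' The equation of motion as solved carries `e^{-i phi}` on the retarded
#' (lag `+tau`) term; `conjugate = TRUE` returns that convention (phases on
#' the `+tau`/`-tau` entries swapped). The default is the kernel that is the
#' exact Fourier pair of [spectral_density()].
#'
#' @param coupling A [feedback_coupling()].
#' @param conjugate If `TRUE`, swap the phases of the retarded and advanced
#'   entries to match the convention of the solved equation of motion.
#' @return A `data.frame` of class `"kernel_weights"` with columns `lag`
#'   (fs), `weight` (complex, fs^-1) and `causal` (logical), ordered by
#'   decreasing lag; the coupling is attached as attribute `"coupling"`.
#' @export
kernel_weights <- function(coupling, conjugate = FALSE) {
  coupling <- as_feedback_coupling(coupling)
  g <- coupling$gamma0
  ph <- if (conjugate) -coupling$phi else coupling$phi
  out <- data.frame(
    lag = c(coupling$tau, 0, -coupling$tau),
    weight = c(g * exp(1i * ph), 2 * g + 0i, g * exp(-1i * ph)),
    causal = c(TRUE, TRUE, FALSE)
  )
  # tau = 0 collapses the comb; keep three rows for a stable contract
  attr(out, "coupling") <- coupling
  attr(out, "conjugate") <- conjugate
  class(out) <- c("kernel_weights", "data.frame")
  out
}

#' Sampled spectral density curve
#'
#' Evaluates [spectral_density()] on a frequency grid, as a serializable
#' two-column table.
#'
#' @param coupling A [feedback_coupling()].
#' @param omega_max Upper end of the grid in fs^-1.
#' @param n Number of grid points (>= 2).
#' @param omega_min Lower end, > 0; defaults to `omega_max / n`.
#' @return `data.frame` with columns `omega` (fs^-1) and `J` (density).
#' @export
spectral_density_curve <- function(coupling, omega_max, n = 1000L,
                                   omega_min = omega_max / n) {
  coupling <- as_feedback_coupling(coupling)
  if (omega_min <= 0 || omega_max <= omega_min) {
    stop("need 0 < omega_min < omega_max", call. = FALSE)
  }
  omega <- seq(omega_min, omega_max, length.out = n)
  data.frame(omega = omega, J = spectral_density(omega, coupling))
}

#' Write / read a spectral density curve
#'
#' Two-column delimited table (`omega,J`) with a one-line header.
#'
#' @param curve A `data.frame` with columns `omega` and `J`.
#' @param path File path.
#' @return `write_spectral_density()` returns `path` invisibly;
#'   `read_spectral_density()` returns the curve `data.frame`.
#' @export
write_spectral_density <- function(curve, path) {
  stopifnot(all(c("omega", "J") %in% names(curve)))
  utils::write.csv(curve[, c("omega", "J")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_density
#' @export
read_spectral_density <- function(path) {
  curve <- utils::read.csv(path)
  if (!all(c("omega", "J") %in% names(curve))) {
    stop("spectral density table must have columns 'omega' and 'J'",
         call. = FALSE)
  }
  if (any(curve$J < 0)) stop("spectral density must be non-negative",
                             call. = FALSE)
  curve
}
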
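# Coefficients of the scalar equation of motion in the rotating frame:
#   dc/dt = -(i delta0 + gamma0) c(t) - theta(t - tau) gamma0 e^{-i phi} c(t - tau)
dde_coeff_a <- function(coupling) 1i * coupling$delta0 + coupling$gamma0
dde_coeff_b <- function(coupling) coupling$gamma0 * exp(-1i * coupling$phi)

# Pick the uniform step: h must divide tau so the propagated derivative
# discontinuities at multiples of tau fall on grid nodes.
resolve_step <- function(coupling, t_max, dt) {
  tau <- coupling$tau
  if (is.null(dt)) dt <- if (tau > 0) min(tau / 200, 0.5) else min(t_max / 2000, 0.5)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (tau > 0) {
    if (dt > tau / 2) {
      stop("dt = ", dt, " fs under-resolves the delay tau = ", tau,
           " fs (need dt <= tau/2, ideally <= tau/10)", call. = FALSE)
    }
    h <- tau / ceiling(tau / dt)
  } else {
    h <- dt
  }
  list(h = h, n = as.integer(ceiling(t_max / h - 1e-9)))
}

solve_linear_dde <- function(A, B, coupling, c_init, t_max, dt, tol, mode) {
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be positive", call. = FALSE)
  c_init <- as.complex(c_init)
  if (any(!is.finite(Re(c_init)) | !is.finite(Im(c_init)))) {
    stop("c_init must be finite", call. = FALSE)
  }
  tau <- coupling$tau
  run <- function(dt_req) {
    st <- resolve_step(coupling, t_max, dt_req)
    if (tau == 0) {
      vals <- cpp_solve_linear_dde(A + B, 0 * B, 0, st$h, st$n, c_init)
    } else {
      vals <- cpp_solve_linear_dde(A, B, tau, st$h, st$n, c_init)
    }
    list(h = st$h, n = st$n, vals = vals)
  }
  r <- run(dt)
  if (!is.null(tol)) {
    # step-halving error control: refine until the solution at shared nodes
    # is reproduced to within tol
    for (i in 1:4) {
      r2 <- run(r$h / 2)
      shared <- seq(1, nrow(r2$vals), by = 2)
      err <- max(abs(r2$vals[shared, , drop = FALSE] - r$vals))
      r <- r2
      if (err <= tol) break
    }
  }
  amplitude_trajectory(
    times = r$h * (0:r$n),
    amplitudes = r$vals,
    coupling = coupling,
    mode = mode,
    solver = list(dt = r$h, method = "rk4-method-of-steps", t_max = t_max)
  )
}

#' Solve the scalar delayed amplitude equation
#'
#' Integrates the delay differential equation for the excitation amplitude
#' of the effective two-level system,
#' `dc/dt = -i delta0 c - gamma0 c - theta(t - tau) gamma0 e^{-i phi} c(t - tau)`,
#' by classical 4th-order Runge-Kutta with the method of steps. No
#' pre-history is needed (or accepted): the Heaviside factor nullifies the
#' delayed term before `t = tau`, so the initial amplitude at `t = 0` fully
#' determines the solution. The step is chosen to divide `tau` exactly so the
#' derivative discontinuities propagated from `t = tau` land on grid nodes;
#' delayed values at stage midpoints come from cubic Hermite interpolation of
#' the stored past.
#'
#' @param coupling A [feedback_coupling()].
#' @param c_init Complex initial amplitude at `t = 0` (default 1).
#' @param t_max Final time in fs, > 0.
#' @param dt Requested step in fs; defaults to `min(tau/200, 0.5)` fs.
#'   Refused if larger than `tau/2`.
#' @param tol Optional step-halving error target; if given, the step is
#'   halved (up to 4 times) until the solution is reproduced to within `tol`.
#' @return An [amplitude_trajectory()] with one component.
#' @examples
#' fc <- feedback_coupling(530, tau = 50, phi = pi, gamma0_unit = "cm-1")
#' traj <- solve_amplitude(fc, t_max = 2000)
#' abs(traj$amplitudes[nrow(traj$amplitudes), 1])  # trapping plateau
#' @export
solve_amplitude <- function(coupling, c_init = 1 + 0i, t_max, dt = NULL,
                            tol = NULL) {
  coupling <- as_feedback_coupling(coupling)
  if (length(c_init) != 1L) stop("scalar mode takes a single c_init", call. = FALSE)
  a <- dde_coeff_a(coupling)
  b <- dde_coeff_b(coupling)
  solve_linear_dde(matrix(-a), matrix(-b), coupling, c_init, t_max, dt, tol,
                   mode = "scalar")
}

#' Solve the cross-delayed dimer pair
#'
#' Propagates two site amplitudes whose delayed feedback is crossed:
#' `dc1/dt = -(i delta0 + gamma0) c1 - theta(t - tau) gamma0 e^{-i phi} c2(t - tau)`
#' and symmetrically for `c2`. The symmetric and antisymmetric combinations
#' `c1 +/- c2` each obey the scalar equation of [solve_amplitude()] with the
#' sign of the delayed term flipped between them (phases `phi` and
#' `phi + pi`), which is this mode's internal consistency check. This is an
#' interpretive donor/acceptor decomposition of the effective two-level
#' amplitude, flagged as such in the trajectory metadata; the scalar mode is
#' the primary model.
#'
#' @inheritParams solve_amplitude
#' @param c_init Complex 2-vector of initial site amplitudes
#'   (default `c(1, 0)`: donor excited).
#' @return An [amplitude_trajectory()] with two components.
#' @export
solve_dimer <- function(coupling, c_init = c(1 + 0i, 0 + 0i), t_max,
                        dt = NULL, tol = NULL) {
  coupling <- as_feedback_coupling(coupling)
  if (length(c_init) != 2L) stop("dimer mode takes a length-2 c_init", call. = FALSE)
  a <- dde_coeff_a(coupling)
  b <- dde_coeff_b(coupling)
  A <- diag(c(-a, -a))
  B <- matrix(c(0, -b, -b, 0), 2, 2)
  solve_linear_dde(A, B, coupling, c_init, t_max, dt, tol, mode = "dimer")
}

#' Exact piecewise closed form of the delayed amplitude equation
#'
#' Evaluates the method-of-steps closed form of the scalar delay equation:
#' with `a = i delta0 + gamma0` and `b = gamma0 e^{-i phi}`, on the n-th
#' delay interval the solution is the truncated series
#' `c(t) = sum_{n=0}^{floor(t/tau)} (-b)^n e^{-a (t - n tau)} (t - n tau)^n / n!`,
#' an exponential times a polynomial of degree n built by recursive
#' integration of the delayed term. Each term is bounded by a Poisson weight,
#' so the sum is numerically benign. Serves as the independent oracle for
#' [solve_amplitude()].
#'
#' @param coupling A [feedback_coupling()].
#' @param t Times in fs (vectorized), >= 0.
#' @param n_max Maximum number of delay intervals allowed; evaluation refuses
#'   times beyond `n_max * tau`. Default covers the requested times.
#' @param c_init Complex initial amplitude (default 1); the solution is
#'   linear in it.
#' @return Complex amplitudes, same length as `t`.
#' @export
amplitude_closed_form <- function(coupling, t, n_max = NULL, c_init = 1 + 0i) {
  coupling <- as_feedback_coupling(coupling)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  a <- dde_coeff_a(coupling)
  b <- dde_coeff_b(coupling)
  tau <- coupling$tau
  if (tau == 0) return(c_init * exp(-(a + b) * t))
  n_int <- floor(t / tau + 1e-12)
  if (!is.null(n_max) && any(n_int > n_max)) {
    stop("requested t reaches interval ", max(n_int),
         " but n_max = ", n_max, call. = FALSE)
  }
  vapply(seq_along(t), function(i) {
    ti <- t[i]
    total <- 0 + 0i
    for (n in 0:n_int[i]) {
      s <- ti - n * tau
      if (n == 0) {
        term <- exp(-a * s)
      } else if (s <= 0 || b == 0) {
        term <- 0 + 0i
      } else {
        # log-space product keeps (-b s)^n / n! overflow-free
        term <- exp(-a * s + n * log(-b * s) - lgamma(n + 1))
      }
      total <- total + term
    }
    total
  }, complex(1)) * c_init
}
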
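observable_series <- function(times, values, label) {
  out <- data.frame(t = times, value = values)
  attr(out, "label") <- label
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Site population
#'
#' The diagonal density-matrix element of a site: `|c_site(t)|^2`.
#'
#' @param traj An [amplitude_trajectory()].
#' @param site Component index (default 1).
#' @return An `observable_series` data frame with columns `t`, `value`.
#' @export
population <- function(traj, site = 1L) {
  if (site < 1 || site > n_components(traj)) {
    stop("site ", site, " does not exist in this trajectory", call. = FALSE)
  }
  observable_series(traj$times, abs(traj$amplitudes[, site])^2,
                    label = paste0("population_site", site))
}

#' Inter-site coherence
#'
#' The modulus of the off-diagonal density-matrix element in the site basis,
#' `|c1(t)* c2(t)|`. Bounded by 1/2 when the total population is at most 1.
#'
#' @param traj An [amplitude_trajectory()] with exactly two components.
#' @return An `observable_series` data frame.
#' @export
coherence <- function(traj) {
  if (n_components(traj) != 2L) {
    stop("coherence needs a two-component trajectory; use solve_dimer() ",
         "for the donor/acceptor mode", call. = FALSE)
  }
  observable_series(
    traj$times,
    abs(Conj(traj$amplitudes[, 1]) * traj$amplitudes[, 2]),
    label = "coherence"
  )
}

#' Coherence rate series
#'
#' Central-difference time derivative of the coherence envelope. Its sign is
#' an interpretive diagnostic: positive stretches mark net flow of amplitude
#' correlation into the site pair, negative stretches mark flow back out.
#'
#' @param traj An [amplitude_trajectory()] with two components.
#' @return An `observable_series` data frame (label
#'   `"coherence_rate (interpretation)"`).
#' @export
coherence_rate <- function(traj) {
  coh <- coherence(traj)
  n <- nrow(coh)
  dv <- c(diff(coh$value[1:2]) / diff(coh$t[1:2]),
          (coh$value[-(1:2)] - coh$value[1:(n - 2)]) /
            (coh$t[-(1:2)] - coh$t[1:(n - 2)]),
          diff(coh$value[(n - 1):n]) / diff(coh$t[(n - 1):n]))
  observable_series(coh$t, dv, label = "coherence_rate (interpretation)")
}

#' Long-time amplitude limit
#'
#' The analytic steady-state modulus of the scalar delayed amplitude
#' equation in the undetuned case: the excitation is trapped at
#' `1 / (1 + gamma0 * tau)` under exact destructive interference
#' (`e^{i phi} = -1`) and decays to zero for every other phase.
#'
#' @param coupling A [feedback_coupling()] with `delta0 = 0` (the limit is
#'   only established for the undetuned case).
#' @param tol Tolerance on `|1 + e^{i phi}|` for detecting destructive
#'   interference (default 1e-12).
#' @return Non-negative scalar.
#' @examples
#' steady_state_amplitude(feedback_coupling(0.02, tau = 50, phi = pi))  # 0.5
#' @export
steady_state_amplitude <- function(coupling, tol = 1e-12) {
  coupling <- as_feedback_coupling(coupling)
  if (coupling$delta0 != 0) {
    stop("the steady-state limit is only established for delta0 = 0",
         call. = FALSE)
  }
  if (Mod(1 + exp(1i * coupling$phi)) < tol) {
    1 / (1 + coupling$gamma0 * coupling$tau)
  } else {
    0
  }
}

# Local maxima with a tie tolerance: plateaus (runs of values equal within
# tol) count once, at their center.
local_maxima <- function(v, tol = 1e-12) {
  n <- length(v)
  if (n < 3) return(integer(0))
  run_id <- cumsum(c(TRUE, abs(diff(v)) > tol))
  starts <- which(!duplicated(run_id))
  ends <- c(starts[-1] - 1L, n)
  vals <- v[starts]
  m <- length(starts)
  if (m < 3) return(integer(0))
  interior <- 2:(m - 1)
  is_max <- vals[interior] > vals[interior - 1] + tol &
    vals[interior] > vals[interior + 1] + tol
  idx <- interior[is_max]
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

#' Quantum-beating metrics of an observable series
#'
#' Detects the population/coherence beats produced by the delayed feedback:
#' the dominant period is the mean spacing of local maxima, the envelope
#' decay rate a log-linear fit to the maxima, and the oscillation count the
#' number of maxima above a floor. A monotone or plateaued series yields a
#' "no beating" marker rather than an error.
#'
#' @param series An `observable_series` (or any data frame with `t` and
#'   `value`).
#' @param floor Maxima below this value are not counted (default 1e-4).
#' @param tol Tie tolerance for extremum detection (default 1e-12).
#' @return A list with elements `beating` (logical), `period` (fs),
#'   `envelope_rate` (fs^-1, positive = decay), `n_oscillations`.
#' @export
beating_metrics <- function(series, floor = 1e-4, tol = 1e-12) {
  v <- series$value
  tt <- series$t
  imax <- local_maxima(v, tol)
  imin <- local_maxima(-v, tol)
  no_beating <- list(beating = FALSE, period = NA_real_,
                     envelope_rate = NA_real_, n_oscillations = 0L)
  if (length(imax) + length(imin) < 3 || length(imax) < 2) return(no_beating)
  counted <- imax[v[imax] > floor]
  period <- mean(diff(tt[imax]))
  env_rate <- NA_real_
  if (length(counted) >= 2 && all(v[counted] > 0)) {
    env_rate <- -unname(stats::coef(
      stats::lm(log(v[counted]) ~ tt[counted]))[2])
  }
  list(beating = TRUE, period = period, envelope_rate = env_rate,
       n_oscillations = length(counted))
}

#' Write an observable series as CSV with a JSON sidecar
#'
#' @param series An `observable_series`.
#' @param path CSV path; the sidecar goes to `<path>.meta.json`.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, extra = list()) {
  utils::write.csv(as.data.frame(series)[, c("t", "value")], path,
                   row.names = FALSE)
  jsonlite::write_json(c(list(label = attr(series, "label")), extra),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
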
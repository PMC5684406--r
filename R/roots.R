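#' Complex Lambert-W function, arbitrary branch
#'
#' Solves `w * exp(w) = z` on branch `k` by Halley iteration from standard
#' series / asymptotic starting points (Taylor series near 0 on the principal
#' branch, the branch-point expansion near `-1/e` for branches 0 and -1, and
#' `log(z) + 2 pi i k - log(log(z) + 2 pi i k)` otherwise).
#'
#' @param z Complex (or numeric) scalar or vector.
#' @param k Integer branch index (default 0, the principal branch).
#' @param tol Convergence tolerance on the residual `|w e^w - z|` relative to
#'   `|z| + 1`.
#' @return Complex values, same length as `z`. `NA` where the iteration does
#'   not converge.
#' @export
lambert_w <- function(z, k = 0L, tol = 1e-15) {
  z <- as.complex(z)
  vapply(z, lambert_w1, complex(1), k = as.integer(k), tol = tol)
}

lambert_w1 <- function(z, k, tol) {
  if (z == 0) {
    if (k == 0L) return(0 + 0i)
    return(NA_complex_)  # all other branches diverge at 0
  }
  # starting point
  if (k == 0L && Mod(z) < 0.3) {
    w <- z * (1 - z + 1.5 * z^2)
  } else if ((k == 0L || k == -1L) && Mod(z + exp(-1)) < 0.25) {
    p <- sqrt(2 * (exp(1) * z + 1))
    if (k == -1L) p <- -p
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  } else {
    L <- log(z) + 2i * pi * k
    w <- if (Mod(L) < 1e-8) 0.5 + 0i else L - log(L)
  }
  scale <- Mod(z) + 1
  for (iter in 1:100) {
    ew <- exp(w)
    f <- w * ew - z
    if (Mod(f) <= tol * scale) return(w)
    wp1 <- w + 1
    step <- f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    w <- w - step
  }
  if (Mod(w * exp(w) - z) <= 1e-10 * scale) w else NA_complex_
}

#' Characteristic roots of the delayed amplitude equation
#'
#' The scalar delay equation has characteristic equation
#' `s + i delta0 + gamma0 + gamma0 e^{-i phi} e^{-s tau} = 0`, with an
#' infinite ladder of complex roots given in closed form by the branches of
#' the Lambert-W function:
#' `s_k = -i delta0 - gamma0 + W_k(-gamma0 tau e^{-i phi} e^{(i delta0 + gamma0) tau}) / tau`.
#' Each root is polished by a few Newton steps on the characteristic function
#' and stored with its residual. For `phi = pi` (destructive interference)
#' the principal branch yields the trapping root `s = 0`.
#'
#' @param coupling A [feedback_coupling()]; `tau` must be > 0.
#' @param branches Integer vector of Lambert-W branch indices
#'   (default `-5:5`).
#' @return A `data.frame` of class `"characteristic_root_set"` with columns
#'   `branch`, `root` (complex, fs^-1) and `residual`, sorted by descending
#'   real part, duplicates (within 1e-12) removed. Branches whose evaluation
#'   fails are kept with `NA` root.
#' @export
characteristic_roots <- function(coupling, branches = -5:5) {
  coupling <- as_feedback_coupling(coupling)
  tau <- coupling$tau
  if (tau <= 0) stop("characteristic roots require tau > 0", call. = FALSE)
  a <- dde_coeff_a(coupling)
  b <- dde_coeff_b(coupling)
  charfun <- function(s) s + a + b * exp(-s * tau)
  zeta <- -b * tau * exp(a * tau)
  roots <- vapply(branches, function(k) {
    s <- tryCatch({
      if (coupling$gamma0 == 0) {
        if (k == 0L) -a else NA_complex_
      } else {
        w <- lambert_w1(zeta, as.integer(k), tol = 1e-15)
        if (is.na(w)) NA_complex_ else (-a + w / tau)
      }
    }, error = function(e) NA_complex_)
    if (!is.na(s)) {
      for (i in 1:5) {  # Newton polish on the characteristic function
        f <- charfun(s)
        s2 <- s - f / (1 - b * tau * exp(-s * tau))
        if (!is.finite(Re(s2)) || Mod(s2 - s) < 1e-16 * (1 + Mod(s))) break
        s <- s2
      }
    }
    s
  }, complex(1))
  out <- data.frame(branch = as.integer(branches), root = roots,
                    residual = Mod(charfun(roots)))
  out <- out[order(is.na(out$root), -Re(out$root)), , drop = FALSE]
  ok <- !is.na(out$root)
  if (any(ok)) {
    keep <- rep(TRUE, nrow(out))
    idx <- which(ok)
    for (i in seq_along(idx)[-1]) {
      if (any(Mod(out$root[idx[i]] - out$root[idx[seq_len(i - 1)]]) < 1e-12)) {
        keep[idx[i]] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "coupling") <- coupling
  class(out) <- c("characteristic_root_set", "data.frame")
  out
}

#' Fit the late-time exponential decay rate of a trajectory
#'
#' Linear fit of `log |c(t)|` over the final fraction of the time grid;
#' used to compare the observed asymptotic decay with the dominant
#' characteristic root.
#'
#' @param traj An [amplitude_trajectory()] (first component used).
#' @param fraction Trailing fraction of the grid to fit (default 0.3).
#' @return The fitted rate (fs^-1): `d log|c| / dt`, negative for decay.
#' @export
fit_decay_rate <- function(traj, fraction = 0.3) {
  n <- length(traj$times)
  idx <- seq.int(ceiling(n * (1 - fraction)), n)
  amp <- abs(traj$amplitudes[idx, 1])
  if (any(amp <= 0)) stop("amplitude underflow in the fit window", call. = FALSE)
  unname(stats::coef(stats::lm(log(amp) ~ traj$times[idx]))[2])
}
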
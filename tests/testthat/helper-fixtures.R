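# Random coupling draws for property-style tests. Fixed seed, documented
# ranges: dimensionless coupling gamma0*tau in [0.1, 10], phase over the
# full circle, delays on the femtosecond scale of the physical system.
draw_couplings <- function(n, seed = 4242) {
  withr::with_seed(seed, {
    data.frame(
      tau = runif(n, 20, 80),
      gamma0_tau = runif(n, 0.1, 10),
      phi = runif(n, 0, 2 * pi)
    )
  })
}

coupling_from_draw <- function(draw, delta0 = 0) {
  feedback_coupling(gamma0 = draw$gamma0_tau / draw$tau, tau = draw$tau,
                    phi = draw$phi, delta0 = delta0)
}

# |c(t)| comparison of a solved trajectory against the closed form on a
# subsample of grid nodes
oracle_deviation <- function(traj, n_check = 200) {
  idx <- unique(round(seq(1, length(traj$times), length.out = n_check)))
  ora <- amplitude_closed_form(traj$coupling, traj$times[idx])
  max(abs(traj$amplitudes[idx, 1] - ora))
}

ref_gamma0 <- function() wavenumber_to_rate(530)  # reference coupling of the strong-coupling regime
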
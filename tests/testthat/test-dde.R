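test_that("free evolution and exact cancellation limits hold", {
  # gamma0 = 0: nothing happens
  fc <- feedback_coupling(0, tau = 10, phi = 0)
  tr <- solve_amplitude(fc, c_init = 0.6 + 0.3i, t_max = 100, dt = 1)
  expect_true(all(abs(tr$amplitudes[, 1] - (0.6 + 0.3i)) < 1e-12))
  # tau = 0, phi = pi: the instantaneous and fed-back terms cancel exactly
  fc2 <- feedback_coupling(0.3, tau = 0, phi = pi)
  tr2 <- solve_amplitude(fc2, c_init = 1 + 0i, t_max = 100, dt = 0.1)
  expect_true(all(abs(tr2$amplitudes[, 1] - 1) < 1e-12))
})

test_that("before the delay activates the decay is a pure exponential", {
  fc <- feedback_coupling(ref_gamma0(), tau = 50, phi = pi)
  tr <- solve_amplitude(fc, t_max = 49.9, dt = 0.25)
  expect_lt(max(abs(abs(tr$amplitudes[, 1]) - exp(-fc$gamma0 * tr$times))),
            1e-8)
})

test_that("solver matches the piecewise closed form on random draws", {
  draws <- draw_couplings(20)
  for (i in seq_len(nrow(draws))) {
    fc <- coupling_from_draw(draws[i, ])
    tr <- solve_amplitude(fc, t_max = 10 * fc$tau, dt = fc$tau / 200)
    expect_lt(oracle_deviation(tr), 1e-6)
  }
})

test_that("the dynamics is dissipative and linear in the initial condition", {
  draws <- draw_couplings(8, seed = 515)
  for (i in seq_len(nrow(draws))) {
    fc <- coupling_from_draw(draws[i, ])
    tr <- solve_amplitude(fc, t_max = 8 * fc$tau, dt = fc$tau / 100)
    expect_true(all(abs(tr$amplitudes[, 1]) <= 1 + 1e-9))
    z <- 0.3 - 1.2i
    trz <- solve_amplitude(fc, c_init = z, t_max = 8 * fc$tau,
                           dt = fc$tau / 100)
    expect_lt(max(abs(trz$amplitudes - z * tr$amplitudes)), 1e-12 * Mod(z))
  }
})

test_that("detuning rotates the phase without changing the modulus", {
  fc0 <- feedback_coupling(0.05, tau = 30, phi = 1.2, delta0 = 0)
  fcd <- feedback_coupling(0.05, tau = 30, phi = 1.2, delta0 = 0.07)
  t <- seq(0, 150, by = 0.5)
  c0 <- amplitude_closed_form(fc0, t)
  cd <- amplitude_closed_form(fcd, t)
  # delta0 enters the equation of motion as a global phase e^{-i delta0 t} only when
  # it also multiplies the delayed term consistently; check pre-delay segment
  pre <- t < 30
  expect_equal(cd[pre], c0[pre] * exp(-1i * 0.07 * t[pre]), tolerance = 1e-12)
  tr <- solve_amplitude(fcd, t_max = 150, dt = 0.1)
  expect_lt(oracle_deviation(tr), 1e-7)
})

test_that("step halving converges at fourth order against the closed form", {
  fc <- feedback_coupling(0.08, tau = 40, phi = 2.4)
  errs <- sapply(c(10, 20, 40), function(L) {
    tr <- solve_amplitude(fc, t_max = 5 * fc$tau, dt = fc$tau / L)
    oracle_deviation(tr, n_check = 50)
  })
  expect_gt(errs[1] / errs[2], 10)  # nominal 16 for RK4
  expect_gt(errs[2] / errs[3], 10)
})

test_that("tol argument refines the step until the target is met", {
  fc <- feedback_coupling(0.08, tau = 40, phi = 2.4)
  tr <- solve_amplitude(fc, t_max = 5 * fc$tau, dt = fc$tau / 10, tol = 1e-9)
  expect_lt(tr$solver$dt, fc$tau / 10)
  expect_lt(oracle_deviation(tr, n_check = 50), 1e-8)
})

test_that("under-resolved delays and bad parameters are refused", {
  fc <- feedback_coupling(0.1, tau = 10, phi = 0)
  expect_error(solve_amplitude(fc, t_max = 100, dt = 6), "under-resolves")
  expect_error(solve_amplitude(fc, t_max = -5), "positive")
  expect_error(solve_amplitude(fc, c_init = NaN + 0i, t_max = 10), "finite")
})

test_that("closed form: first-interval formula, continuity, interval guard", {
  fc <- feedback_coupling(0.06, tau = 35, phi = 1.7)
  expect_equal(amplitude_closed_form(fc, 0), 1 + 0i)
  # hand-integrated second interval: e^{-g t} (1 - g e^{-i phi} e^{g tau} (t - tau))
  t2 <- seq(35, 69.9, length.out = 7)
  g <- fc$gamma0
  expected <- exp(-g * t2) *
    (1 - g * exp(-1i * fc$phi) * exp(g * fc$tau) * (t2 - fc$tau))
  expect_equal(amplitude_closed_form(fc, t2), expected, tolerance = 1e-12)
  # continuity across every interval boundary
  eps <- 1e-9
  for (n in 1:6) {
    left <- amplitude_closed_form(fc, n * fc$tau - eps)
    right <- amplitude_closed_form(fc, n * fc$tau + eps)
    expect_lt(Mod(left - right), 1e-7)  # continuous, slope changes only
  }
  expect_error(amplitude_closed_form(fc, 100, n_max = 1), "n_max")
})

test_that("solver agrees with an independent general-purpose DDE integrator", {
  fc <- feedback_coupling(0.04, tau = 30, phi = 0.9)
  g0 <- fc$gamma0
  b <- g0 * exp(-1i * fc$phi)
  f <- function(t, y, parms) {
    cc <- complex(real = y[1], imaginary = y[2])
    del <- if (t > fc$tau) {
      yl <- deSolve::lagvalue(t - fc$tau)
      complex(real = yl[1], imaginary = yl[2])
    } else 0 + 0i
    d <- -g0 * cc - b * del
    list(c(Re(d), Im(d)))
  }
  out <- deSolve::dede(c(1, 0), times = seq(0, 300, by = 1), func = f,
                       parms = NULL)
  ref <- complex(real = out[, 2], imaginary = out[, 3])
  tr <- solve_amplitude(fc, t_max = 300, dt = 0.5)
  mine <- tr$amplitudes[match(seq(0, 300, by = 1), round(tr$times, 9)), 1]
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("dimer mode decomposes into the scalar normal modes", {
  fc <- feedback_coupling(0.05, tau = 40, phi = 1.3)
  dm <- solve_dimer(fc, c(1, 0), t_max = 400, dt = 0.2)
  sym <- solve_amplitude(fc, t_max = 400, dt = 0.2)
  fca <- feedback_coupling(0.05, tau = 40, phi = 1.3 + pi)
  anti <- solve_amplitude(fca, t_max = 400, dt = 0.2)
  expect_lt(max(abs(dm$amplitudes[, 1] + dm$amplitudes[, 2] -
                    sym$amplitudes[, 1])), 1e-8)
  expect_lt(max(abs(dm$amplitudes[, 1] - dm$amplitudes[, 2] -
                    anti$amplitudes[, 1])), 1e-8)
  # symmetric start keeps both sites identical
  dms <- solve_dimer(fc, c(1, 1) / sqrt(2), t_max = 200, dt = 0.2)
  expect_lt(max(abs(dms$amplitudes[, 1] - dms$amplitudes[, 2])), 1e-12)
  # before the delay the acceptor stays empty and the donor decays freely
  pre <- dm$times < 40
  expect_lt(max(abs(dm$amplitudes[pre, 2])), 1e-12)
  expect_lt(max(abs(abs(dm$amplitudes[pre, 1]) -
                    exp(-fc$gamma0 * dm$times[pre]))), 1e-8)
})

test_that("trajectories round-trip through CSV + JSON sidecar", {
  fc <- feedback_coupling(0.05, tau = 40, phi = 1.3)
  tr <- solve_dimer(fc, c(1, 0), t_max = 100, dt = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path, extra = list(seed = 7))
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times, tolerance = 1e-12)
  expect_lt(max(abs(back$amplitudes - tr$amplitudes)), 1e-12)
  expect_equal(back$mode, "dimer")
  expect_equal(back$coupling$gamma0, fc$gamma0, tolerance = 1e-12)
})
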
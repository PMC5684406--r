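test_that("build_kernel reduces to the delta comb for the feedback form", {
  fc <- feedback_coupling(0.1, tau = 25, phi = 0.8)
  sys <- feedback_site_system(fc, width = 0, conjugate = FALSE)
  k <- build_kernel(sys, 1, 1)
  expect_s3_class(k, "memory_kernel")
  kw <- kernel_weights(fc)
  expect_equal(k$lags, kw$lag)
  expect_equal(k$weights, kw$weight, tolerance = 1e-14)
  expect_null(build_kernel(site_system(c(0, 0)), 1, 2))
  expect_error(build_kernel(sys, 1, 5), "out of range")
})

test_that("a flat spectral density gives a memoryless kernel", {
  # J = gamma/pi constant with a wide cutoff: the transform concentrates at
  # zero time difference with integrated weight 2*gamma
  gam <- 0.05
  cutoff <- 40
  curve <- data.frame(omega = seq(-cutoff, cutoff, length.out = 20001),
                      J = gam / pi)
  k <- density_memory_kernel(curve)
  h <- 0.005
  dts <- seq(0, 3, by = h)
  f <- kernel_smooth_part(k, dts)
  # two-sided mass (even in dt) equals 2*gamma
  mass <- 2 * sum(f * h) - f[1] * h
  expect_equal(Re(mass), 2 * gam, tolerance = 1e-2)
  # concentration: the sinc tail is down by >= the cutoff ratio at dt = 1
  expect_lt(max(Mod(f[dts > 1])), Mod(f[1]) / 30)
})

test_that("zero site frequencies make the kernel stationary", {
  fc <- feedback_coupling(0.1, tau = 25, phi = 0.8)
  sys <- feedback_site_system(fc, width = 2)
  k <- build_kernel(sys, 1, 1)
  ev <- attr(k, "evaluate")
  expect_equal(ev(30, 5), ev(40, 15), tolerance = 1e-13)   # t - t' = 25
  expect_equal(ev(7.5, 7.5), ev(100, 100), tolerance = 1e-13)
})

test_that("zero kernel and zero coupling freeze the amplitudes", {
  sys <- site_system(c(0, 0))
  tr <- solve_volterra(sys, c(0.8 + 0.1i, 0.2 - 0.4i), t_max = 50, dt = 0.5)
  expect_lt(max(abs(sweep(tr$amplitudes, 2, tr$amplitudes[1, ], "-"))), 1e-12)
})

test_that("a memoryless (flat-bath) kernel reproduces Markovian decay", {
  gam <- 0.01
  sys <- site_system(0, kernels = delta_memory_kernel(0, 2 * gam, width = 0))
  tr <- solve_volterra(sys, 1 + 0i, t_max = 200, dt = 0.05)
  expect_lt(max(abs(abs(tr$amplitudes[, 1]) - exp(-gam * tr$times))), 1e-4)
})

test_that("halving dt reduces the Markovian stepping error about 4-fold", {
  gam <- 0.02
  errs <- sapply(c(0.4, 0.2, 0.1), function(dt) {
    sys <- site_system(0, kernels = delta_memory_kernel(0, 2 * gam, width = 0))
    tr <- solve_volterra(sys, 1 + 0i, t_max = 100, dt = dt)
    max(abs(abs(tr$amplitudes[, 1]) - exp(-gam * tr$times)))
  })
  expect_gt(errs[1] / errs[2], 3.5)
  expect_gt(errs[2] / errs[3], 3.5)
})

test_that("exact-delta feedback kernel reproduces the DDE solution", {
  fc <- feedback_coupling(0.02, tau = 20, phi = 2.6)
  sys <- feedback_site_system(fc, width = 0)
  # the predictor-corrector loses an order at the delay-activation kink, so
  # the step must be finer than the RK4 method-of-steps needs
  tr <- solve_volterra(sys, 1 + 0i, t_max = 100, dt = 0.005)
  dde <- solve_amplitude(fc, t_max = 100, dt = 0.05)
  idx <- match(round(dde$times, 9), round(tr$times, 9))
  expect_lt(max(abs(tr$amplitudes[idx, 1] - dde$amplitudes[, 1])), 1e-4)
})

test_that("halving the regularization width halves the DDE deviation", {
  fc <- feedback_coupling(0.002, tau = 50, phi = 2.2)
  dt <- 50 / 1280
  dde <- solve_amplitude(fc, t_max = 150, dt = dt)
  devs <- sapply(50 / c(32, 64, 128), function(w) {
    v <- solve_volterra(feedback_site_system(fc, width = w), 1 + 0i,
                        t_max = 150, dt = dt)
    max(abs(v$amplitudes - dde$amplitudes))
  })
  expect_gt(devs[1] / devs[2], 1.9)
  expect_gt(devs[2] / devs[3], 1.9)
})

test_that("two-site symmetric cross kernels do not mix the normal modes", {
  fc <- feedback_coupling(0.03, tau = 20, phi = 1.1)
  kw <- kernel_weights(fc, conjugate = TRUE)
  cross <- delta_memory_kernel(kw$lag, kw$weight, width = 0)
  sys2 <- site_system(c(0, 0), kernels = list(
    list(j = 1L, l = 2L, kernel = cross),
    list(j = 2L, l = 1L, kernel = cross)
  ))
  tr2 <- solve_volterra(sys2, c(1 + 0i, 0 + 0i), t_max = 100, dt = 0.1)
  plus <- tr2$amplitudes[, 1] + tr2$amplitudes[, 2]
  minus <- tr2$amplitudes[, 1] - tr2$amplitudes[, 2]
  sysp <- site_system(0, kernels = delta_memory_kernel(kw$lag, kw$weight,
                                                       width = 0))
  sysm <- site_system(0, kernels = delta_memory_kernel(kw$lag, -kw$weight,
                                                       width = 0))
  trp <- solve_volterra(sysp, 1 + 0i, t_max = 100, dt = 0.1)
  trm <- solve_volterra(sysm, 1 + 0i, t_max = 100, dt = 0.1)
  expect_lt(max(abs(plus - trp$amplitudes[, 1])), 1e-10)
  expect_lt(max(abs(minus - trm$amplitudes[, 1])), 1e-10)
})

test_that("under-resolved kernel features are refused with a diagnostic", {
  fc <- feedback_coupling(0.1, tau = 25, phi = 0.8)
  expect_error(
    solve_volterra(feedback_site_system(fc, width = 1), 1 + 0i,
                   t_max = 50, dt = 0.5),
    "regularization width")
  expect_error(
    solve_volterra(feedback_site_system(fc, width = 0), 1 + 0i,
                   t_max = 50, dt = 5),
    "lag")
  # exact lags must sit on the grid
  expect_error(
    solve_volterra(feedback_site_system(fc, width = 0), 1 + 0i,
                   t_max = 50, dt = 0.3),
    "integer multiples")
  expect_error(
    site_system(c(0, 0), delta = matrix(c(0, 1i, 1i, 0), 2, 2)),
    "Hermitian")
})
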
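test_that("kernel evaluation puts the delta weight and the damped oscillation on the grid", {
  dt <- 0.002
  t <- (0:5) * dt
  # pure delta kernel
  expect_equal(kernel_eval(kernel_params(1, 1e-300, 1, 100), t, dt),
               c(2 / dt, rep(0, 5)), tolerance = 1e-200)
  # Gamma_0 identity holds for arbitrary parameters
  for (p in list(kernel_params(2, 3, 0.5, 50), kernel_params(0.1, 5000, 3, 20),
                 kernel_params(30, 1, 0.05, 250))) {
    expect_equal(kernel_eval(p, 0, dt), 2 * p$a / dt + p$b)
  }
  # direct evaluation at one step
  p <- kernel_params(2, 3, 0.5, 50)
  expect_equal(kernel_eval(p, t, dt)[2], 3 * exp(-0.004) * cos(0.1))
  # cosine at the Nyquist frequency alternates sign
  pn <- kernel_params(1e-12, 4, 1e6, pi / dt)
  expect_equal(sign(kernel_eval(pn, (1:4) * dt, dt)), c(-1, 1, -1, 1))
})

test_that("forward VACF: Markovian closed form, dual-route agreement, resolution guard", {
  # b = 0: exact exponential to near machine precision
  a <- 3; B <- 250
  cf <- forward_vacf(kernel_params(a, 0, 1, 50), B, 0.3, 0.002)
  expect_lt(max(abs(cf$values - B * exp(-a * cf$lags))), 1e-10 * B)

  # the matrix-exponential and characteristic-root routes are independent
  # and must agree across the constraint box (they are mutual oracles)
  sweep_params <- list(kernel_params(5, 2000, 0.5, 120),
                       kernel_params(0.5, 100, 3, 20),
                       kernel_params(30, 8000, 0.05, 240),
                       kernel_params(1, 500, 1.5, 60, sin_coeff = 0.05))
  for (p in sweep_params) {
    v1 <- forward_vacf(p, 1000, 0.2, 0.002, method = "expm")
    v2 <- forward_vacf(p, 1000, 0.2, 0.002, method = "roots")
    expect_lt(max(abs(v1$values - v2$values)) / 1000, 1e-8)
  }

  # damped-oscillator regime (a = 0 limit approached)
  po <- kernel_params(1e-8, 3000, 50, 50)
  v1 <- forward_vacf(po, 1, 0.2, 0.002)
  v2 <- forward_vacf(po, 1, 0.2, 0.002, method = "roots")
  expect_lt(max(abs(v1$values - v2$values)), 1e-8)

  expect_error(forward_vacf(kernel_params(1, 1, 1, 300), 1, 0.1, 0.002),
               "resolution error")
})

test_that("forward MSD: closed form at b = 0, ballistic limit, stencil consistency", {
  a <- 4; B <- 900
  mm <- forward_msd(kernel_params(a, 0, 1, 50), B, 0.3, 0.002)
  t <- mm$lags
  expect_rel_equal(mm$values[-1],
                   (2 * B * (t / a - (1 - exp(-a * t)) / a^2))[-1], 1e-8)
  expect_equal(mm$values[1], 0)

  # short-time ballistic limit MSD(dt)/dt^2 -> B
  p <- ref_params()
  for (dt in c(1e-3, 1e-4)) {
    m1 <- forward_msd(p, ref_B, 2 * dt, dt)$values[2]
    expect_lt(abs(m1 / dt^2 - ref_B) / ref_B, 5 * p$a * dt)
  }

  # second difference of the model MSD reproduces the model VACF to O(dt^2)
  dt <- 0.002
  mm2 <- forward_msd(p, ref_B, 0.1, dt)
  vv <- forward_vacf(p, ref_B, 0.1 - dt, dt)
  res <- msd_vacf_consistency(mm2, vv)
  expect_lt(res$max_abs / ref_B, 0.01)
})

test_that("discretized noisy VACF carries the exact localization-noise signature", {
  dt <- 0.002; sig <- 0.02
  # no noise: equals the stencil applied to the forward MSD
  p <- ref_params()
  d0 <- discretized_noisy_vacf(p, ref_B, 0, 10, dt)
  m <- forward_msd(p, ref_B, 11 * dt, dt)$values
  stencil <- (m[c(2, 3:12)] - 2 * m[1:11] + c(m[2], m[1:10])) / (2 * dt^2)
  expect_equal(d0$values, stencil, tolerance = 1e-12)

  # pure noise (B -> 0 limit): (2 sig^2/dt^2, -sig^2/dt^2, 0, ...)
  dn <- discretized_noisy_vacf(kernel_params(5, 1e-290, 1, 100), 1e-290,
                               sig, 5, dt)
  expect_equal(dn$values,
               c(2 * sig^2 / dt^2, -sig^2 / dt^2, rep(0, 4)),
               tolerance = 1e-9)

  # adding noise to simulator positions shifts the empirical lag-0/lag-1
  # VACF by (+2 sig^2/dt^2, -sig^2/dt^2) within sampling error
  tr <- sim_traj(n_steps = 2e5, seed = 31)
  trn <- add_localization_noise(tr, sig, seed = 32)
  cf0 <- vacf(velocities(tr), 2)$values
  cfn <- vacf(velocities(trn), 2)$values
  shift <- cfn - cf0
  expect_lt(abs(shift[1] - 2 * sig^2 / dt^2) / (2 * sig^2 / dt^2), 0.1)
  expect_lt(abs(shift[2] + sig^2 / dt^2) / (sig^2 / dt^2), 0.1)
})

test_that("kernel fit is exact on self-generated data and respects its bounds", {
  dt <- 0.002
  p0 <- ref_params()
  t <- (0:100) * dt
  k <- gle_kernel(dt, G_half = rep(NA_real_, 101),
                  gamma = kernel_eval(p0, t, dt))
  fit <- fit_kernel(k, B = ref_B)
  expect_rel_equal(coef(fit)[c("a", "b", "tau", "omega")],
                   c(a = 5, b = 2000, tau = 0.5, omega = 120), 1e-6)
  expect_false(any(fit$details$active_bounds))
  expect_true(all(is.finite(fit$fit_errors)))

  # fit idempotence over random draws inside the box
  set.seed(9)
  for (i in 1:8) {
    a <- runif(1, 1, 20); b <- runif(1, 500, 5000)
    tau <- runif(1, 0.1, 2); om <- runif(1, 30, 200)
    kk <- gle_kernel(dt, G_half = rep(NA_real_, 101),
                     gamma = kernel_eval(kernel_params(a, b, tau, om), t, dt))
    ff <- fit_kernel(kk, B = 1)
    expect_rel_equal(coef(ff)[c("a", "b", "tau", "omega")],
                     c(a, b, tau, om), 1e-4)
  }
})

test_that("kernel fit recovers parameters from the forward-solver round trip", {
  p0 <- ref_params()
  cf <- forward_vacf(p0, ref_B, 0.25, 0.002)
  fit <- fit_kernel(extract_kernel(cf, horizon = 0.2), B = ref_B)
  expect_rel_equal(coef(fit)[c("a", "b", "tau", "omega")],
                   c(5, 2000, 0.5, 120), 0.02)
  expect_equal(coef(fit)[["B"]], ref_B)
})

test_that("noisy-VACF fit recovers all six parameters from its own forward model", {
  dt <- 0.002
  p0 <- ref_params()
  dcf <- discretized_noisy_vacf(p0, ref_B, 0.02, 100, dt)
  fit <- fit_noisy_vacf(dcf)
  expect_rel_equal(coef(fit),
                   c(a = 5, b = 2000, tau = 0.5, omega = 120, B = 1000,
                     sigma_loc = 0.02), 1e-4)
  expect_false(fit$details$underdetermined)

  # degenerate flat input errors out
  flat <- gle_corrfun("VACF", lags = (0:50) * dt, values = rep(5, 51),
                      counts = rep(1, 51), dt = dt)
  expect_error(fit_noisy_vacf(flat), "degenerate-input")

  # a 5-step window cannot determine 6 parameters: flagged, not silent
  short <- gle_corrfun("VACF", lags = (0:5) * dt,
                       values = dcf$values[1:6], counts = rep(1, 6), dt = dt)
  expect_warning(fs <- fit_noisy_vacf(short, window = 5 * dt),
                 "under-determined")
  expect_true(fs$details$underdetermined)
})
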
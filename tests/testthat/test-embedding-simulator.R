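test_that("embedding-to-kernel map follows the Hamiltonian reduction", {
  # a = gamma_x / m
  e1 <- embedding_params(m = 1, m_y = 0.5, gamma_x = 2, gamma_y = 1,
                         K = 5000, kT = 1)
  k1 <- embedding_to_kernel(e1)
  expect_equal(k1$params$a, 2)
  # tau = 2 m_y / gamma_y = 1 s; Omega = sqrt(K/m_y - 1/tau^2)
  expect_equal(k1$params$tau, 1)
  expect_equal(k1$params$omega, sqrt(5000 / 0.5 - 1))
  expect_equal(k1$B, 1)

  # overdamped hidden mode is a domain error reporting the critical K
  e_over <- embedding_params(m = 1, m_y = 0.5, gamma_x = 2, gamma_y = 100,
                             K = 1, kT = 1)
  expect_error(embedding_to_kernel(e_over), "domain error.*K")

  # tau*Omega = 100: sine-correction coefficient 0.01, and the cosine-only
  # kernel approximates the embedding kernel to < 1.5% over [0, tau]
  p <- kernel_params(1, 1000, 1, 100)
  e <- kernel_to_embedding(p, B = 1)
  ke <- embedding_to_kernel(e)
  expect_equal(ke$params$sin_coeff, 1 / (1 * 100))
  expect_false(ke$flagged)
  t <- seq(0.002, 1, by = 0.002)
  k_cos <- kernel_eval(p, t, 0.002)
  k_sin <- kernel_eval(ke$params, t, 0.002)
  expect_lt(max(abs(k_sin - k_cos)) / max(abs(k_cos)), 0.015)
})

test_that("kernel-to-embedding inversion is exact and flags near-critical input", {
  p <- ref_params()
  e <- kernel_to_embedding(p, B = ref_B)
  # worked inversion: m_y = b / (Omega^2 + 1/tau^2)
  expect_equal(e$m_y, 2000 / (120^2 + 4), tolerance = 1e-12)
  expect_equal(e$m_y, 0.1389, tolerance = 1e-3)
  ke <- embedding_to_kernel(e)
  expect_equal(ke$params$a, p$a, tolerance = 1e-12)
  expect_equal(ke$params$b, p$b, tolerance = 1e-12)
  expect_equal(ke$params$tau, p$tau, tolerance = 1e-12)
  expect_equal(ke$params$omega, p$omega, tolerance = 1e-12)
  expect_equal(ke$B, ref_B)

  near <- kernel_to_embedding(kernel_params(1, 100, 1, 0.05), B = 1)
  expect_true(attr(near, "near_critical"))
})

test_that("simulator is reproducible, stationary and component-independent", {
  e <- kernel_to_embedding(ref_params(), ref_B)
  t1 <- simulate_embedding(e, 2000, 0.002, seed = 5)
  t2 <- simulate_embedding(e, 2000, 0.002, seed = 5)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  t3 <- simulate_embedding(e, 2000, 0.002, seed = 6)
  expect_false(identical(t1$x, t3$x))

  # stationarity from step 0: first and second halves have compatible
  # velocity variance; components uncorrelated
  tr <- simulate_embedding(e, 1e5, 0.002, seed = 8, keep_velocities = TRUE)
  v <- tr$meta$velocities
  n <- length(v$x)
  expect_lt(abs(cor(v$x, v$y)), 4 / sqrt(n / 250))   # ~250-step corr time
  expect_lt(abs(mean(v$x[1:5000]^2) / ref_B - 1), 0.2)

  expect_error(simulate_embedding(e, 100, dt = 0.05), "resolution error")
})

test_that("equipartition and the forward-solver equivalence hold for the simulator", {
  p <- ref_params()
  e <- kernel_to_embedding(p, ref_B)
  # exact stationary velocity variance equals kT/m before any sampling
  S <- gletraj:::embedding_stationary_cov(e)
  expect_equal(S[1, 1], e$kT / e$m, tolerance = 1e-10)

  tr <- simulate_embedding(e, 2e5, 0.002, seed = 12, keep_velocities = TRUE)
  v2 <- mean(c(tr$meta$velocities$x^2, tr$meta$velocities$y^2))
  expect_lt(abs(v2 - ref_B) / ref_B, 0.1)

  # empirical VACF vs forward solver with the embedding (sine-corrected)
  # kernel, within blocked Monte-Carlo errors
  vel <- velocities(tr)
  cf <- vacf(vel, 50)
  se <- vacf_block_se(vel, 50, n_blocks = 20)$se
  ek <- embedding_to_kernel(e)
  model <- forward_vacf(ek$params, ek$B, 0.1, 0.002)$values
  expect_lt(max(abs(cf$values - model) / se), 6)
})

test_that("Markovian limit: weak coupling gives an exponential VACF", {
  a <- 6; B <- 500
  e <- kernel_to_embedding(kernel_params(a, 0.5, 0.3, 60), B)
  tr <- simulate_embedding(e, 3e5, 0.002, seed = 21, keep_velocities = TRUE)
  v <- tr$meta$velocities
  cf_v <- vapply(0:25, function(i) {
    n <- length(v$x)
    (sum(v$x[1:(n - i)] * v$x[(1 + i):n]) +
       sum(v$y[1:(n - i)] * v$y[(1 + i):n])) / (2 * (n - i))
  }, numeric(1))
  model <- B * exp(-a * (0:25) * 0.002)
  expect_lt(max(abs(cf_v - model)) / B, 0.06)   # a few MC standard errors
})

test_that("localization noise: identity at zero, MSD plateau, reproducibility", {
  tr <- make_traj(rep(1, 600), rep(2, 600))
  expect_identical(add_localization_noise(tr, 0), tr)

  sig <- 0.02
  n1 <- add_localization_noise(tr, sig, seed = 3)
  n2 <- add_localization_noise(tr, sig, seed = 3)
  expect_identical(n1$x, n2$x)

  # static object: MSD plateau at 2 sigma^2 for all lags >= 1
  set.seed(4)
  big <- add_localization_noise(make_traj(rep(0, 4e4), rep(0, 4e4)), sig)
  m <- msd(big, 5)
  expect_rel_equal(m$values[-1], rep(2 * sig^2, 5), 0.05)
})

test_that("population generation is reproducible with correct bookkeeping", {
  specs <- demo_population_specs(n_cells = c(3L, 2L), n_steps = 600L,
                                 seed = 42L)
  pop1 <- generate_population(specs)
  pop2 <- generate_population(specs)
  expect_identical(pop1$ground_truth, pop2$ground_truth)
  expect_identical(pop1$trajectories[[1]]$x, pop2$trajectories[[1]]$x)
  expect_equal(nrow(pop1$ground_truth), 5L)
  expect_equal(as.integer(table(pop1$ground_truth$population)[c("wobbler", "synchro")]),
               c(3L, 2L))
  expect_equal(length(pop1$trajectories), 5L)
  expect_equal(length(pop1$trajectories[[1]]$x), 601L)

  # zero spread: all cells share the center parameters
  sp0 <- population_spec("mono", 3L,
                         center = list(a = 5, b = 2000, tau = 0.5,
                                       omega = 120, B = 1000),
                         spread = 0, n_steps = 600L, seed = 1L)
  gt <- generate_population(sp0)$ground_truth
  expect_equal(gt$a, rep(5, 3))
  expect_equal(gt$B, rep(1000, 3))

  # cohort-scale bookkeeping (59 cells in a 30/29 split)
  specs59 <- demo_population_specs(n_cells = c(30L, 29L), n_steps = 600L)
  set.seed(1)
  tabs <- do.call(rbind, lapply(specs59, draw_population_params))
  expect_equal(nrow(tabs), 59L)
})
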
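# Shared fixtures, built in code at test time.

# A minimal valid trajectory from explicit positions (length checks off).
make_traj <- function(x, y = rep(0, length(x)), dt = 0.002, ...) {
  gle_traj(x = x, y = y, dt = dt, min_length = 0L, ...)
}

# Reference kernel parameters used across modules (oscillatory, inside the
# fit constraint box) and the matching embedding.
ref_params <- function() kernel_params(a = 5, b = 2000, tau = 0.5, omega = 120)
ref_B <- 1000

# Short simulated trajectory for smoke tests.
sim_traj <- function(n_steps = 2e4, dt = 0.002, seed = 101,
                     p = ref_params(), B = ref_B, sigma_loc = 0, ...) {
  e <- kernel_to_embedding(p, B)
  tr <- simulate_embedding(e, n_steps = n_steps, dt = dt, seed = seed, ...)
  if (sigma_loc > 0) tr <- add_localization_noise(tr, sigma_loc)
  tr
}

# Analytic integral kernel G(t) = a + int_0^t b e^{-s/tau} cos(Omega s) ds.
analytic_G <- function(p, t) {
  u <- 1 / p$tau
  p$a + p$b * (u + exp(-u * t) * (p$omega * sin(p$omega * t) -
                                    u * cos(p$omega * t))) / (u^2 + p$omega^2)
}

# Two-population parameter cohort on the feature-table level:
# center ratios exp(+-shift) per feature, log-normal within-population
# spread sdlog.  Returns the median-rescaled matrix and the truth labels.
param_cohort <- function(seed, shift = 0.7 * c(1, 1, -1, -1, -1),
                         sdlog = 0.1, n_per = 20L) {
  set.seed(seed)
  c1 <- c(a = 4, b = 1200, tau = 0.6, omega = 150, B = 1500)
  c2 <- c1 * exp(shift)
  draw <- function(ctr, n) t(replicate(n, ctr * exp(stats::rnorm(5) * sdlog)))
  X <- rbind(draw(c1, n_per), draw(c2, n_per))
  colnames(X) <- names(c1)
  list(X = median_rescale(X), raw = X, truth = rep(1:2, each = n_per))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected),
                                              .Machine$double.eps)), tol)
}
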
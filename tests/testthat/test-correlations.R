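test_that("VACF estimator matches hand-computed and asymptotic oracles", {
  # constant velocity in both components
  cf <- vacf(velocities(make_traj((0:5) * 1, y = (0:5) * 1)), max_lag = 3)
  expect_equal(cf$values, rep(500^2, 4))

  # alternating single-component series: direct evaluation
  v <- structure(list(cell_id = "alt", v = list(x = c(1, -1, 1, -1),
                                                y = c(1, -1, 1, -1)),
                      dt = 0.002), class = "gle_vel")
  cf2 <- vacf(v, max_lag = 2)
  expect_equal(cf2$values, c(1, -1, 1))
  expect_equal(cf2$counts, c(4, 3, 2))

  # i.i.d. Gaussian: Cvv_0 -> s^2, later lags -> 0 (law of large numbers)
  set.seed(2)
  n <- 2e5
  s <- 3
  viid <- structure(list(cell_id = "iid",
                         v = list(x = rnorm(n, sd = s), y = rnorm(n, sd = s)),
                         dt = 0.002), class = "gle_vel")
  cf3 <- vacf(viid, max_lag = 3)
  expect_lt(abs(cf3$values[1] - s^2), 4 * s^2 / sqrt(n))
  expect_lt(max(abs(cf3$values[-1])), 4 * s^2 / sqrt(n))

  expect_error(vacf(viid, max_lag = n), "parameter error")
})

test_that("Cvv(0) is the pooled mean-squared velocity (the B estimator)", {
  tr <- sim_traj(n_steps = 5000)
  vel <- velocities(tr)
  cf <- vacf(vel, 10)
  expect_equal(cf$values[1],
               (mean(vel$v$x^2) + mean(vel$v$y^2)) / 2, tolerance = 1e-12)
})

test_that("MSD estimator: ballistic law, direct evaluation, model agreement", {
  # uniform motion x = v t
  v0 <- 40
  tr <- make_traj(v0 * (0:9) * 0.002, y = v0 * (0:9) * 0.002)
  cf <- msd(tr, 4)
  expect_equal(cf$values, (v0 * (0:4) * 0.002)^2)

  # x = (0,1,0,1,0): MSD_1 = 1, MSD_2 = 0
  tr2 <- make_traj(c(0, 1, 0, 1, 0), y = c(0, 1, 0, 1, 0))
  expect_equal(msd(tr2, 2)$values, c(0, 1, 0))

  # Markovian GLE closed form 2B[t/a - (1 - e^{-at})/a^2]
  a <- 3; B <- 400
  mm <- forward_msd(kernel_params(a, 0, 1, 50), B, 0.2, 0.002)
  t <- mm$lags
  expect_rel_equal(mm$values[-1],
                   (2 * B * (t / a - (1 - exp(-a * t)) / a^2))[-1], 1e-8)
})

test_that("second-difference stencil of the MSD reproduces the VACF", {
  # exact ballistic identity
  v0 <- 25; dt <- 0.002
  msd_cf <- gle_corrfun("MSD", lags = (0:20) * dt,
                        values = (v0 * (0:20) * dt)^2, counts = rep(1, 21),
                        dt = dt)
  vacf_cf <- gle_corrfun("VACF", lags = (0:19) * dt,
                         values = rep(v0^2, 20), counts = rep(1, 20),
                         dt = dt)
  res <- msd_vacf_consistency(msd_cf, vacf_cf)
  expect_lt(res$max_abs, 1e-8)

  # corrupted MSD entry -> residual localized around that lag
  bad <- msd_cf
  bad$values[11] <- bad$values[11] + 1
  res_bad <- msd_vacf_consistency(bad, vacf_cf)
  hit <- which(abs(res_bad$residuals) > 1e-8)
  expect_true(all(hit %in% 10:12))

  # estimator-level self consistency on simulated data (reported residual
  # small relative to the VACF scale)
  tr <- sim_traj(n_steps = 5e4)
  vel <- velocities(tr)
  res_sim <- msd_vacf_consistency(msd(tr, 40), vacf(vel, 40))
  expect_lt(res_sim$max_abs, 0.05 * vacf(vel, 0)$values[1])

  expect_error(
    msd_vacf_consistency(msd_cf, gle_corrfun("VACF", lags = 0, values = 1,
                                             counts = 1, dt = 0.001)),
    "parameter error")
})

test_that("velocity rescaling standardizes per cell or over the ensemble", {
  v1 <- structure(list(cell_id = "c1", v = list(x = c(1, 2, 3), y = c(1, 2, 3)),
                       dt = 0.002), class = "gle_vel")
  out <- rescale_velocities(list(v1), "per_cell")
  expect_lt(abs(mean(out$samples)), 1e-12)
  expect_equal(sd(out$samples), 1, tolerance = 1e-12)

  # two Gaussian cells with different means: per-cell collapses to N(0,1),
  # ensemble keeps the bimodal mixture (platykurtic, excess kurtosis < 0)
  set.seed(3)
  n <- 2e4
  mkvel <- function(id, mu) structure(
    list(cell_id = id, v = list(x = rnorm(n, mu), y = rnorm(n, mu)),
         dt = 0.002), class = "gle_vel")
  cells <- list(mkvel("up", 10), mkvel("down", -10))
  pc <- rescale_velocities(cells, "per_cell")
  expect_lt(abs(mean(pc$samples)), 4 / sqrt(4 * n))
  expect_lt(abs(sd(pc$samples) - 1), 4 / sqrt(4 * n))
  kurt <- function(z) mean((z - mean(z))^4) / var(z)^2
  expect_lt(abs(kurt(pc$samples) - 3), 0.1)
  en <- rescale_velocities(cells, "ensemble")
  expect_lt(kurt(en$samples), 3)    # bimodal mixture

  vz <- structure(list(cell_id = "z", v = list(x = rep(1, 5), y = rep(1, 5)),
                       dt = 0.002), class = "gle_vel")
  expect_error(rescale_velocities(list(vz)), "degenerate-cell")
})

test_that("conditional velocity law follows the bivariate Gaussian formula", {
  cf <- gle_corrfun("VACF", lags = (0:3) * 0.002,
                    values = c(100, 60, 0, -20), counts = rep(10, 4),
                    dt = 0.002)
  # lag 0: deterministic conditioning
  c0 <- conditional_velocity(cf, v1 = 7, lag = 0)
  expect_equal(c0$mean, 7)
  expect_equal(c0$variance, 0)
  # uncorrelated lag: independence limit
  c2 <- conditional_velocity(cf, v1 = 7, lag = 2)
  expect_equal(c2$mean, 0)
  expect_equal(c2$variance, 100)
  # generic lag
  c1 <- conditional_velocity(cf, v1 = 5, lag = 1)
  expect_equal(c1$mean, 5 * 60 / 100)
  expect_equal(c1$variance, 100 - 36)
  # estimator-noise violation |Cvv_lag| > Cvv_0 must error, not return a
  # negative variance
  bad <- cf
  bad$values[2] <- 120
  expect_error(conditional_velocity(bad, 1, 1), "non-PSD")
})

test_that("correlation functions serialize to delimited text and back", {
  tr <- sim_traj(n_steps = 2000)
  cf <- vacf(velocities(tr), 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_corrfun(cf, f)
  back <- read_corrfun(f)
  expect_equal(back$kind, "VACF")
  expect_equal(back$values, cf$values, tolerance = 1e-12)
  expect_equal(back$counts, cf$counts)
  expect_equal(back$dt, cf$dt)
})
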
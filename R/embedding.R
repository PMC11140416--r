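#' Markovian-embedding parameters
#'
#' Parameters of the coupled-Langevin ("Markovian embedding") model: the
#' observed coordinate x (effective mass `m`, friction `gamma_x`) is
#' harmonically coupled with strength `K` to a hidden coordinate y
#' (mass `m_y`, friction `gamma_y`); both are driven by white noise with
#' amplitude set by the thermal energy `kT`. Integrating out the hidden
#' coordinate yields a GLE for x with the memory kernel
#' `Gamma(t) = 2 a delta(t) + b exp(-t/tau) (cos(Omega t) +
#' sin(Omega t)/(tau Omega))`, which reduces to the pure cosine kernel when
#' `tau * Omega >> 1`.
#'
#' @param m,m_y effective masses.
#' @param gamma_x,gamma_y friction coefficients.
#' @param K harmonic coupling strength.
#' @param kT thermal energy (sets `B = kT/m` by equipartition).
#' @return An object of class `gle_embedding`.
#' @export
embedding_params <- function(m, m_y, gamma_x, gamma_y, K, kT) {
  vals <- c(m = m, m_y = m_y, gamma_x = gamma_x, gamma_y = gamma_y,
            K = K, kT = kT)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all embedding parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "gle_embedding")
}

#' @method print gle_embedding
#' @export
print.gle_embedding <- function(x, ...) {
  cat(sprintf(
    "Embedding: m = %.4g, m_y = %.4g, gamma_x = %.4g, gamma_y = %.4g, K = %.4g, kT = %.4g\n",
    x$m, x$m_y, x$gamma_x, x$gamma_y, x$K, x$kT))
  invisible(x)
}

#' Map embedding parameters to effective-kernel parameters
#'
#' `a = gamma_x / m`, `b = K / m`, `tau = 2 m_y / gamma_y`,
#' `Omega = sqrt(K / m_y - 1 / tau^2)`. The hidden mode must be underdamped
#' (`K / m_y > 1 / tau^2`) for an oscillatory kernel; otherwise a domain
#' error reporting the critical coupling is raised. The returned kernel
#' carries the sine-correction coefficient `1 / (tau Omega)`; when that
#' coefficient is >= 0.1 the cosine-only approximation of the kernel is no
#' longer accurate and `flagged` is set.
#'
#' @param e a [embedding_params()] object.
#' @return A list with `params` (a `gle_kernel_params` including
#'   `sin_coeff`), `B` (= kT/m) and `flagged`.
#' @export
embedding_to_kernel <- function(e) {
  stopifnot(inherits(e, "gle_embedding"))
  a <- e$gamma_x / e$m
  b <- e$K / e$m
  tau <- 2 * e$m_y / e$gamma_y
  disc <- e$K / e$m_y - 1 / tau^2
  if (disc <= 0)
    stop(sprintf(
      "domain error: hidden mode overdamped; need K > %.6g (got %.6g)",
      e$m_y / tau^2, e$K), call. = FALSE)
  omega <- sqrt(disc)
  sc <- 1 / (tau * omega)
  list(params = kernel_params(a, b, tau, omega, sin_coeff = sc),
       B = e$kT / e$m,
       flagged = sc >= 0.1)
}

#' Map effective-kernel parameters to an embedding (gauge m = 1)
#'
#' Inverse of [embedding_to_kernel()]. Only ratios are identifiable from
#' trajectories, so the observed mass is fixed to 1: `gamma_x = a`,
#' `K = b`, `m_y = K / (Omega^2 + 1/tau^2)`, `gamma_y = 2 m_y / tau`,
#' `kT = B`. Round-trips through [embedding_to_kernel()] exactly.
#'
#' @param p kernel parameters (`sin_coeff` is ignored; the embedding always
#'   regenerates it as `1/(tau Omega)`).
#' @param B mean-squared velocity (um^2/s^2).
#' @return A `gle_embedding`; when `Omega * tau < 0.1` (near the critical
#'   damping boundary) the attribute `near_critical` is set to `TRUE`.
#' @export
kernel_to_embedding <- function(p, B) {
  p <- as_kernel_params(p)
  stopifnot(is.finite(B), B > 0)
  m <- 1
  m_y <- p$b / (p$omega^2 + 1 / p$tau^2)
  e <- embedding_params(m = m, m_y = m_y, gamma_x = p$a,
                        gamma_y = 2 * m_y / p$tau, K = p$b, kT = B * m)
  attr(e, "near_critical") <- (p$omega * p$tau) < 0.1
  e
}

# Drift matrix of the per-component 4-state linear SDE in coordinates
# z = (x, v, r = x - y, v_y), and the white-noise intensity matrix Q.
embedding_drift <- function(e) {
  A <- matrix(0, 4L, 4L)
  A[1L, 2L] <- 1
  A[2L, 2L] <- -e$gamma_x / e$m
  A[2L, 3L] <- -e$K / e$m
  A[3L, 2L] <- 1
  A[3L, 4L] <- -1
  A[4L, 3L] <- e$K / e$m_y
  A[4L, 4L] <- -e$gamma_y / e$m_y
  Q <- diag(c(0, 2 * e$gamma_x * e$kT / e$m^2, 0,
              2 * e$gamma_y * e$kT / e$m_y^2))
  list(A = A, Q = Q)
}

# Exact discrete-time transition: Phi = exp(A dt) and the innovation
# covariance S = int_0^dt exp(A s) Q exp(A' s) ds, via Van Loan's block
# matrix exponential.
embedding_transition <- function(e, dt) {
  dr <- embedding_drift(e)
  d <- nrow(dr$A)
  blk <- rbind(cbind(-dr$A, dr$Q),
               cbind(matrix(0, d, d), t(dr$A))) * dt
  E <- as.matrix(Matrix::expm(blk))
  F2 <- E[(d + 1):(2 * d), (d + 1):(2 * d)]
  G1 <- E[1:d, (d + 1):(2 * d)]
  Phi <- t(F2)
  S <- Phi %*% G1
  S <- (S + t(S)) / 2
  list(Phi = Phi, S = S)
}

# Symmetric matrix square root (eigen-based; robust to near-singular S).
mat_sqrt <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

# Stationary covariance of (v, r, v_y): solves the Lyapunov equation
# A3 Sigma + Sigma A3' + Q3 = 0 by vectorization.
embedding_stationary_cov <- function(e) {
  dr <- embedding_drift(e)
  A3 <- dr$A[2:4, 2:4]
  Q3 <- dr$Q[2:4, 2:4]
  I3 <- diag(3L)
  M <- kronecker(I3, A3) + kronecker(A3, I3)
  Sig <- matrix(solve(M, -as.vector(Q3)), 3L, 3L)
  (Sig + t(Sig)) / 2
}

#' Simulate a 2-D trajectory from the Markovian embedding
#'
#' Integrates the coupled linear Langevin equations per spatial component
#' (x and y directions are independent with independent noise streams)
#' using the exact Gaussian transition of the linear SDE: the state is
#' propagated by the matrix exponential of the drift and innovations drawn
#' from the exact integrated covariance, so there is no time-discretization
#' bias at any step size. The process is started from its stationary
#' distribution (velocities and the relative coordinate drawn from the
#' stationary Gaussian), so the output is stationary from step 0.
#'
#' @param e a [embedding_params()] object.
#' @param n_steps number of steps (output has `n_steps + 1` positions).
#' @param dt sampling step (s). Must satisfy
#'   `dt * max(rates) < 1` where the rates are `gamma_x/m`, `gamma_y/m_y`,
#'   `1/tau` and `Omega`; beyond that the sampled output cannot resolve the
#'   dynamics (resolution error). The update itself is exact at any dt.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the trajectory is bit-reproducible.
#' @param cell_id identifier for the returned trajectory.
#' @param keep_velocities if `TRUE`, the instantaneous velocity states are
#'   attached as `meta$velocities` (a list with components `x`, `y` of
#'   length `n_steps + 1`), e.g. for equipartition checks.
#' @return A [gle_traj].
#' @export
simulate_embedding <- function(e, n_steps, dt, seed = NULL,
                               cell_id = "sim", keep_velocities = FALSE) {
  stopifnot(inherits(e, "gle_embedding"))
  n_steps <- as.integer(n_steps)
  k <- embedding_to_kernel(e)
  rates <- c(k$params$a, 1 / k$params$tau, k$params$omega,
             e$gamma_y / e$m_y)
  if (dt * max(rates) >= 1)
    stop(sprintf(
      "resolution error: dt * max rate = %.3g >= 1; reduce dt below %.3g s",
      dt * max(rates), 1 / max(rates)), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- embedding_transition(e, dt)
  L <- mat_sqrt(tr$S)
  Sig3 <- embedding_stationary_cov(e)
  L3 <- mat_sqrt(Sig3)
  comp <- function() {
    z0 <- c(0, L3 %*% stats::rnorm(3L))
    eta <- L %*% matrix(stats::rnorm(4L * n_steps), 4L, n_steps)
    propagate_lti(tr$Phi, z0, eta)
  }
  px <- comp()
  py <- comp()
  meta <- list(embedding = unclass(e), simulated = TRUE)
  if (keep_velocities)
    meta$velocities <- list(x = px[, 2L], y = py[, 2L])
  gle_traj(x = px[, 1L], y = py[, 1L], dt = dt, cell_id = cell_id,
           min_length = 0L, meta = meta)
}

#' Add localization noise to a trajectory
#'
#' Adds i.i.d. Gaussian offsets of standard deviation `sigma_loc` to every
#' position of every component, emulating the measurement error of
#' finite-resolution particle localization. The noise adds `2 sigma_loc^2`
#' to the MSD at every nonzero lag and an exact -1/2 lag-one anticorrelation
#' to the discrete VACF of an otherwise static object.
#'
#' @param traj a [gle_traj].
#' @param sigma_loc noise width (um), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return A [gle_traj] with `meta$sigma_loc` recorded.
#' @export
add_localization_noise <- function(traj, sigma_loc, seed = NULL) {
  stopifnot(inherits(traj, "gle_traj"), sigma_loc >= 0)
  if (sigma_loc == 0) return(traj)
  if (!is.null(seed)) set.seed(seed)
  n <- length(traj$x)
  traj$x <- traj$x + stats::rnorm(n, sd = sigma_loc)
  traj$y <- traj$y + stats::rnorm(n, sd = sigma_loc)
  traj$meta$sigma_loc <- sigma_loc
  traj
}

#' Specify a synthetic cell population
#'
#' Defines one sub-population of cells whose kernel parameters are drawn
#' log-normally around a common center, emulating the cell-to-cell parameter
#' spread seen in motility cohorts.
#'
#' @param name population label.
#' @param n_cells number of cells.
#' @param center named list of center parameters: either kernel form
#'   (`a`, `b`, `tau`, `omega`, `B`) or embedding form (`m`, `m_y`,
#'   `gamma_x`, `gamma_y`, `K`, `kT`).
#' @param spread relative log-normal spread: scalar or named vector of
#'   `sdlog` values per parameter (0 = all cells identical).
#' @param sigma_loc localization-noise width added to every trajectory (um).
#' @param n_steps,dt trajectory length (steps) and sampling step (s).
#' @param seed integer seed recorded in the spec; population generation is
#'   fully reproducible from it.
#' @return An object of class `gle_popspec`.
#' @export
population_spec <- function(name, n_cells, center, spread = 0.15,
                            sigma_loc = 0.02, n_steps = 10000L, dt = 0.002,
                            seed = 1L) {
  stopifnot(n_cells >= 1L, all(spread >= 0), sigma_loc >= 0)
  form <- if (all(c("a", "b", "tau", "omega", "B") %in% names(center))) {
    "kernel"
  } else if (all(c("m", "m_y", "gamma_x", "gamma_y", "K", "kT") %in%
                 names(center))) {
    "embedding"
  } else stop("center must be kernel (a,b,tau,omega,B) or embedding ",
              "(m,m_y,gamma_x,gamma_y,K,kT) parameters", call. = FALSE)
  structure(list(name = name, n_cells = as.integer(n_cells),
                 center = center, form = form, spread = spread,
                 sigma_loc = sigma_loc, n_steps = as.integer(n_steps),
                 dt = dt, seed = as.integer(seed)),
            class = "gle_popspec")
}

#' Draw per-cell ground-truth parameters for a population
#'
#' Log-normal multiplicative draws around the spec's center. Draws that
#' violate the oscillatory (underdamped hidden mode) condition are redrawn,
#' up to 100 attempts per cell. Consumes the current RNG stream; call
#' `set.seed()` or use [generate_population()] (which seeds from the spec)
#' for reproducibility.
#'
#' @param spec a [population_spec()].
#' @return A data frame with one row per cell: `cell_id`, `population`,
#'   the kernel-form ground truth `a, b, tau, omega, B`, and `sigma_loc`.
#' @export
draw_population_params <- function(spec) {
  stopifnot(inherits(spec, "gle_popspec"))
  ctr <- unlist(spec$center)
  sdlog <- if (length(spec$spread) == 1L) {
    stats::setNames(rep(spec$spread, length(ctr)), names(ctr))
  } else {
    out <- stats::setNames(rep(0, length(ctr)), names(ctr))
    out[names(spec$spread)] <- spec$spread
    out
  }
  draw_one <- function(i) {
    for (try in 1:100) {
      p <- ctr * exp(stats::rnorm(length(ctr)) * sdlog[names(ctr)])
      kp <- if (spec$form == "kernel") {
        list(a = p[["a"]], b = p[["b"]], tau = p[["tau"]],
             omega = p[["omega"]], B = p[["B"]])
      } else {
        e <- tryCatch(
          embedding_params(p[["m"]], p[["m_y"]], p[["gamma_x"]],
                           p[["gamma_y"]], p[["K"]], p[["kT"]]),
          error = function(err) NULL)
        if (is.null(e)) next
        ek <- tryCatch(embedding_to_kernel(e), error = function(err) NULL)
        if (is.null(ek)) next
        list(a = ek$params$a, b = ek$params$b, tau = ek$params$tau,
             omega = ek$params$omega, B = ek$B)
      }
      if (!is.null(kp)) return(kp)
    }
    stop("domain error: could not draw oscillatory-compatible parameters ",
         "after 100 attempts", call. = FALSE)
  }
  rows <- lapply(seq_len(spec$n_cells), function(i) {
    kp <- draw_one(i)
    data.frame(cell_id = sprintf("%s_%02d", spec$name, i),
               population = spec$name,
               a = kp$a, b = kp$b, tau = kp$tau, omega = kp$omega,
               B = kp$B, sigma_loc = spec$sigma_loc)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cell population with known ground truth
#'
#' Draws per-cell kernel parameters around the spec center(s), simulates
#' each cell with the Markovian embedding, adds localization noise, and
#' returns the trajectories together with the ground-truth parameter table.
#' Fully reproducible from the seed of the first spec.
#'
#' @param specs a [population_spec()] or a list of them (e.g. two
#'   sub-populations).
#' @return A list of class `gle_population` with elements `trajectories`
#'   (list of [gle_traj]) and `ground_truth` (data frame).
#' @export
generate_population <- function(specs) {
  if (inherits(specs, "gle_popspec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "gle_popspec")))
  set.seed(specs[[1L]]$seed)
  gt <- list()
  trajs <- list()
  for (spec in specs) {
    params <- draw_population_params(spec)
    gt[[spec$name]] <- params
    for (i in seq_len(nrow(params))) {
      row <- params[i, ]
      e <- kernel_to_embedding(
        kernel_params(row$a, row$b, row$tau, row$omega), B = row$B)
      tr <- simulate_embedding(e, n_steps = spec$n_steps, dt = spec$dt,
                               cell_id = row$cell_id)
      if (spec$sigma_loc > 0)
        tr <- add_localization_noise(tr, spec$sigma_loc)
      trajs[[row$cell_id]] <- tr
    }
  }
  structure(list(trajectories = trajs, ground_truth = do.call(rbind, gt),
                 specs = specs),
            class = "gle_population")
}

#' @method print gle_population
#' @export
print.gle_population <- function(x, ...) {
  tab <- table(x$ground_truth$population)
  cat(sprintf("Synthetic population: %d cells (%s)\n",
              nrow(x$ground_truth),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Demo two-population specification
#'
#' Two sub-populations emulating the two flagellar-beating phenotypes of
#' strongly confined *Chlamydomonas reinhardtii*: a "wobbler"-like
#' population (lower friction, faster motion) and a "synchro"-like one
#' (higher friction amplitudes, slower motion), with a realistic relative
#' cell-to-cell spread and pixel-scale localization noise. These defaults
#' define the package's reference study conditions.
#'
#' @param n_cells integer vector of length 2: cells per population.
#' @param n_steps,dt trajectory length and sampling step.
#' @param seed integer seed.
#' @param spread relative log-normal spread of all parameters.
#' @param sigma_loc localization noise width (um).
#' @return A list of two [population_spec()] objects.
#' @export
demo_population_specs <- function(n_cells = c(10L, 10L), n_steps = 10000L,
                                  dt = 0.002, seed = 1L, spread = 0.15,
                                  sigma_loc = 0.02) {
  list(
    population_spec("wobbler", n_cells[1L],
                    center = list(a = 4, b = 1200, tau = 0.6, omega = 150,
                                  B = 1500),
                    spread = spread, sigma_loc = sigma_loc,
                    n_steps = n_steps, dt = dt, seed = seed),
    population_spec("synchro", n_cells[2L],
                    center = list(a = 10, b = 4000, tau = 0.5, omega = 90,
                                  B = 400),
                    spread = spread, sigma_loc = sigma_loc,
                    n_steps = n_steps, dt = dt, seed = seed))
}
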
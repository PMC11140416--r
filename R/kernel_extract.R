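#' Memory-kernel container
#'
#' Discrete representation of the effective GLE memory kernel: the integral
#' kernel G on the half-step grid (i + 1/2) dt (units 1/s) and the kernel
#' Gamma on the full-step grid i dt (units 1/s^2). G is odd and Gamma even
#' in time, which is why the two live on staggered grids.
#'
#' @param dt sampling step (s).
#' @param G_half integral kernel values at (i + 1/2) dt, i = 0, 1, ...
#' @param gamma kernel values at i dt (may be `NULL` until
#'   [gamma_from_G()] is applied).
#' @param meta named list of provenance (horizon, source).
#' @return An object of class `gle_kernel`.
#' @export
gle_kernel <- function(dt, G_half, gamma = NULL, meta = list()) {
  structure(list(dt = dt, G_half = G_half, gamma = gamma,
                 gamma0 = if (!is.null(gamma)) gamma[1L] else NULL,
                 meta = meta),
            class = "gle_kernel")
}

#' @method print gle_kernel
#' @export
print.gle_kernel <- function(x, ...) {
  cat(sprintf("Memory kernel: %d half-steps, dt = %g s (horizon %.4g s)\n",
              length(x$G_half), x$dt, length(x$G_half) * x$dt))
  if (!is.null(x$gamma))
    cat(sprintf("  Gamma_0 = %.6g 1/s^2\n", x$gamma[1L]))
  invisible(x)
}

#' @export
as.data.frame.gle_kernel <- function(x, ...) {
  n <- length(x$G_half)
  data.frame(t_half_s = (seq_len(n) - 0.5) * x$dt, G = x$G_half,
             t_s = (seq_len(n) - 1) * x$dt,
             gamma = if (is.null(x$gamma)) NA_real_ else x$gamma)
}

#' Extract the integral kernel G from a VACF by Volterra inversion
#'
#' The GLE implies the Volterra equation
#' `Cvv(t) - Cvv(0) = -int_0^t Cvv(s) G(t-s) ds` with
#' `G(t) = int_0^t Gamma(s) ds`. Discretizing G on half steps and Cvv on
#' full steps gives the forward recursion (for i = 0 .. n_steps-1)
#'
#' `G[i+1/2] = 2 (Cvv_0 - Cvv_{i+1}) / (dt (Cvv_1 + Cvv_0))
#'            - sum_{j=1}^{i} G[i-j+1/2] (Cvv_{j+1} + Cvv_j) / (Cvv_1 + Cvv_0)`
#'
#' which is solved step by step; it is the exact inverse of its own
#' discretization, so substituting G back reproduces `Cvv_0 - Cvv_{i+1}`
#' to machine precision.
#'
#' @param vacf_cf a `gle_corrfun` of kind VACF with at least `n_steps + 1`
#'   lags.
#' @param n_steps extraction horizon in steps.
#' @param tol relative tolerance below which `Cvv_1 + Cvv_0` is considered
#'   zero (ill-conditioned inversion).
#' @return A `gle_kernel` with `G_half` filled.
#' @export
extract_G <- function(vacf_cf, n_steps, tol = 1e-12) {
  stopifnot(inherits(vacf_cf, "gle_corrfun"), vacf_cf$kind == "VACF")
  n_steps <- as.integer(n_steps)
  C <- vacf_cf$values
  if (n_steps < 1L || n_steps + 1L > length(C))
    stop("parameter error: n_steps exceeds the available VACF range",
         call. = FALSE)
  dt <- vacf_cf$dt
  denom <- C[2L] + C[1L]                      # Cvv_1 + Cvv_0
  if (abs(denom) <= tol * abs(C[1L]))
    stop("ill-conditioned error: Cvv_1 + Cvv_0 is (numerically) zero",
         call. = FALSE)
  G <- numeric(n_steps)
  # w[j] = (Cvv_{j+1} + Cvv_j) / (Cvv_1 + Cvv_0), j = 1..n_steps-1
  if (n_steps > 1L) w <- (C[3:(n_steps + 1L)] + C[2:n_steps]) / denom
  for (i in 0:(n_steps - 1L)) {
    acc <- 2 * (C[1L] - C[i + 2L]) / (dt * denom)
    if (i >= 1L)
      acc <- acc - sum(G[i:1L] * w[1:i])
    G[i + 1L] <- acc
  }
  gle_kernel(dt = dt, G_half = G,
             meta = list(horizon = n_steps * dt, n_steps = n_steps))
}

#' Kernel Gamma from the integral kernel G
#'
#' Central difference on the staggered grid:
#' `Gamma_i = (G[i+1/2] - G[i-1/2]) / dt` for i >= 1, and the initial value
#' `Gamma_0 = 2 G[1/2] / dt` (G is odd, so G(-dt/2) = -G(dt/2)).
#'
#' @param kernel a `gle_kernel` with `G_half` populated.
#' @return The kernel with `gamma` (and `gamma0`) filled.
#' @export
gamma_from_G <- function(kernel) {
  stopifnot(inherits(kernel, "gle_kernel"))
  G <- kernel$G_half
  n <- length(G)
  gamma <- numeric(n)
  gamma[1L] <- 2 * G[1L] / kernel$dt
  if (n > 1L)
    gamma[2:n] <- diff(G) / kernel$dt
  kernel$gamma <- gamma
  kernel$gamma0 <- gamma[1L]
  kernel
}

#' Extract the memory kernel from a trajectory or a VACF
#'
#' Convenience composition: (velocities ->) VACF -> [extract_G()] ->
#' [gamma_from_G()]. The default horizon of 0.2 s matches the window over
#' which the parametric kernel is fitted; extraction beyond it amplifies
#' estimator noise.
#'
#' @param x a [gle_traj], a `gle_vel`, or a `gle_corrfun` of kind VACF.
#' @param horizon extraction horizon in seconds (default 0.2).
#' @param smooth_window running-mean window applied to positions before
#'   differentiation when `x` is a trajectory (default 2; see
#'   [smooth_positions()]).
#' @return A `gle_kernel` with both `G_half` and `gamma` filled and an
#'   attached `vacf` element.
#' @export
extract_kernel <- function(x, horizon = 0.2, smooth_window = 2L) {
  cf <- if (inherits(x, "gle_corrfun")) {
    x
  } else {
    vel <- if (inherits(x, "gle_traj")) {
      velocities(smooth_positions(x, smooth_window))
    } else if (inherits(x, "gle_vel")) {
      x
    } else stop("x must be a gle_traj, gle_vel or VACF gle_corrfun",
                call. = FALSE)
    n_steps_req <- as.integer(round(horizon / vel$dt))
    vacf(vel, max_lag = min(n_steps_req + 1L, length(vel$v$x) - 1L))
  }
  n_steps <- as.integer(round(horizon / cf$dt))
  n_steps <- min(n_steps, length(cf$values) - 1L)
  k <- gamma_from_G(extract_G(cf, n_steps))
  k$vacf <- cf
  k$meta$horizon <- horizon
  k
}

#' Serialize a memory kernel to delimited text
#'
#' Columns `t_s, gamma`; '#' header lines carry dt, horizon and Gamma_0.
#'
#' @param kernel a `gle_kernel` with `gamma` filled.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "gle_kernel"), !is.null(kernel$gamma))
  n <- length(kernel$gamma)
  hdr <- c(sprintf("# dt: %.15g", kernel$dt),
           sprintf("# horizon: %.15g", n * kernel$dt),
           sprintf("# gamma0: %.15g", kernel$gamma0),
           "t_s,gamma")
  body <- sprintf("%.15g,%.15g", (0:(n - 1L)) * kernel$dt, kernel$gamma)
  writeLines(c(hdr, body), path)
  invisible(path)
}
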
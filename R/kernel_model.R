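#' Parametric memory-kernel parameters
#'
#' The effective friction kernel of the motility model is a delta peak plus
#' an exponentially damped oscillation,
#' `Gamma(t) = 2 a delta(t) + b exp(-t/tau) cos(Omega t)`,
#' with delta-peak amplitude `a` (1/s), oscillation amplitude `b` (1/s^2),
#' decay time `tau` (s) and oscillation frequency `omega` (1/s). An optional
#' `sin_coeff` c generalizes the oscillatory part to
#' `cos(Omega t) + c sin(Omega t)`, the exact form produced by the
#' harmonic Markovian embedding (where c = 1/(tau Omega)).
#'
#' @param a,b,tau,omega kernel parameters (see description).
#' @param sin_coeff coefficient of the sine correction (default 0, the pure
#'   cosine kernel used for fitting).
#' @return An object of class `gle_kernel_params`.
#' @export
kernel_params <- function(a, b, tau, omega, sin_coeff = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(tau), is.finite(omega),
            a > 0 || b > 0, tau > 0, omega >= 0)
  structure(list(a = a, b = b, tau = tau, omega = omega,
                 sin_coeff = sin_coeff),
            class = "gle_kernel_params")
}

#' @method print gle_kernel_params
#' @export
print.gle_kernel_params <- function(x, ...) {
  cat(sprintf(
    "Kernel parameters: a = %.5g 1/s, b = %.5g 1/s^2, tau = %.5g s, Omega = %.5g 1/s%s\n",
    x$a, x$b, x$tau, x$omega,
    if (x$sin_coeff != 0) sprintf(" (sin coeff %.4g)", x$sin_coeff) else ""))
  invisible(x)
}

as_kernel_params <- function(p) {
  if (inherits(p, "gle_kernel_params")) return(p)
  if (is.numeric(p) && !is.null(names(p)))
    return(kernel_params(p[["a"]], p[["b"]], p[["tau"]], p[["omega"]],
                         if ("sin_coeff" %in% names(p)) p[["sin_coeff"]] else 0))
  if (is.list(p))
    return(kernel_params(p$a, p$b, p$tau, p$omega,
                         if (!is.null(p$sin_coeff)) p$sin_coeff else 0))
  stop("cannot interpret kernel parameters", call. = FALSE)
}

#' Evaluate the parametric kernel on a discrete time grid
#'
#' On a grid with step `dt` the delta peak contributes `2a/dt` to the t = 0
#' value, so `Gamma(0) = 2 a / dt + b` and
#' `Gamma(i dt) = b exp(-i dt / tau) cos(Omega i dt)` for i >= 1 (plus the
#' sine correction when `sin_coeff != 0`).
#'
#' @param p kernel parameters ([kernel_params()] or coercible).
#' @param t uniform time grid starting at 0 (seconds).
#' @param dt grid step (seconds), used for the delta-peak discretization.
#' @return Numeric vector of kernel values (1/s^2).
#' @export
kernel_eval <- function(p, t, dt) {
  p <- as_kernel_params(p)
  osc <- p$b * exp(-t / p$tau) *
    (cos(p$omega * t) + p$sin_coeff * sin(p$omega * t))
  out <- osc
  out[t == 0] <- 2 * p$a / dt + p$b
  out
}

# Drift matrix of the 3-state linear system obeyed by the model VACF:
# state (C, P, Q) with P, Q the exp(-t/tau)cos / exp(-t/tau)sin convolution
# integrals of C.  dC/dt = -a C - b (P + c Q); dP/dt = C - P/tau - Omega Q;
# dQ/dt = Omega P - Q/tau.
vacf_drift_matrix <- function(p) {
  u <- 1 / p$tau
  matrix(c(-p$a, -p$b, -p$b * p$sin_coeff,
           1,    -u,   -p$omega,
           0,    p$omega, -u),
         nrow = 3L, byrow = TRUE)
}

#' Model VACF from kernel parameters (forward solver)
#'
#' Solves the memory equation
#' `C'(t) = -a C(t) - int_0^t b exp(-(t-s)/tau) cos(Omega (t-s)) C(s) ds`
#' (plus the sine correction when present) with `C(0) = B`. Two independent
#' routes are provided and agree to high precision:
#' \describe{
#'   \item{`"expm"`}{the convolution is removed by two auxiliary states,
#'     giving a 3-variable linear ODE whose exact solution is propagated by
#'     the matrix exponential of the constant drift (exact on the grid up to
#'     floating point).}
#'   \item{`"roots"`}{partial-fraction closed form: the Laplace transform of
#'     C is a rational function with a cubic denominator; C(t) is the sum of
#'     three exponentials at the cubic's roots.}
#' }
#'
#' @param p kernel parameters.
#' @param B mean-squared velocity, C(0) (um^2/s^2).
#' @param t_max horizon (s).
#' @param dt grid step (s); must satisfy `dt * omega <= 0.5` so the
#'   oscillation is resolved.
#' @param method `"expm"` (default) or `"roots"`.
#' @return A `gle_corrfun` of kind VACF on the grid `seq(0, t_max, dt)`.
#' @export
forward_vacf <- function(p, B, t_max, dt, method = c("expm", "roots")) {
  p <- as_kernel_params(p)
  method <- match.arg(method)
  if (dt * p$omega > 0.5)
    stop("resolution error: dt * omega must be <= 0.5", call. = FALSE)
  n <- as.integer(round(t_max / dt))
  lags <- (0:n) * dt
  vals <- if (method == "expm") {
    M <- vacf_drift_matrix(p)
    Phi <- as.matrix(Matrix::expm(M * dt))
    s <- c(B, 0, 0)
    out <- numeric(n + 1L)
    out[1L] <- B
    for (i in seq_len(n)) {
      s <- Phi %*% s
      out[i + 1L] <- s[1L]
    }
    out
  } else {
    forward_vacf_roots(p, B, lags)
  }
  gle_corrfun("VACF", lags = lags, values = vals,
              counts = rep(NA_real_, n + 1L), dt = dt, n_components = 1L)
}

# Closed form via the characteristic cubic.  With u = 1/tau, c = sin_coeff:
# denominator D(s) = (s + a) ((s + u)^2 + Omega^2) + b (s + u + c Omega),
# numerator N(s) = (s + u)^2 + Omega^2; C(t) = B sum_k N(l_k)/D'(l_k) e^{l_k t}.
forward_vacf_roots <- function(p, B, t) {
  u <- 1 / p$tau
  cc <- p$sin_coeff
  # D(s) = s^3 + (a + 2u) s^2 + (u^2 + Omega^2 + 2ua + b) s
  #        + a (u^2 + Omega^2) + b (u + c Omega)
  c2 <- p$a + 2 * u
  c1 <- u^2 + p$omega^2 + 2 * u * p$a + p$b
  c0 <- p$a * (u^2 + p$omega^2) + p$b * (u + cc * p$omega)
  roots <- polyroot(c(c0, c1, c2, 1))
  vals <- rep(0 + 0i, length(t))
  for (l in roots) {
    Nl <- (l + u)^2 + p$omega^2
    Dpl <- 3 * l^2 + 2 * c2 * l + c1
    vals <- vals + Nl / Dpl * exp(l * t)
  }
  B * Re(vals)
}

#' Model MSD from kernel parameters (forward solver)
#'
#' The MSD is the double time integral of the VACF,
#' `MSD(t) = 2 int_0^t (t - s) C(s) ds`. The 3-state VACF system is
#' augmented with `I(t) = int_0^t C` and `MSD' = 2 I`, and the resulting
#' 5-variable constant-coefficient linear ODE is propagated exactly by its
#' matrix exponential. Short-time limit `B t^2` (ballistic), `MSD(0) = 0`.
#'
#' @inheritParams forward_vacf
#' @return A `gle_corrfun` of kind MSD on the grid `seq(0, t_max, dt)`.
#' @export
forward_msd <- function(p, B, t_max, dt) {
  p <- as_kernel_params(p)
  if (dt * p$omega > 0.5)
    stop("resolution error: dt * omega must be <= 0.5", call. = FALSE)
  n <- as.integer(round(t_max / dt))
  M3 <- vacf_drift_matrix(p)
  M <- matrix(0, 5L, 5L)
  M[1:3, 1:3] <- M3
  M[4L, 1L] <- 1          # I' = C
  M[5L, 4L] <- 2          # MSD' = 2 I
  Phi <- as.matrix(Matrix::expm(M * dt))
  s <- c(B, 0, 0, 0, 0)
  out <- numeric(n + 1L)
  for (i in seq_len(n)) {
    s <- Phi %*% s
    out[i + 1L] <- s[5L]
  }
  gle_corrfun("MSD", lags = (0:n) * dt, values = out,
              counts = rep(NA_real_, n + 1L), dt = dt, n_components = 1L)
}

#' Discretized model VACF including localization noise
#'
#' Builds the model prediction for the VACF estimated from positions sampled
#' with a finite step and contaminated by i.i.d. Gaussian localization noise
#' of width `sigma_loc`: the noisy MSD is
#' `MSD_noise(t) = MSD_theo(t) + 2 sigma_loc^2` for t != 0 (and 0 at t = 0),
#' and the discrete VACF follows from the second-difference stencil
#' `Cvv_fit(i dt) = (MSD_noise((i+1)dt) - 2 MSD_noise(i dt) +
#' MSD_noise((i-1)dt)) / (2 dt^2)`, with the even extension
#' `MSD_noise(-dt) = MSD_noise(dt)` at i = 0.
#'
#' Pure localization noise (no motion) leaves the signature
#' `(2 sigma^2/dt^2, -sigma^2/dt^2, 0, 0, ...)`: a lag-one anticorrelation
#' of exactly -1/2 of the apparent Cvv(0).
#'
#' @param p kernel parameters.
#' @param B mean-squared velocity (um^2/s^2).
#' @param sigma_loc localization-noise width (um).
#' @param n_lags number of positive lags (output covers 0..n_lags).
#' @param dt sampling step (s).
#' @return A `gle_corrfun` of kind VACF (the discretized model prediction).
#' @export
discretized_noisy_vacf <- function(p, B, sigma_loc, n_lags, dt) {
  n_lags <- as.integer(n_lags)
  stopifnot(n_lags >= 1L, sigma_loc >= 0)
  m_theo <- forward_msd(p, B, t_max = (n_lags + 1L) * dt, dt = dt)$values
  m_noise <- m_theo + 2 * sigma_loc^2
  m_noise[1L] <- 0
  m_ext <- c(m_noise[2L], m_noise)        # even extension at -dt
  i <- 0:n_lags
  vals <- (m_ext[i + 3L] - 2 * m_ext[i + 2L] + m_ext[i + 1L]) / (2 * dt^2)
  gle_corrfun("VACF", lags = i * dt, values = vals,
              counts = rep(NA_real_, n_lags + 1L), dt = dt,
              n_components = 1L)
}

# ---- fitting ---------------------------------------------------------------

# Bounds on (a, b, tau, omega) used by both fits.  The delta and oscillation
# contributions to the initial kernel value Gamma_0 = 2a/dt + b are each
# constrained to lie between 0.1% and 99.9% of Gamma_0; tau and omega are
# box-constrained to the physiological window.
kernel_fit_bounds <- function(gamma0, dt,
                              tau_range = c(0.05, 3),
                              omega_range = c(20, 250)) {
  list(lower = c(a = 0.001 * gamma0 * dt / 2, b = 0.001 * gamma0,
                 tau = tau_range[1L], omega = omega_range[1L]),
       upper = c(a = 0.999 * gamma0 * dt / 2, b = 0.999 * gamma0,
                 tau = tau_range[2L], omega = omega_range[2L]))
}

# Latin-hypercube starting points inside the box, deterministic (local seed;
# the caller's RNG stream is untouched).
lhs_starts <- function(lower, upper, n_starts, seed = 20L) {
  d <- length(lower)
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts, d))
  sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
}

run_multistart_nlslm <- function(resid_fn, starts, lower, upper,
                                 max_iter = 200L) {
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    # individual starts may fail or stall; only the best survivor matters
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[r, ], fn = resid_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = max_iter, ftol = 1e-12,
                             ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit error: no optimizer start converged", call. = FALSE)
  best
}

# Parameter standard deviations from the local quadratic model at the
# optimum (diagonal of the covariance sigma^2 (J'J)^-1).
nlslm_param_sd <- function(fit) {
  p <- length(fit$par)
  n <- length(fit$fvec)
  dof <- max(n - p, 1L)
  s2 <- fit$deviance / dof
  cov_un <- tryCatch(solve(fit$hessian / 2), error = function(e) NULL)
  if (is.null(cov_un)) return(rep(NA_real_, p))
  sqrt(pmax(diag(cov_un), 0) * s2)
}

flag_active_bounds <- function(par, lower, upper, rel = 1e-4) {
  span <- pmax(upper - lower, .Machine$double.eps)
  (par - lower) / span < rel | (upper - par) / span < rel
}

#' Cell-parameter record
#'
#' Bundles the fitted kernel parameters with the mean-squared velocity B,
#' the localization-noise width (when estimated), per-parameter standard
#' deviations and fit diagnostics.
#'
#' @param kernel a `gle_kernel_params`.
#' @param B mean-squared velocity (um^2/s^2).
#' @param sigma_loc localization-noise width (um) or `NA`.
#' @param fit_errors named numeric vector of parameter standard deviations.
#' @param cell_id cell identifier.
#' @param details list of fit diagnostics (ssr, active bounds, ...).
#' @return An object of class `gle_cellparams`.
#' @export
cell_params <- function(kernel, B, sigma_loc = NA_real_,
                        fit_errors = NULL, cell_id = "cell",
                        details = list()) {
  structure(list(kernel = kernel, B = B, sigma_loc = sigma_loc,
                 fit_errors = fit_errors, cell_id = cell_id,
                 details = details),
            class = "gle_cellparams")
}

#' @method print gle_cellparams
#' @export
print.gle_cellparams <- function(x, ...) {
  k <- x$kernel
  cat(sprintf("Cell '%s':\n", x$cell_id))
  cat(sprintf("  a = %.5g 1/s, b = %.5g 1/s^2, tau = %.5g s, Omega = %.5g 1/s\n",
              k$a, k$b, k$tau, k$omega))
  cat(sprintf("  B = %.5g um^2/s^2", x$B))
  if (is.finite(x$sigma_loc)) cat(sprintf(", sigma_loc = %.4g um", x$sigma_loc))
  cat("\n")
  if (!is.null(x$details$active_bounds) && any(x$details$active_bounds))
    cat("  note: active bounds on",
        paste(names(which(x$details$active_bounds)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.gle_cellparams <- function(object, ...) {
  k <- object$kernel
  c(a = k$a, b = k$b, tau = k$tau, omega = k$omega, B = object$B,
    sigma_loc = object$sigma_loc)
}

#' Fit the parametric kernel to an extracted memory kernel
#'
#' Bounded least squares of the delta-plus-damped-oscillation kernel against
#' the extracted `Gamma(i dt)` values over the first `window` seconds.
#' The delta and oscillation contributions to the initial value
#' `Gamma_0 = 2a/dt + b` are each constrained between 0.1% and 99.9% of the
#' data's `Gamma_0`; `tau` is constrained to \[0.05, 3\] s and `omega` to
#' \[20, 250\] 1/s. Because the oscillatory model has local minima in
#' `omega`, the optimizer is restarted from Latin-hypercube draws inside the
#' box and the best solution is kept. Parameter standard deviations come
#' from the diagonal of the parameter covariance at the optimum.
#'
#' @param kernel a `gle_kernel` with `gamma` filled (see
#'   [extract_kernel()]).
#' @param window fit window in seconds (default 0.2).
#' @param B mean-squared velocity to attach; defaults to Cvv(0) of the
#'   kernel's attached VACF when present.
#' @param n_starts number of multi-start draws (default 8).
#' @param tau_range,omega_range box constraints for tau (s) and omega (1/s).
#' @param cell_id identifier for the result.
#' @return A [cell_params()] object (without `sigma_loc`).
#' @export
fit_kernel <- function(kernel, window = 0.2, B = NULL, n_starts = 8L,
                       tau_range = c(0.05, 3), omega_range = c(20, 250),
                       cell_id = "cell") {
  stopifnot(inherits(kernel, "gle_kernel"), !is.null(kernel$gamma))
  dt <- kernel$dt
  n <- length(kernel$gamma)
  t <- (0:(n - 1L)) * dt
  keep <- t <= window + 1e-12
  if (sum(keep) < 5L)
    stop("parameter error: kernel does not cover the fit window",
         call. = FALSE)
  t <- t[keep]
  g <- kernel$gamma[keep]
  gamma0 <- g[1L]
  if (!is.finite(gamma0) || gamma0 <= 0)
    stop("degenerate-input error: nonpositive Gamma_0", call. = FALSE)
  bd <- kernel_fit_bounds(gamma0, dt, tau_range, omega_range)
  resid_fn <- function(th) {
    kernel_eval(kernel_params(th[1L], th[2L], th[3L], th[4L]), t, dt) - g
  }
  starts <- lhs_starts(bd$lower, bd$upper, n_starts)
  # one informed start: split Gamma_0 evenly between the two contributions
  starts <- rbind(c(gamma0 * dt / 4, gamma0 / 2, 0.5,
                    mean(omega_range)), starts)
  fit <- run_multistart_nlslm(resid_fn, starts, bd$lower, bd$upper)
  par <- stats::setNames(fit$par, c("a", "b", "tau", "omega"))
  sds <- stats::setNames(nlslm_param_sd(fit), names(par))
  active <- flag_active_bounds(par, bd$lower, bd$upper)
  if (is.null(B) && !is.null(kernel$vacf)) B <- kernel$vacf$values[1L]
  if (is.null(B)) B <- NA_real_
  cell_params(kernel_params(par[["a"]], par[["b"]], par[["tau"]],
                            par[["omega"]]),
              B = B, fit_errors = sds, cell_id = cell_id,
              details = list(method = "kernel", ssr = fit$deviance,
                             n_points = length(t), window = window,
                             active_bounds = active,
                             converged = fit$info %in% 1:4,
                             gamma0_data = gamma0, dt = dt))
}

#' Fit the discretized noisy VACF model to an experimental VACF
#'
#' Minimizes the summed squared difference between the measured VACF and the
#' discretized model prediction ([discretized_noisy_vacf()]) over the six
#' parameters (a, b, tau, omega, B, sigma_loc), for lags up to `window`
#' seconds (the longer-lag VACF estimate is dominated by noise). Bounds are
#' as in [fit_kernel()] for the kernel parameters, `B` within a factor 10 of
#' the measured Cvv(0), and `sigma_loc` in \[0, 1\] um (well above
#' pixel-scale noise while preventing a noise/signal swap).
#'
#' With very short windows the six-parameter model is under-determined; the
#' fit then carries `details$underdetermined = TRUE` and a warning is
#' emitted rather than reporting a silent success.
#'
#' @param vacf_exp a `gle_corrfun` of kind VACF (measured).
#' @param window fit window in seconds (default 0.2).
#' @param n_starts multi-start draws (default 8).
#' @param sigma_max upper bound for sigma_loc in um (default 1).
#' @param tau_range,omega_range box constraints as in [fit_kernel()].
#' @param cell_id identifier.
#' @return A [cell_params()] object with `sigma_loc` estimated.
#' @export
fit_noisy_vacf <- function(vacf_exp, window = 0.2, n_starts = 8L,
                           sigma_max = 1,
                           tau_range = c(0.05, 3), omega_range = c(20, 250),
                           cell_id = "cell") {
  stopifnot(inherits(vacf_exp, "gle_corrfun"), vacf_exp$kind == "VACF")
  dt <- vacf_exp$dt
  c0 <- vacf_exp$values[1L]
  if (!is.finite(c0) || c0 <= 0)
    stop("degenerate-input error: nonpositive Cvv(0)", call. = FALSE)
  if (stats::sd(vacf_exp$values) <= 1e-12 * abs(c0))
    stop("degenerate-input error: flat VACF", call. = FALSE)
  n_w <- as.integer(round(window / dt))
  n_w <- min(n_w, length(vacf_exp$values) - 1L)
  if (n_w < 1L)
    stop("parameter error: VACF does not cover the fit window", call. = FALSE)
  target <- vacf_exp$values[1:(n_w + 1L)]
  # rough Gamma_0 from a short Volterra inversion, for the a/b bounds
  g0 <- tryCatch(
    gamma_from_G(extract_G(vacf_exp, min(5L, n_w)))$gamma0,
    error = function(e) NA_real_)
  if (!is.finite(g0) || g0 <= 0) g0 <- 2 * c0 / dt  # fallback scale
  bd4 <- kernel_fit_bounds(g0, dt, tau_range, omega_range)
  lower <- c(bd4$lower, B = 0.1 * c0, sigma_loc = 0)
  upper <- c(bd4$upper, B = 10 * c0, sigma_loc = sigma_max)
  resid_fn <- function(th) {
    discretized_noisy_vacf(kernel_params(th[1L], th[2L], th[3L], th[4L]),
                           B = th[5L], sigma_loc = th[6L],
                           n_lags = n_w, dt = dt)$values - target
  }
  # Staged initialization.  The localization noise enters only the first
  # two lags (+2 sigma^2/dt^2 at lag 0, -sigma^2/dt^2 at lag 1), so the
  # noise-free five-parameter model is first fitted to lags >= 2 from a
  # neutral grid of starts covering the multi-modal omega axis; sigma_loc
  # is then read off the lag-0 residual and the full six-parameter model is
  # polished jointly (with additional Latin-hypercube joint starts as a
  # safety net).
  stage1 <- NULL
  if (n_w >= 4L) {
    s1_resid <- function(th) {
      (discretized_noisy_vacf(kernel_params(th[1L], th[2L], th[3L], th[4L]),
                              B = th[5L], sigma_loc = 0,
                              n_lags = n_w, dt = dt)$values - target)[-(1:2)]
    }
    s1_starts <- as.matrix(expand.grid(
      a = 2, b = NA, tau = c(0.3, 1.5),
      omega = seq(omega_range[1L] * 1.2, omega_range[2L] * 0.95,
                  length.out = 6L), B = c0))
    s1_starts[, "b"] <- pmin(pmax(s1_starts[, "omega"]^2 / 4,
                                  lower[["b"]]), upper[["b"]])
    s1_starts[, "a"] <- pmin(pmax(s1_starts[, "a"], lower[["a"]]),
                             upper[["a"]])
    stage1 <- tryCatch(
      run_multistart_nlslm(s1_resid, s1_starts, lower[1:5], upper[1:5]),
      error = function(e) NULL)
  }
  starts <- lhs_starts(lower, upper, n_starts, seed = 21L)
  starts <- rbind(c(g0 * dt / 4, g0 / 2, 0.5, mean(omega_range), c0, 0.01),
                  starts)
  if (!is.null(stage1)) {
    th <- stage1$par
    m0 <- discretized_noisy_vacf(kernel_params(th[1L], th[2L], th[3L],
                                               th[4L]),
                                 B = th[5L], sigma_loc = 0,
                                 n_lags = n_w, dt = dt)$values[1L]
    sig0 <- sqrt(max(0, (target[1L] - m0) * dt^2 / 2))
    starts <- rbind(pmin(pmax(c(th, min(sig0, sigma_max)), lower), upper),
                    starts)
  }
  fit <- run_multistart_nlslm(resid_fn, starts, lower, upper)
  par <- stats::setNames(fit$par,
                         c("a", "b", "tau", "omega", "B", "sigma_loc"))
  sds <- stats::setNames(nlslm_param_sd(fit), names(par))
  active <- flag_active_bounds(par, lower, upper)
  n_pts <- n_w + 1L
  # scale-invariant conditioning of the quadratic model at the optimum
  h <- fit$hessian
  dsc <- sqrt(pmax(diag(h), .Machine$double.eps))
  rc <- tryCatch(rcond(h / tcrossprod(dsc)), error = function(e) 0)
  underdet <- n_pts < length(par) + 2L || !is.finite(rc) || rc < 1e-12
  if (underdet)
    warning("noisy-VACF fit is under-determined for this window; ",
            "parameter covariances are unreliable", call. = FALSE)
  cell_params(kernel_params(par[["a"]], par[["b"]], par[["tau"]],
                            par[["omega"]]),
              B = par[["B"]], sigma_loc = par[["sigma_loc"]],
              fit_errors = sds, cell_id = cell_id,
              details = list(method = "noisy_vacf", ssr = fit$deviance,
                             n_points = n_pts, window = window,
                             active_bounds = active,
                             converged = fit$info %in% 1:4,
                             underdetermined = underdet,
                             rcond_hessian = rc, dt = dt))
}
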
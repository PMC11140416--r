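#' Fit the generalized Langevin model to a cell trajectory
#'
#' End-to-end per-cell analysis: positions are smoothed by a short running
#' mean, differentiated to half-step velocities, the VACF and MSD are
#' estimated, the effective memory kernel is extracted by discrete Volterra
#' inversion, and the parametric delta-plus-damped-oscillation kernel is
#' fitted. Two fitting routes are available:
#' \describe{
#'   \item{`"kernel"`}{(default) bounded least squares of the parametric
#'     kernel against the extracted `Gamma(t)` over the first `window`
#'     seconds ([fit_kernel()]); the mean-squared velocity B is taken as
#'     the measured Cvv(0). This is the route whose parameters feed the
#'     cluster analysis.}
#'   \item{`"vacf"`}{fit of the discretized noisy-VACF forward model to the
#'     measured VACF ([fit_noisy_vacf()]), which additionally estimates the
#'     localization-noise width and treats B as a free parameter; a
#'     validation tool for finite-sampling and noise effects.}
#' }
#'
#' @param traj a [gle_traj] (see [read_trajectory()], [simulate_embedding()]).
#' @param method `"kernel"` or `"vacf"`.
#' @param smooth_window running-mean window applied to positions before
#'   differentiation (default 2; 1 disables smoothing).
#' @param horizon kernel-extraction horizon in seconds (default 0.2).
#' @param window fit window in seconds (default 0.2, disregarding the
#'   noisy long-lag part of the data).
#' @param max_lag number of VACF/MSD lags to estimate (default: horizon
#'   plus one step).
#' @param ... further arguments passed to [fit_kernel()] or
#'   [fit_noisy_vacf()] (`n_starts`, `tau_range`, `omega_range`, ...).
#' @return An object of class `gle_fit` with components `params`
#'   (a `gle_cellparams`), `vacf`, `msd`, `kernel`, `method` and `call`;
#'   supports `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`,
#'   `plot` and `simulate`.
#' @examples
#' e <- kernel_to_embedding(kernel_params(5, 2000, 0.5, 120), B = 1000)
#' tr <- simulate_embedding(e, n_steps = 20000, dt = 0.002, seed = 7)
#' fit <- gle_fit(tr)
#' coef(fit)
#' @export
gle_fit <- function(traj, method = c("kernel", "vacf"), smooth_window = 2L,
                    horizon = 0.2, window = 0.2, max_lag = NULL, ...) {
  stopifnot(inherits(traj, "gle_traj"))
  method <- match.arg(method)
  sm <- smooth_positions(traj, smooth_window)
  vel <- velocities(sm)
  n_v <- length(vel$v$x)
  if (is.null(max_lag))
    max_lag <- as.integer(round(max(horizon, window) / traj$dt)) + 1L
  max_lag <- min(max_lag, n_v - 1L)
  cf_vacf <- vacf(vel, max_lag)
  cf_msd <- msd(sm, max_lag)
  kern <- extract_kernel(cf_vacf, horizon = horizon)
  params <- if (method == "kernel") {
    fit_kernel(kern, window = window, B = cf_vacf$values[1L],
               cell_id = traj$cell_id, ...)
  } else {
    fit_noisy_vacf(cf_vacf, window = window, cell_id = traj$cell_id, ...)
  }
  structure(list(call = match.call(), cell_id = traj$cell_id,
                 n_positions = length(traj$x), dt = traj$dt,
                 smooth_window = smooth_window, horizon = horizon,
                 window = window, method = method,
                 vacf = cf_vacf, msd = cf_msd, kernel = kern,
                 params = params),
            class = "gle_fit")
}

#' @method print gle_fit
#' @export
print.gle_fit <- function(x, ...) {
  cat(sprintf("GLE fit ('%s' route) for cell '%s' (%d positions, dt = %g s)\n",
              x$method, x$cell_id, x$n_positions, x$dt))
  print(x$params)
  invisible(x)
}

#' @export
coef.gle_fit <- function(object, ...) coef(object$params)

#' @export
vcov.gle_fit <- function(object, ...) {
  se <- object$params$fit_errors
  v <- diag(se^2, nrow = length(se))
  dimnames(v) <- list(names(se), names(se))
  v
}

#' @method summary gle_fit
#' @export
summary.gle_fit <- function(object, ...) {
  p <- object$params
  est <- coef(p)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  se[names(p$fit_errors)] <- p$fit_errors
  tab <- cbind(Estimate = est, `Std. Error` = se)
  structure(list(fit = object, coefficients = tab,
                 ssr = p$details$ssr, n_points = p$details$n_points,
                 active_bounds = p$details$active_bounds,
                 underdetermined = isTRUE(p$details$underdetermined)),
            class = "summary.gle_fit")
}

#' @method print summary.gle_fit
#' @export
print.summary.gle_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("GLE fit ('%s' route) for cell '%s'\n", f$method, f$cell_id))
  cat(sprintf("  %d positions at dt = %g s; smoothing window %d;",
              f$n_positions, f$dt, f$smooth_window))
  cat(sprintf(" fit window %g s (%d points)\n", f$window, x$n_points))
  cat("\nParameters:\n")
  stats::printCoefmat(x$coefficients, na.print = "-")
  cat(sprintf("\nResidual sum of squares: %.6g\n", x$ssr))
  if (!is.null(x$active_bounds) && any(x$active_bounds))
    cat("Active bounds:",
        paste(names(which(x$active_bounds)), collapse = ", "), "\n")
  if (x$underdetermined)
    cat("Warning: fit flagged as under-determined for this window.\n")
  invisible(x)
}

#' Model predictions from a GLE fit
#'
#' Evaluates the fitted forward model: the model VACF or MSD (solved from
#' the fitted kernel parameters and B), the fitted parametric kernel on the
#' extraction grid, or the discretized noisy VACF (finite sampling step and
#' localization noise included, available when `sigma_loc` was estimated or
#' supplied).
#'
#' @param object a `gle_fit`.
#' @param type `"vacf"`, `"msd"`, `"kernel"` or `"noisy_vacf"`.
#' @param t_max horizon (default: the lag range of the data).
#' @param dt grid step (default: the data's step).
#' @param ... unused.
#' @return A `gle_corrfun` (vacf/msd/noisy_vacf) or a numeric vector of
#'   kernel values with attribute `t` (kernel).
#' @export
predict.gle_fit <- function(object, type = c("vacf", "msd", "kernel",
                                             "noisy_vacf"),
                            t_max = NULL, dt = NULL, ...) {
  type <- match.arg(type)
  p <- object$params$kernel
  B <- object$params$B
  if (is.null(dt)) dt <- object$dt
  if (is.null(t_max)) t_max <- max(object$vacf$lags)
  switch(type,
    vacf = forward_vacf(p, B, t_max, dt),
    msd = forward_msd(p, B, t_max, dt),
    noisy_vacf = {
      s <- object$params$sigma_loc
      if (!is.finite(s)) s <- 0
      discretized_noisy_vacf(p, B, s, n_lags = as.integer(round(t_max / dt)),
                             dt = dt)
    },
    kernel = {
      t <- seq(0, t_max, by = dt)
      structure(kernel_eval(p, t, dt), t = t)
    })
}

#' @export
residuals.gle_fit <- function(object, ...) {
  p <- object$params
  if (object$method == "kernel") {
    n <- length(object$kernel$gamma)
    t <- (0:(n - 1L)) * object$dt
    keep <- t <= object$window + 1e-12
    object$kernel$gamma[keep] -
      kernel_eval(p$kernel, t[keep], object$dt)
  } else {
    n_w <- min(as.integer(round(object$window / object$dt)),
               length(object$vacf$values) - 1L)
    object$vacf$values[1:(n_w + 1L)] -
      discretized_noisy_vacf(p$kernel, p$B,
                             ifelse(is.finite(p$sigma_loc), p$sigma_loc, 0),
                             n_lags = n_w, dt = object$dt)$values
  }
}

#' Diagnostic plot of a GLE fit
#'
#' Three panels: MSD (log-log, data and model), VACF (data and model) and
#' extracted memory kernel with the parametric fit over the fit window.
#'
#' @param x a `gle_fit`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.gle_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  # MSD
  keep <- x$msd$lags > 0
  graphics::plot(x$msd$lags[keep], x$msd$values[keep], log = "xy",
                 xlab = "lag (s)", ylab = "MSD (um^2)", main = x$cell_id,
                 col = "darkorange", pch = 16, cex = 0.6, ...)
  pm <- predict(x, "msd")
  graphics::lines(pm$lags[-1], pm$values[-1], lwd = 2)
  # VACF
  graphics::plot(x$vacf$lags, x$vacf$values, xlab = "lag (s)",
                 ylab = "VACF (um^2/s^2)", main = "VACF",
                 col = "darkorange", pch = 16, cex = 0.6, ...)
  pv <- predict(x, "vacf")
  graphics::lines(pv$lags, pv$values, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  # kernel
  n <- length(x$kernel$gamma)
  t <- (seq_len(n) - 1) * x$dt
  graphics::plot(t[-1], x$kernel$gamma[-1], xlab = "t (s)",
                 ylab = "Gamma (1/s^2)", main = "memory kernel",
                 col = "darkorange", pch = 16, cex = 0.6, ...)
  fitv <- kernel_eval(x$params$kernel, t, x$dt)
  graphics::lines(t[-1], fitv[-1], lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Simulate trajectories from a fitted GLE model
#'
#' Maps the fitted kernel parameters and B to the Markovian embedding
#' (gauge m = 1) and simulates new trajectories with the exact linear-SDE
#' propagator. If the fit estimated a localization-noise width, matching
#' measurement noise is added.
#'
#' @param object a `gle_fit`.
#' @param nsim number of trajectories.
#' @param seed optional integer seed.
#' @param n_steps steps per trajectory (default: as the fitted data).
#' @param dt sampling step (default: as the fitted data).
#' @param ... unused.
#' @return A list of [gle_traj] objects.
#' @export
simulate.gle_fit <- function(object, nsim = 1, seed = NULL,
                             n_steps = NULL, dt = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_steps)) n_steps <- object$n_positions - 1L
  if (is.null(dt)) dt <- object$dt
  e <- kernel_to_embedding(object$params$kernel, B = object$params$B)
  s <- object$params$sigma_loc
  lapply(seq_len(nsim), function(i) {
    tr <- simulate_embedding(e, n_steps = n_steps, dt = dt,
                             cell_id = sprintf("%s_sim%d", object$cell_id, i))
    if (is.finite(s) && s > 0) tr <- add_localization_noise(tr, s)
    tr
  })
}
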
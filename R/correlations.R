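#' Correlation-function container
#'
#' Holds a lag-indexed estimate of the velocity autocorrelation function
#' (VACF) or the mean-squared displacement (MSD), averaged over spatial
#' components with equal weight. Only lags >= 0 are stored; both functions
#' are even in the lag.
#'
#' @param kind `"VACF"` or `"MSD"`.
#' @param lags numeric vector of time lags (seconds), starting at 0,
#'   uniformly spaced by `dt`.
#' @param values estimates (um^2/s^2 for VACF, um^2 for MSD).
#' @param counts number of averaged pairs per lag, per component.
#' @param dt sampling step (seconds).
#' @param n_components number of spatial directions averaged.
#' @return An object of class `gle_corrfun`.
#' @export
gle_corrfun <- function(kind = c("VACF", "MSD"), lags, values, counts, dt,
                        n_components = 2L) {
  kind <- match.arg(kind)
  stopifnot(length(lags) == length(values), length(counts) == length(values))
  if (abs(lags[1]) > 1e-12 * dt)
    stop("lags must start at 0", call. = FALSE)
  structure(list(kind = kind, lags = lags, values = values, counts = counts,
                 dt = dt, n_components = as.integer(n_components)),
            class = "gle_corrfun")
}

#' @method print gle_corrfun
#' @export
print.gle_corrfun <- function(x, ...) {
  cat(sprintf("%s estimate: %d lags (0 .. %.4g s, dt = %g s), %d component(s)\n",
              x$kind, length(x$lags), max(x$lags), x$dt, x$n_components))
  if (x$kind == "VACF")
    cat(sprintf("  Cvv(0) = %.6g um^2/s^2\n", x$values[1]))
  invisible(x)
}

#' @export
as.data.frame.gle_corrfun <- function(x, ...) {
  data.frame(lag_s = x$lags, value = x$values, count = x$counts)
}

#' Write / read a correlation function as delimited text
#'
#' Columns `lag_s, value, count`; metadata (kind, dt, number of components)
#' in '#'-prefixed header lines.
#'
#' @param cf a `gle_corrfun`.
#' @param path file path.
#' @return `path` invisibly ([write_corrfun()]); a `gle_corrfun`
#'   ([read_corrfun()]).
#' @export
write_corrfun <- function(cf, path) {
  stopifnot(inherits(cf, "gle_corrfun"))
  hdr <- c(sprintf("# kind: %s", cf$kind),
           sprintf("# dt: %.15g", cf$dt),
           sprintf("# n_components: %d", cf$n_components),
           "lag_s,value,count")
  body <- sprintf("%.15g,%.15g,%.15g", cf$lags, cf$values, cf$counts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_corrfun
#' @export
read_corrfun <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), meta, value = TRUE))
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  gle_corrfun(kind = get("kind"), lags = dat$lag_s, values = dat$value,
              counts = dat$count, dt = as.numeric(get("dt")),
              n_components = as.integer(get("n_components")))
}

#' Velocity autocorrelation function
#'
#' Time-averaged VACF estimator on the half-step velocity grid:
#' `Cvv_i = (1/n_pairs) * sum_j v[j+1/2] v[j+i+1/2]`, using all overlapping
#' pairs, computed per spatial component and then averaged over components
#' with equal weight (x and y are uncoupled in the model, so averaging the
#' per-component estimates is the unbiased combination).
#'
#' The zero-lag value `Cvv_0` is the pooled mean-squared velocity, i.e. the
#' estimator of B.
#'
#' @param vel a `gle_vel` object (see [velocities()]).
#' @param max_lag largest lag index (number of steps); must be smaller than
#'   the number of velocity samples.
#' @return A `gle_corrfun` of kind `"VACF"`.
#' @export
vacf <- function(vel, max_lag) {
  stopifnot(inherits(vel, "gle_vel"))
  n <- length(vel$v$x)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n || max_lag < 0L)
    stop(sprintf("parameter error: max_lag must be in [0, %d)", n),
         call. = FALSE)
  one <- function(v) {
    vapply(0:max_lag, function(i) {
      sum(v[1:(n - i)] * v[(1 + i):n]) / (n - i)
    }, numeric(1))
  }
  vals <- (one(vel$v$x) + one(vel$v$y)) / 2
  gle_corrfun("VACF", lags = (0:max_lag) * vel$dt, values = vals,
              counts = n - (0:max_lag), dt = vel$dt, n_components = 2L)
}

#' Block standard errors of a VACF estimate
#'
#' Splits each velocity component into `n_blocks` contiguous blocks,
#' estimates the VACF in each, and reports the standard error of the
#' across-block (and across-component) mean per lag. Blocks must be much
#' longer than the correlation time for the errors to be trustworthy.
#'
#' @param vel a `gle_vel`.
#' @param max_lag largest lag index.
#' @param n_blocks number of blocks per component (default 50).
#' @return A list with `se` (per-lag standard error of the mean VACF) and
#'   `n_blocks_total`.
#' @export
vacf_block_se <- function(vel, max_lag, n_blocks = 50L) {
  stopifnot(inherits(vel, "gle_vel"))
  n <- length(vel$v$x)
  bl <- floor(n / n_blocks)
  if (bl <= max_lag)
    stop("parameter error: blocks shorter than max_lag", call. = FALSE)
  est <- matrix(NA_real_, nrow = 2L * n_blocks, ncol = max_lag + 1L)
  row <- 0L
  for (comp in vel$v) {
    for (b in seq_len(n_blocks)) {
      seg <- comp[((b - 1L) * bl + 1L):(b * bl)]
      row <- row + 1L
      est[row, ] <- vapply(0:max_lag, function(i)
        sum(seg[1:(bl - i)] * seg[(1 + i):bl]) / (bl - i), numeric(1))
    }
  }
  se <- apply(est, 2L, stats::sd) / sqrt(nrow(est))
  list(se = se, n_blocks_total = nrow(est))
}

#' Mean-squared displacement
#'
#' Time-averaged MSD over all overlapping start points,
#' `MSD_i = mean_j (x[j+i] - x[j])^2`, per component, then averaged over the
#' two components. `MSD_0 = 0` by construction.
#'
#' @param traj a [gle_traj].
#' @param max_lag largest lag index; must be smaller than the number of
#'   positions.
#' @return A `gle_corrfun` of kind `"MSD"`.
#' @export
msd <- function(traj, max_lag) {
  stopifnot(inherits(traj, "gle_traj"))
  n <- length(traj$x)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n || max_lag < 0L)
    stop(sprintf("parameter error: max_lag must be in [0, %d)", n),
         call. = FALSE)
  one <- function(p) {
    vapply(0:max_lag, function(i) {
      if (i == 0L) return(0)
      d <- p[(1 + i):n] - p[1:(n - i)]
      sum(d * d) / (n - i)
    }, numeric(1))
  }
  vals <- (one(traj$x) + one(traj$y)) / 2
  gle_corrfun("MSD", lags = (0:max_lag) * traj$dt, values = vals,
              counts = n - (0:max_lag), dt = traj$dt, n_components = 2L)
}

#' Consistency residual between MSD and VACF
#'
#' The VACF is half the second time derivative of the MSD. On the discrete
#' grid this becomes the three-point stencil
#' `(MSD[i+1] - 2 MSD[i] + MSD[i-1]) / (2 dt^2)`; this function returns the
#' difference between that stencil applied to the supplied MSD and the
#' supplied VACF over the shared lag range (a data sanity check, reported,
#' not thresholded). At lag 0 the even extension `MSD[-1] = MSD[1]` is used.
#'
#' @param msd_cf a `gle_corrfun` of kind MSD.
#' @param vacf_cf a `gle_corrfun` of kind VACF with the same dt.
#' @return A list with `residuals` (per shared lag), `lags`, and `max_abs`.
#' @export
msd_vacf_consistency <- function(msd_cf, vacf_cf) {
  stopifnot(inherits(msd_cf, "gle_corrfun"), msd_cf$kind == "MSD",
            inherits(vacf_cf, "gle_corrfun"), vacf_cf$kind == "VACF")
  if (abs(msd_cf$dt - vacf_cf$dt) > 1e-9 * msd_cf$dt)
    stop("parameter error: MSD and VACF have different dt", call. = FALSE)
  m <- msd_cf$values
  n_st <- min(length(m) - 1L, length(vacf_cf$values))  # stencil needs i+1
  i <- 0:(n_st - 1L)
  m_ext <- c(m[2L], m)                                 # even extension at -dt
  stencil <- (m_ext[i + 3L] - 2 * m_ext[i + 2L] + m_ext[i + 1L]) /
    (2 * msd_cf$dt^2)
  res <- stencil - vacf_cf$values[i + 1L]
  list(lags = msd_cf$lags[i + 1L], residuals = res, max_abs = max(abs(res)))
}

#' Standardize velocity samples per cell or over the ensemble
#'
#' Pools the two velocity components of each cell and standardizes them
#' either by each cell's own mean and standard deviation (`per_cell`) or by
#' the pooled ensemble mean and standard deviation (`ensemble`). Per-cell
#' rescaling removes cell-to-cell speed variation so that a Gaussian process
#' collapses onto the standard normal; the ensemble mode retains the
#' between-cell spread (a mixture of cells with different speeds stays
#' visibly non-Gaussian there).
#'
#' @param vels a list of `gle_vel` objects.
#' @param mode `"per_cell"` or `"ensemble"`.
#' @return A list with `samples` (pooled standardized velocities),
#'   `per_cell` (data frame of cell_id, mean, sd of pooled components) and
#'   `mode`.
#' @export
rescale_velocities <- function(vels, mode = c("per_cell", "ensemble")) {
  mode <- match.arg(mode)
  stopifnot(length(vels) >= 1L)
  pooled <- lapply(vels, function(v) {
    stopifnot(inherits(v, "gle_vel"))
    c(v$v$x, v$v$y)
  })
  stats_df <- data.frame(
    cell_id = vapply(vels, function(v) v$cell_id, character(1)),
    mean = vapply(pooled, mean, numeric(1)),
    sd = vapply(pooled, stats::sd, numeric(1)))
  if (any(stats_df$sd <= 0))
    stop("degenerate-cell error: zero velocity standard deviation",
         call. = FALSE)
  samples <- if (mode == "per_cell") {
    unlist(Map(function(v, m, s) (v - m) / s,
               pooled, stats_df$mean, stats_df$sd), use.names = FALSE)
  } else {
    allv <- unlist(pooled, use.names = FALSE)
    (allv - mean(allv)) / stats::sd(allv)
  }
  list(samples = samples, per_cell = stats_df, mode = mode)
}

#' Conditional velocity distribution from the VACF
#'
#' For a stationary Gaussian process the velocity pair (v(t), v(t + lag)) is
#' bivariate normal with covariance matrix built from Cvv(0) and Cvv(lag),
#' so the conditional law of v(t + lag) given v(t) = v1 is Gaussian with
#' mean `v1 * Cvv(lag)/Cvv(0)` and variance `Cvv(0) - Cvv(lag)^2/Cvv(0)`.
#'
#' @param vacf_cf a `gle_corrfun` of kind VACF.
#' @param v1 conditioning velocity (um/s).
#' @param lag lag index (integer steps).
#' @return A list with `mean`, `variance` and `correlation`
#'   (Cvv(lag)/Cvv(0)), of class `gle_conditional`.
#' @export
conditional_velocity <- function(vacf_cf, v1, lag) {
  stopifnot(inherits(vacf_cf, "gle_corrfun"), vacf_cf$kind == "VACF")
  lag <- as.integer(lag)
  if (lag < 0L || lag >= length(vacf_cf$values))
    stop("parameter error: lag outside the stored VACF range", call. = FALSE)
  c0 <- vacf_cf$values[1L]
  cl <- vacf_cf$values[lag + 1L]
  if (c0 <= 0)
    stop("degenerate-input error: Cvv(0) must be positive", call. = FALSE)
  if (abs(cl) > c0)
    stop(paste("non-PSD covariance error: |Cvv(lag)| > Cvv(0);",
               "truncate noisy long lags before conditioning"), call. = FALSE)
  structure(list(mean = v1 * cl / c0, variance = c0 - cl^2 / c0,
                 correlation = cl / c0),
            class = "gle_conditional")
}
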
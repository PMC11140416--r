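#' Construct a cell trajectory
#'
#' A `gle_traj` holds the uniformly sampled 2-D positions of one cell.
#' Internal units are fixed: seconds for time and micrometers for positions,
#' because the kernel-fit parameter constraints (decay time, oscillation
#' frequency, localization noise) are unit-bound.
#'
#' @param x,y numeric vectors of positions (micrometers), equal length.
#' @param dt sampling time step Delta in seconds. Alternatively supply
#'   `times`, from which `dt` is inferred and checked for uniformity.
#' @param times optional numeric vector of time points (seconds).
#' @param cell_id character identifier of the cell.
#' @param min_length minimum number of positions accepted (default 500, the
#'   shortest record for which correlation estimates over a 0.2 s window are
#'   meaningful at 2 ms sampling). Set to 0 to disable.
#' @param meta optional named list of provenance metadata (smoothing window,
#'   source file, ...).
#'
#' @return An object of class `gle_traj`: a list with elements `cell_id`,
#'   `times`, `x`, `y`, `dt` and `meta`.
#' @export
gle_traj <- function(x, y, dt = NULL, times = NULL, cell_id = "cell",
                     min_length = 500L, meta = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  n <- length(x)
  if (is.null(times)) {
    if (is.null(dt) || !is.finite(dt) || dt <= 0)
      stop("either `times` or a positive `dt` must be supplied", call. = FALSE)
    times <- seq(0, by = dt, length.out = n)
  } else {
    times <- as.numeric(times)
    if (length(times) != n)
      stop("times, x and y must have identical length", call. = FALSE)
    if (anyNA(times))
      stop("gap error: missing values in the time column", call. = FALSE)
    if (n < 2L)
      stop("length error: at least two time points required", call. = FALSE)
    steps <- diff(times)
    dt_inf <- stats::median(steps)
    if (dt_inf <= 0 || any(steps <= 0))
      stop("sampling error: time points must be strictly increasing",
           call. = FALSE)
    if (max(abs(steps - dt_inf)) / dt_inf >= 1e-6)
      stop(sprintf(
        "sampling error: non-uniform time step (max relative deviation %.3g)",
        max(abs(steps - dt_inf)) / dt_inf), call. = FALSE)
    if (!is.null(dt) && abs(dt - dt_inf) / dt_inf >= 1e-6)
      stop("sampling error: supplied dt disagrees with the time column",
           call. = FALSE)
    dt <- dt_inf
  }
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("gap error: missing or non-finite positions (gaps are not interpolated)",
         call. = FALSE)
  if (n < max(2L, min_length))
    stop(sprintf("length error: trajectory has %d points, minimum is %d",
                 n, max(2L, min_length)), call. = FALSE)
  structure(list(cell_id = as.character(cell_id), times = times,
                 x = x, y = y, dt = dt, meta = meta),
            class = "gle_traj")
}

#' @method print gle_traj
#' @export
print.gle_traj <- function(x, ...) {
  cat(sprintf("Cell trajectory '%s': %d positions, dt = %g s, duration %.3g s\n",
              x$cell_id, length(x$x), x$dt, x$times[length(x$times)] - x$times[1]))
  if (!is.null(x$meta$smoothing_window))
    cat(sprintf("  smoothed: running mean over %d positions\n",
                x$meta$smoothing_window))
  invisible(x)
}

#' @export
length.gle_traj <- function(x) length(x$x)

#' Read a trajectory from a delimited text file
#'
#' Reads one cell's 2-D trajectory from a CSV/TSV file with a header row,
#' converts to canonical units (seconds, micrometers), infers the sampling
#' step from the time column and validates uniform sampling.
#'
#' Gaps (missing values) and non-uniform sampling are hard errors: the
#' downstream correlation and Volterra machinery assumes a strictly uniform
#' time grid, and silent interpolation would bias the extracted kernel.
#'
#' @param path path to a delimited text file.
#' @param column_map named character vector mapping the roles `time`, `x`,
#'   `y` to column names in the file.
#' @param units named list with multiplicative factors `time` and `pos`
#'   converting file units into seconds and micrometers (default 1, 1).
#' @param min_length minimum accepted number of rows (default 500).
#' @param cell_id identifier; default the file name without extension.
#' @param sep field separator; `"auto"` lets the reader sniff it.
#'
#' @return A [gle_traj] object.
#' @export
read_trajectory <- function(path,
                            column_map = c(time = "time", x = "x", y = "y"),
                            units = list(time = 1, pos = 1),
                            min_length = 500L,
                            cell_id = NULL,
                            sep = "auto") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- data.table::fread(path, sep = sep, header = TRUE,
                           na.strings = c("NA", ""), data.table = FALSE)
  need <- unname(column_map[c("time", "x", "y")])
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop(sprintf("declared columns not present in file: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  tcol <- suppressWarnings(as.numeric(dat[[column_map[["time"]]]]))
  xcol <- suppressWarnings(as.numeric(dat[[column_map[["x"]]]]))
  ycol <- suppressWarnings(as.numeric(dat[[column_map[["y"]]]]))
  if (anyNA(tcol) || anyNA(xcol) || anyNA(ycol))
    stop("gap error: missing or non-numeric entries in trajectory file",
         call. = FALSE)
  gle_traj(x = xcol * units$pos, y = ycol * units$pos,
           times = tcol * units$time, cell_id = cell_id,
           min_length = min_length,
           meta = list(source = path, units = units))
}

#' Write a trajectory (and a provenance sidecar) to delimited text
#'
#' Writes `time,x,y` in canonical units with a fixed print precision so that
#' a read/write/read cycle round-trips exactly, plus a YAML sidecar
#' (`<path>.meta.yaml`) recording cell id, dt, and any provenance metadata
#' such as the smoothing window.
#'
#' @param traj a [gle_traj].
#' @param path output file path.
#' @param digits significant digits used when printing (default 15, enough
#'   for exact round trips of doubles written in decimal).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 15) {
  stopifnot(inherits(traj, "gle_traj"))
  df <- data.frame(time = signif(traj$times, digits),
                   x = signif(traj$x, digits),
                   y = signif(traj$y, digits))
  data.table::fwrite(df, path)
  side <- c(list(cell_id = traj$cell_id, dt = traj$dt,
                 n_points = length(traj$x),
                 units = list(time = "s", position = "um")),
            traj$meta)
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Smooth positions by a running mean
#'
#' Averages `window` consecutive positions to reduce localization noise
#' before differentiation. With window w the output has `N + 2 - w` positions
#' (w = 1 is the identity); the time stamp assigned to each averaged position
#' is the mean of the contributing time stamps, so the sampling step is
#' unchanged. For i.i.d. localization noise of variance sigma^2 the smoothed
#' noise variance is sigma^2 / w.
#'
#' @param traj a [gle_traj].
#' @param window integer >= 1, number of consecutive positions averaged.
#'   Default 2, the smallest nontrivial window.
#' @return A smoothed [gle_traj] with the window recorded in `meta`.
#' @export
smooth_positions <- function(traj, window = 2L) {
  stopifnot(inherits(traj, "gle_traj"))
  window <- as.integer(window)
  n <- length(traj$x)
  if (is.na(window) || window < 1L || window >= n)
    stop(sprintf("parameter error: window must be in [1, %d)", n),
         call. = FALSE)
  if (window == 1L) {
    out <- traj
    out$meta$smoothing_window <- 1L
    return(out)
  }
  runmean <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(window + 1):(n + 1)] - cs[1:(n + 1 - window)]) / window
  }
  meta <- traj$meta
  meta$smoothing_window <- window
  # time stamp of the averaged position is the center of its window; built
  # from the original grid (not a running mean) to avoid rounding drift
  times_new <- traj$times[1:(n + 1L - window)] + (window - 1L) / 2 * traj$dt
  gle_traj(x = runmean(traj$x), y = runmean(traj$y),
           times = times_new, cell_id = traj$cell_id,
           min_length = 0L, meta = meta)
}

#' Velocities at half time steps
#'
#' Differentiates positions by the forward difference
#' `v[i + 1/2] = (x[i + 1] - x[i]) / dt`, per spatial component. Positions
#' are indexed 0..N; the N velocities live on the half-step grid
#' (i + 1/2) dt.
#'
#' @param traj a [gle_traj].
#' @return An object of class `gle_vel`: list with `cell_id`, `v` (a list
#'   with numeric components `x` and `y`, each of length N) and `dt`.
#' @export
velocities <- function(traj) {
  stopifnot(inherits(traj, "gle_traj"))
  v <- list(x = diff(traj$x) / traj$dt, y = diff(traj$y) / traj$dt)
  structure(list(cell_id = traj$cell_id, v = v, dt = traj$dt),
            class = "gle_vel")
}

#' @method print gle_vel
#' @export
print.gle_vel <- function(x, ...) {
  cat(sprintf("Velocity series '%s': %d half-step samples per component, dt = %g s\n",
              x$cell_id, length(x$v$x), x$dt))
  invisible(x)
}

#' Integrate a velocity series back to positions
#'
#' Inverse of [velocities()] given the starting position: cumulative sum of
#' `v * dt`. Mainly a consistency tool for tests and diagnostics.
#'
#' @param vel a `gle_vel` object.
#' @param x0,y0 starting positions (micrometers).
#' @param cell_id optional identifier override.
#' @return A [gle_traj].
#' @export
integrate_velocities <- function(vel, x0 = 0, y0 = 0, cell_id = vel$cell_id) {
  stopifnot(inherits(vel, "gle_vel"))
  gle_traj(x = x0 + c(0, cumsum(vel$v$x * vel$dt)),
           y = y0 + c(0, cumsum(vel$v$y * vel$dt)),
           dt = vel$dt, cell_id = cell_id, min_length = 0L)
}
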
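#' Rescale features by their medians
#'
#' Divides every feature (column) by the median of its distribution, the
#' scale-equalization used before clustering cell parameters that live on
#' very different numeric scales. The medians are recorded in the
#' `"medians"` attribute for inversion; rescaling twice is idempotent
#' because the median of a median-rescaled feature is 1.
#'
#' @param x numeric matrix (cells in rows, features in columns) or data
#'   frame of numeric columns.
#' @return The rescaled matrix with attribute `medians`.
#' @export
median_rescale <- function(x) {
  x <- as.matrix(x)
  med <- apply(x, 2L, stats::median)
  if (any(med == 0))
    stop("scaling error: zero median for feature(s) ",
         paste(colnames(x)[med == 0], collapse = ", "), call. = FALSE)
  out <- sweep(x, 2L, med, "/")
  attr(out, "medians") <- med
  out
}

#' Lloyd's k-means with explicit deterministic initialization
#'
#' Plain Lloyd iterations on the Euclidean metric: assign each point to the
#' nearest center, recompute centers as cluster means, stop when the
#' assignment no longer changes (or the center shift falls below `tol`).
#' Entirely deterministic given the initial centers, which is what the
#' all-pairs consensus protocol requires. If a cluster empties during the
#' iteration its center is re-seeded at the point currently farthest from
#' its assigned center.
#'
#' @param x numeric matrix, points in rows.
#' @param centers k x d matrix of initial centers (rows may be data points).
#' @param max_iter iteration cap (default 100).
#' @param tol center-shift convergence tolerance.
#' @return A list with `labels` (1..k), `centers`, `inertia` (total
#'   within-cluster sum of squared distances), `iterations`, `converged`.
#' @export
kmeans_lloyd <- function(x, centers, max_iter = 100L, tol = 1e-10) {
  x <- as.matrix(x)
  centers <- matrix(as.numeric(centers), ncol = ncol(x))
  k <- nrow(centers)
  n <- nrow(x)
  if (k > n) stop("parameter error: more centers than points", call. = FALSE)
  xsq <- rowSums(x^2)
  dist2 <- function(C) {
    # n x k matrix of squared Euclidean distances
    d2 <- outer(xsq, rowSums(C^2), "+") - 2 * x %*% t(C)
    pmax(d2, 0)
  }
  labels <- integer(n)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    d2 <- dist2(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    own <- d2[cbind(seq_len(n), new_labels)]
    # re-seed empty clusters at the farthest point from its current center
    for (c_empty in setdiff(seq_len(k), unique(new_labels))) {
      far <- which.max(own)
      centers[c_empty, ] <- x[far, ]
      new_labels[far] <- c_empty
      own[far] <- 0
    }
    new_centers <- centers
    for (c_i in seq_len(k))
      new_centers[c_i, ] <- colMeans(x[new_labels == c_i, , drop = FALSE])
    shift <- max(abs(new_centers - centers))
    no_change <- all(new_labels == labels) && it > 1L
    labels <- new_labels
    centers <- new_centers
    if (no_change || shift < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  d2 <- dist2(centers)
  list(labels = labels, centers = centers,
       inertia = sum(d2[cbind(seq_len(n), labels)]),
       iterations = it, converged = converged)
}

# --- split-acceptance criteria ---------------------------------------------

cluster_rss <- function(x, labels, centers) {
  rss <- 0
  for (c_i in seq_len(nrow(centers))) {
    pts <- x[labels == c_i, , drop = FALSE]
    rss <- rss + sum(sweep(pts, 2L, centers[c_i, ])^2)
  }
  rss
}

# Two-part description length of a clustering of `n` points in `d`
# dimensions: Gaussian code length for the residuals, plus the cost of the
# model parameters (d center coordinates and one variance per cluster,
# (1/2) log(nd) nats per scalar) plus an equal selection cost for the
# data-optimized choice of split geometry -- the cluster boundary is picked
# to maximize the apparent gain, so its description must be paid for at the
# same precision -- plus, for k > 1, the per-point cluster assignments at
# their empirical entropy.  Lower is better.
dl_score <- function(rss, n, d, sizes) {
  k <- length(sizes)
  data_bits <- (n * d / 2) * log(max(rss, 1e-300) / (n * d))
  param_bits <- k * (d + 1) * log(n * d)
  assign_bits <- if (k > 1L) sum(sizes * log(n / sizes)) else 0
  data_bits + param_bits + assign_bits
}

# Bayesian information criterion of a spherical Gaussian mixture fitted by
# k-means (identical covariance across clusters).  Higher is better.
bic_score <- function(rss, n, d, sizes) {
  k <- length(sizes)
  if (n <= k) return(-Inf)
  sig2 <- max(rss / (d * (n - k)), 1e-300)
  ll <- sum(sizes * log(sizes / n)) -
    (n * d / 2) * log(2 * pi * sig2) - d * (n - k) / 2
  n_par <- (k - 1) + k * d + 1
  ll - n_par / 2 * log(n)
}

# Should a cluster (points `pts`, center `ctr`) be split into the two
# sub-clusters `sub` (a kmeans_lloyd result on pts)?  Local comparison of
# the chosen criterion on the cluster's own points.
split_improves <- function(pts, ctr, sub, criterion) {
  n <- nrow(pts)
  d <- ncol(pts)
  rss1 <- sum(sweep(pts, 2L, ctr)^2)
  rss2 <- cluster_rss(pts, sub$labels, sub$centers)
  sizes2 <- tabulate(sub$labels, nbins = 2L)
  # a (near-)singleton child is an overfitting signature, never a split
  if (any(sizes2 < 2L)) return(list(accept = FALSE, parent = NA, child = NA))
  if (criterion == "bic") {
    parent <- bic_score(rss1, n, d, n)
    child <- bic_score(rss2, n, d, sizes2)
    list(accept = child > parent, parent = parent, child = child)
  } else {
    parent <- dl_score(rss1, n, d, n)
    child <- dl_score(rss2, n, d, sizes2)
    list(accept = child < parent, parent = parent, child = child)
  }
}

# Deterministic child initialization: the two cluster members farthest
# apart from each other.
farthest_pair <- function(pts) {
  d2 <- as.matrix(stats::dist(pts))^2
  idx <- arrayInd(which.max(d2), dim(d2))
  pts[as.vector(idx), , drop = FALSE]
}

#' X-means: k-means with data-driven choice of the number of clusters
#'
#' Starts from `k_min` clusters at the supplied initial centers, runs Lloyd
#' k-means, then repeatedly tries to split every cluster into two
#' sub-clusters (child k-means initialized at the two members farthest
#' apart). A split is accepted only if it improves a model-selection score
#' that accounts for the added parameters: either a two-part
#' description-length criterion (`"mdl"`, default; lower is better) or the
#' spherical-Gaussian BIC (`"bic"`; higher is better). After each round of
#' accepted splits the full configuration is polished by global k-means.
#' Stops when no split is accepted or `k_max` is reached.
#'
#' @param x numeric matrix, points in rows (typically median-rescaled).
#' @param init_centers `k_min` x d matrix of initial centers; for the
#'   consensus protocol these are two individual cells' parameter vectors.
#' @param k_min,k_max allowed range of cluster numbers (defaults 2 and 20).
#' @param criterion `"mdl"` or `"bic"`.
#' @return As [kmeans_lloyd()], plus `k` and `criterion_trace` (a data
#'   frame of attempted splits with parent/child scores and decisions).
#' @export
xmeans <- function(x, init_centers, k_min = 2L, k_max = 20L,
                   criterion = c("mdl", "bic")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (k_min < 2L) stop("parameter error: k_min must be >= 2", call. = FALSE)
  if (k_max > nrow(x))
    stop("parameter error: k_max cannot exceed the number of points",
         call. = FALSE)
  init_centers <- matrix(as.numeric(init_centers), ncol = ncol(x))
  if (nrow(init_centers) != k_min)
    stop("parameter error: init_centers must have k_min rows", call. = FALSE)
  fit <- kmeans_lloyd(x, init_centers)
  trace <- list()
  repeat {
    k <- nrow(fit$centers)
    new_centers <- NULL
    n_accepted <- 0L
    for (c_i in seq_len(k)) {
      pts <- x[fit$labels == c_i, , drop = FALSE]
      accepted <- FALSE
      if (nrow(pts) >= 5L && k + n_accepted + 1L <= k_max &&
          nrow(unique(pts)) >= 2L) {
        sub <- kmeans_lloyd(pts, farthest_pair(pts))
        dec <- split_improves(pts, fit$centers[c_i, ], sub, criterion)
        trace[[length(trace) + 1L]] <-
          data.frame(k_before = k, cluster = c_i, size = nrow(pts),
                     parent_score = dec$parent, child_score = dec$child,
                     accepted = dec$accept)
        if (isTRUE(dec$accept)) {
          new_centers <- rbind(new_centers, sub$centers)
          n_accepted <- n_accepted + 1L
          accepted <- TRUE
        }
      }
      if (!accepted)
        new_centers <- rbind(new_centers, fit$centers[c_i, , drop = FALSE])
    }
    if (n_accepted == 0L) break
    fit <- kmeans_lloyd(x, new_centers)
  }
  fit$k <- nrow(fit$centers)
  fit$criterion <- criterion
  fit$criterion_trace <- if (length(trace)) do.call(rbind, trace) else NULL
  fit
}

#' Canonical form of a partition
#'
#' Relabels cluster labels by order of first occurrence, making partition
#' equality invariant under label permutation.
#'
#' @param labels integer vector of cluster labels.
#' @return Integer labels in 1..k, first occurrences in increasing order.
#' @export
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

#' All-pairs consensus clustering
#'
#' Runs X-means once for every unordered pair of distinct cells used as the
#' two initial cluster centers (n(n-1)/2 runs) and returns the partition
#' that occurs most often, in canonical (permutation-invariant) form,
#' together with its support fraction. X-means can converge to different
#' partitions depending on initialization; the modal partition over all
#' pair initializations is the protocol's stabilized answer. The procedure
#' contains no hidden randomness: results depend only on the feature table.
#' Ties between modal partitions are broken by the lexicographically
#' smallest canonical labeling and flagged.
#'
#' @param x numeric matrix of (rescaled) features, cells in rows; at least
#'   3 cells.
#' @param k_min,k_max,criterion passed to [xmeans()].
#' @return A list of class `gle_consensus`: `labels` (modal canonical
#'   partition), `k`, `support` (fraction of runs yielding it), `n_runs`,
#'   `tie` (logical), `partition_counts` (named counts of all observed
#'   partitions).
#' @export
allpairs_consensus <- function(x, k_min = 2L, k_max = 20L,
                               criterion = c("mdl", "bic")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L)
    stop("parameter error: consensus needs at least 3 cells", call. = FALSE)
  k_max <- min(k_max, n)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  n_runs <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      fit <- xmeans(x, init_centers = x[c(i, j), , drop = FALSE],
                    k_min = k_min, k_max = k_max, criterion = criterion)
      key <- paste(canonical_labels(fit$labels), collapse = ",")
      counts[[key]] <- if (is.null(counts[[key]])) 1L else counts[[key]] + 1L
      n_runs <- n_runs + 1L
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  top <- max(cnt)
  modal_keys <- sort(keys[cnt == top])     # lexicographic tie-break
  labels <- as.integer(strsplit(modal_keys[1L], ",")[[1L]])
  structure(list(labels = labels, k = length(unique(labels)),
                 support = top / n_runs, n_runs = n_runs,
                 tie = sum(cnt == top) > 1L,
                 partition_counts = stats::setNames(cnt, keys)),
            class = "gle_consensus")
}

#' @method print gle_consensus
#' @export
print.gle_consensus <- function(x, ...) {
  cat(sprintf(
    "Consensus clustering: k = %d, support %.3f (%d/%d pair initializations)%s\n",
    x$k, x$support, round(x$support * x$n_runs), x$n_runs,
    if (x$tie) " [modal tie, lexicographic tie-break]" else ""))
  invisible(x)
}

# All permutations of 1..n (n <= 8 in practice: k clusters).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Classification accuracy against ground truth
#'
#' Best agreement between predicted cluster labels and true class labels
#' over all mappings of predicted to true labels (exhaustive over label
#' permutations for up to 8 labels, greedy confusion-matrix matching
#' beyond).
#'
#' @param labels predicted integer labels.
#' @param truth true labels (any type; coerced to factor).
#' @return Accuracy in \[0, 1\].
#' @export
label_accuracy <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  pred <- canonical_labels(as.integer(factor(labels)))
  tr <- as.integer(factor(truth))
  kk <- max(max(pred), max(tr))
  if (kk <= 8L) {
    perms <- permutations(kk)
    best <- 0
    for (r in seq_len(nrow(perms))) {
      acc <- mean(perms[r, ][pred] == tr)
      if (acc > best) best <- acc
    }
    best
  } else {
    conf <- table(pred, tr)
    sum(apply(conf, 1L, max)) / length(pred)
  }
}

#' Classify cells by consensus X-means on their fitted parameters
#'
#' Builds the feature table from a chosen subset of the per-cell parameters
#' (default all five: a, b, tau, omega, B), rescales each feature by its
#' median, and runs the all-pairs consensus X-means protocol. When ground
#' truth is supplied the best-permutation accuracy is reported.
#'
#' @param params a data frame with a `cell_id` column and numeric parameter
#'   columns, or a list of `gle_cellparams` / `gle_fit` objects.
#' @param features character vector of feature columns (default
#'   `c("a","b","tau","omega","B")`; alternatives: `"B"` alone or the four
#'   kernel parameters).
#' @param truth optional vector of true class labels, aligned with the
#'   cells (or a data frame with `cell_id` and `population` columns).
#' @param k_min,k_max,criterion passed to [allpairs_consensus()].
#' @return An object of class `gle_classify`: the consensus result plus
#'   `cell_ids`, `features`, `scaling` (feature medians) and `accuracy`
#'   (NA without ground truth).
#' @export
classify_cells <- function(params, features = c("a", "b", "tau", "omega", "B"),
                           truth = NULL, k_min = 2L, k_max = 20L,
                           criterion = c("mdl", "bic")) {
  criterion <- match.arg(criterion)
  df <- as_cellparams_table(params)
  if (nrow(df) < 3L)
    stop("parameter error: need at least 3 cells with complete parameters",
         call. = FALSE)
  missing_f <- setdiff(features, names(df))
  if (length(missing_f))
    stop("features not present: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  feat <- as.matrix(df[, features, drop = FALSE])
  if (anyNA(feat))
    stop("parameter error: missing values in the feature table",
         call. = FALSE)
  scaled <- median_rescale(feat)
  cons <- allpairs_consensus(scaled, k_min = k_min, k_max = k_max,
                             criterion = criterion)
  acc <- NA_real_
  if (!is.null(truth)) {
    if (is.data.frame(truth))
      truth <- truth$population[match(df$cell_id, truth$cell_id)]
    acc <- label_accuracy(cons$labels, truth)
  }
  structure(c(cons, list(cell_ids = df$cell_id, features = features,
                         scaling = attr(scaled, "medians"),
                         accuracy = acc)),
            class = c("gle_classify", "gle_consensus"))
}

#' @method print gle_classify
#' @export
print.gle_classify <- function(x, ...) {
  cat(sprintf("Cell classification on features (%s):\n",
              paste(x$features, collapse = ", ")))
  cat(sprintf("  k = %d clusters, support %.3f over %d consensus runs\n",
              x$k, x$support, x$n_runs))
  sizes <- table(x$labels)
  cat(sprintf("  cluster sizes: %s\n",
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  if (is.finite(x$accuracy))
    cat(sprintf("  accuracy vs ground truth: %.3f\n", x$accuracy))
  invisible(x)
}

# Coerce supported inputs to a per-cell parameter data frame.
as_cellparams_table <- function(params) {
  if (is.data.frame(params)) return(params)
  if (is.list(params)) {
    rows <- lapply(params, function(p) {
      if (inherits(p, "gle_fit")) p <- p$params
      stopifnot(inherits(p, "gle_cellparams"))
      k <- p$kernel
      data.frame(cell_id = p$cell_id, a = k$a, b = k$b, tau = k$tau,
                 omega = k$omega, B = p$B, sigma_loc = p$sigma_loc)
    })
    return(do.call(rbind, rows))
  }
  stop("cannot interpret `params` as a cell-parameter table", call. = FALSE)
}

#' Write a cell-parameter table to delimited text
#'
#' One row per cell: parameters, fit standard errors (`se_` columns) and
#' active-bound flags.
#'
#' @param params list of `gle_cellparams` or `gle_fit` objects.
#' @param path file path.
#' @return The assembled data frame, invisibly.
#' @export
write_cellparams <- function(params, path) {
  rows <- lapply(params, function(p) {
    if (inherits(p, "gle_fit")) p <- p$params
    k <- p$kernel
    se <- p$fit_errors
    ab <- p$details$active_bounds
    data.frame(cell_id = p$cell_id, a = k$a, b = k$b, tau = k$tau,
               omega = k$omega, B = p$B, sigma_loc = p$sigma_loc,
               se_a = se[["a"]], se_b = se[["b"]], se_tau = se[["tau"]],
               se_omega = se[["omega"]],
               se_B = if ("B" %in% names(se)) se[["B"]] else NA_real_,
               se_sigma_loc = if ("sigma_loc" %in% names(se))
                 se[["sigma_loc"]] else NA_real_,
               active_bounds = if (is.null(ab)) "" else
                 paste(names(which(ab)), collapse = ";"))
  })
  df <- do.call(rbind, rows)
  data.table::fwrite(df, path)
  invisible(df)
}
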
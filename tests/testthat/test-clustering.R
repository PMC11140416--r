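test_that("median rescaling divides by medians, is idempotent, and errors on zero medians", {
  X <- cbind(f1 = c(1, 2, 3), f2 = c(4, 4, 4))
  s <- median_rescale(X)
  expect_equal(unname(s[, 1]), c(0.5, 1, 1.5))
  expect_equal(unname(s[, 2]), c(1, 1, 1))
  expect_equal(attr(s, "medians"), c(f1 = 2, f2 = 4))
  s2 <- median_rescale(s)
  expect_equal(as.numeric(s2), as.numeric(s))
  expect_error(median_rescale(cbind(a = c(-1, 0, 1))), "scaling error")
})

test_that("Lloyd k-means is deterministic, monotone and agrees with the stats oracle", {
  # two points, two clusters
  X <- rbind(c(0, 0), c(5, 5))
  km <- kmeans_lloyd(X, X)
  expect_equal(sort(km$labels), c(1, 2))
  expect_equal(km$inertia, 0)

  # long rectangle, one init on each short side: converges to the split
  # that pairs each short side's corners.  Enumerating both 2+2
  # partitions: pairing the short sides costs inertia 1, pairing the long
  # sides costs 100, so Lloyd keeps the cheap one.
  rect <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  km_r <- kmeans_lloyd(rect, rbind(c(0, 0.5), c(10, 0.5)))
  expect_equal(canonical_labels(km_r$labels), c(1, 1, 2, 2))
  expect_equal(km_r$inertia, 1)
  inertia_of <- function(groups) sum(vapply(groups, function(g)
    sum(sweep(rect[g, , drop = FALSE], 2,
              colMeans(rect[g, , drop = FALSE]))^2), numeric(1)))
  expect_equal(inertia_of(list(1:2, 3:4)), 1)
  expect_equal(inertia_of(list(c(1, 3), c(2, 4))), 100)

  # well-separated blobs: perfect labels, inertia equal to stats::kmeans
  set.seed(11)
  blobs <- rbind(cbind(rnorm(50), rnorm(50)), cbind(rnorm(50, 6), rnorm(50, 6)))
  km_b <- kmeans_lloyd(blobs, blobs[c(1, 60), ])
  expect_equal(label_accuracy(km_b$labels, rep(1:2, each = 50)), 1)
  ref <- stats::kmeans(blobs, centers = blobs[c(1, 60), ],
                       algorithm = "Lloyd")
  expect_equal(km_b$inertia, ref$tot.withinss, tolerance = 1e-9)

  expect_error(kmeans_lloyd(X, rbind(X, c(1, 1))), "more centers")
})

test_that("x-means chooses the number of clusters by the split criterion", {
  blob <- function(n, mx, my) cbind(rnorm(n, mx), rnorm(n, my))

  # single Gaussian blob: stays at k_min in the large majority of draws
  ks <- vapply(1:20, function(s) {
    set.seed(s)
    X <- blob(60, 0, 0)
    xmeans(X, X[1:2, ])$k
  }, numeric(1))
  expect_gte(mean(ks == 2), 0.75)

  # two well-separated blobs: k = 2 with exact labels
  set.seed(2)
  X2 <- rbind(blob(25, 0, 0), blob(25, 8, 8))
  xm2 <- xmeans(X2, X2[c(1, 2), ])
  expect_equal(xm2$k, 2L)
  expect_equal(label_accuracy(xm2$labels, rep(1:2, each = 25)), 1)

  # four well-separated blobs: two rounds of accepted splits
  set.seed(1)
  X4 <- rbind(blob(30, 0, 0), blob(30, 8, 8), blob(30, 0, 16),
              blob(30, 16, 0))
  xm4 <- xmeans(X4, X4[c(1, 40), ])
  expect_equal(xm4$k, 4L)
  expect_equal(label_accuracy(xm4$labels, rep(1:4, each = 30)), 1)
  expect_true(any(xm4$criterion_trace$accepted))

  # the BIC variant is available and also separates clean blobs
  expect_equal(xmeans(X2, X2[c(1, 2), ], criterion = "bic")$k, 2L)

  expect_error(xmeans(X2, X2[1:2, ], k_max = 1000), "parameter error")
  expect_error(xmeans(X2, X2[1:3, ]), "k_min rows")
})

test_that("partition canonicalization is invariant under label permutation", {
  set.seed(7)
  for (i in 1:20) {
    lab <- sample(1:4, 30, replace = TRUE)
    perm <- sample(4)
    expect_identical(canonical_labels(lab), canonical_labels(perm[lab]))
  }
  expect_identical(canonical_labels(c(3, 3, 1, 3, 2)), c(1L, 1L, 2L, 1L, 3L))
})

test_that("all-pairs consensus runs n(n-1)/2 deterministic initializations", {
  set.seed(13)
  X <- rbind(cbind(rnorm(10), rnorm(10)), cbind(rnorm(10, 7), rnorm(10, 7)))
  cc1 <- allpairs_consensus(X)
  cc2 <- allpairs_consensus(X)
  expect_identical(cc1$labels, cc2$labels)       # no hidden RNG
  expect_equal(cc1$n_runs, 20 * 19 / 2)
  expect_equal(cc1$k, 2L)
  expect_equal(cc1$support, 1)
  expect_equal(label_accuracy(cc1$labels, rep(1:2, each = 10)), 1)

  # n = 3: exactly 3 runs
  X3 <- rbind(c(0, 0), c(0.1, 0), c(9, 9))
  expect_equal(allpairs_consensus(X3)$n_runs, 3L)
  expect_error(allpairs_consensus(X3[1:2, ]), "at least 3")
})

test_that("label accuracy maximizes agreement over label permutations", {
  expect_equal(label_accuracy(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(label_accuracy(c(2, 2, 1, 1), c(1, 1, 2, 2)), 1)
  expect_equal(label_accuracy(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0.75)
  # more predicted clusters than truth classes: best injective mapping
  expect_equal(label_accuracy(c(1, 2, 3, 3), c(1, 1, 2, 2)), 0.75)
})

test_that("cell classification separates synthetic populations and ranks feature sets", {
  co <- param_cohort(seed = 1)
  df <- data.frame(cell_id = sprintf("c%02d", 1:40), co$raw)
  cls <- classify_cells(df, truth = co$truth)
  expect_s3_class(cls, "gle_classify")
  expect_equal(cls$k, 2L)
  expect_equal(cls$accuracy, 1)
  expect_equal(cls$support, 1)
  expect_equal(cls$n_runs, 780L)

  # B-only clustering on a cohort whose B distributions overlap is
  # strictly worse than the five-parameter clustering
  co2 <- param_cohort(seed = 2, shift = c(0.7, 0.7, -0.7, -0.7, -0.25))
  df2 <- data.frame(cell_id = sprintf("c%02d", 1:40), co2$raw)
  cls5 <- classify_cells(df2, truth = co2$truth)
  clsB <- classify_cells(df2, features = "B", truth = co2$truth)
  clsK <- classify_cells(df2, features = c("a", "b", "tau", "omega"),
                         truth = co2$truth)
  expect_lt(clsB$accuracy, cls5$accuracy)
  expect_gte(clsK$accuracy, clsB$accuracy)
  expect_lte(clsK$accuracy, cls5$accuracy)

  expect_error(classify_cells(df[1:2, ]), "at least 3")
  expect_error(classify_cells(df, features = "nope"), "not present")
})
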
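fake_descriptors <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stats::setNames(abs(rnorm(9, mean = 10)), descriptor_names())
  })
}

test_that("feature assembly yields descriptors plus site indicators", {
  pats <- enumerate_patterns(four_sites())
  m <- assemble_features(fake_descriptors(16), pats)
  expect_equal(dim(m), c(16L, 13L))
  expect_equal(colnames(m),
               c(descriptor_names(), "A.45", "A.59", "B.45", "B.59"))
  # unmodified system: all indicators 0; fully modified: all 1
  expect_equal(unname(m["noP", 10:13]), rep(0, 4))
  expect_equal(unname(m["A.45-A.59-B.45-B.59", 10:13]), rep(1, 4))
  expect_equal(attr(m, "indicator_cols"), 10:13)

  one <- assemble_features(fake_descriptors(1),
                           list(ptm_pattern(list(c("A", 45)), 1)))
  expect_equal(dim(one), c(1L, 10L))

  bad <- enumerate_patterns(list(c("A", 1)))[1]
  expect_no_error(assemble_features(fake_descriptors(1), bad))
  expect_error(
    assemble_features(fake_descriptors(2),
                      c(bad, enumerate_patterns(list(c("B", 2)))[1])),
    "inconsistent site lists")
})

test_that("multimer aggregation is the element-wise mean", {
  v <- function(x) stats::setNames(rep(x, 9), descriptor_names())
  expect_equal(unname(aggregate_hexamer(list(v(1), v(2), v(3)))["total_sas"]),
               2)
  single <- fake_descriptors(1)[[1]]
  expect_equal(aggregate_hexamer(list(single)), single)
  trio <- fake_descriptors(3, seed = 9)
  expect_equal(aggregate_hexamer(trio),
               colMeans(do.call(rbind, trio)))
  expect_error(aggregate_hexamer(list()), "no member")
})

test_that("pairwise normalization divides by the pair mean", {
  m <- rbind(a = c(4, 10, 7), b = c(6, 10, 7))
  colnames(m) <- c("v1", "v2", "v3")
  out <- pairwise_normalize(m, rbind(c(1, 2)))
  expect_equal(unname(out[, "v1"]), c(0.8, 1.2))
  expect_equal(unname(out[, "v2"]), c(1, 1))       # equal pair -> identity
  # algebraic identities: pairs sum to 2, within-pair ratios preserved
  expect_equal(unname(colSums(out)), rep(2, 3))
  expect_equal(out["a", ] / out["b", ], m["a", ] / m["b", ])

  mz <- rbind(a = c(1, 0), b = c(3, 0))
  expect_warning(oz <- pairwise_normalize(mz, rbind(c(1, 2))), "mean is 0")
  expect_equal(unname(oz[, 2]), c(1, 1))

  # indicator columns of a feature matrix are exempt
  pats <- enumerate_patterns(list(c("A", 1)))
  fm <- assemble_features(fake_descriptors(2), pats)
  fn <- pairwise_normalize(fm, rbind(c(1, 2)))
  expect_equal(unname(fn[, 10]), unname(fm[, 10]))
  expect_equal(unname(colSums(fn[, 1:9])), rep(2, 9))

  expect_error(pairwise_normalize(m, rbind(c(1, 2), c(2, 1))), "disjoint")
})

test_that("PCA satisfies the loading and reconstruction identities", {
  set.seed(42)
  m <- matrix(rnorm(16 * 13), 16, 13,
              dimnames = list(NULL, paste0("v", 1:13)))
  p <- run_pca(m)
  # unit-norm, orthonormal loadings
  expect_equal(unname(colSums(p$loadings^2)), rep(1, 13),
               tolerance = 1e-8)
  expect_equal(crossprod(p$loadings), diag(13), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: the dominant entry of each column is positive
  doms <- apply(p$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(doms > 0))
  # reconstruction of the centred/scaled data
  Xc <- scale(m, center = p$center, scale = p$scale)
  expect_equal(p$scores %*% t(p$loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained variance fractions match an SVD oracle
  sv <- svd(Xc)
  expect_equal(p$explained_variance, sv$d^2 / sum(sv$d^2),
               tolerance = 1e-8)
  expect_lte(max(p$cumulative_variance), 1 + 1e-12)

  # planted perfect correlation: one component carries all variance
  x <- rnorm(10)
  p2 <- run_pca(cbind(a = x, b = 2 * x), scale. = TRUE)
  expect_equal(p2$explained_variance[1], 1, tolerance = 1e-10)

  # constant column dropped with warning under scaling
  mc <- cbind(m, const = 5)
  expect_warning(p3 <- run_pca(mc), "constant")
  expect_equal(ncol(p3$loadings), 13L)
})

test_that("k-means on leading components is seeded and exact", {
  set.seed(1)
  sc <- rbind(matrix(rnorm(8 * 3, mean = 0, sd = 0.5), 8),
              matrix(rnorm(8 * 3, mean = 10, sd = 0.5), 8))
  colnames(sc) <- paste0("PC", 1:3)
  fakep <- structure(list(scores = sc), class = "PCAResult")
  ca <- kmeans_on_pcs(fakep, n_pcs = 3, k = 2, seed = 5)
  expect_equal(ari(ca$labels, rep(1:2, each = 8)), 1)
  expect_equal(ca$metadata$algorithm, "Hartigan-Wong")

  # determinism for a fixed seed
  ca2 <- kmeans_on_pcs(fakep, n_pcs = 3, k = 2, seed = 5)
  expect_identical(ca$labels, ca2$labels)

  # singleton clusters have zero inertia
  ca3 <- kmeans_on_pcs(fakep, n_pcs = 3, k = 16, seed = 5)
  expect_equal(ca3$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_on_pcs(fakep, n_pcs = 3, k = 17, seed = 1),
               "exceeds")
})

test_that("cluster-count report spans the requested range", {
  set.seed(2)
  sc <- rbind(matrix(rnorm(9 * 3), 9), matrix(rnorm(9 * 3, 8), 9))
  fakep <- structure(list(scores = sc), class = "PCAResult")
  rep_ <- cluster_count_report(fakep, n_pcs = 3, k_range = 2:4)
  expect_equal(rep_$k, 2:4)
  expect_true(all(diff(rep_$inertia) <= 1e-9))  # inertia non-increasing
  expect_equal(which.max(rep_$silhouette), 1L)  # true k = 2 wins
})

test_that("site-descriptor correlations match the Pearson formula", {
  set.seed(3)
  desc <- fake_descriptors(16, seed = 3)
  pats <- enumerate_patterns(four_sites())
  m <- assemble_features(desc, pats)
  cm <- correlate_ptm(m)
  expect_equal(dim(cm$r), c(4L, 9L))
  expect_true(all(abs(cm$r) <= 1))
  # direct covariance / sigma sigma oracle
  for (i in 1:4) for (j in 1:9) {
    x <- m[, 9 + i]; y <- m[, j]
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
      length(x) / (length(x) - 1)
    expect_equal(unname(cm$r[i, j]), r_oracle, tolerance = 1e-10)
  }
  # significance mask is exactly the |r| > 0.30 rule
  expect_identical(cm$significant, abs(cm$r) > 0.30)

  # an indicator duplicated as a descriptor correlates perfectly
  desc2 <- do.call(rbind, desc)
  desc2[, "volume"] <- vapply(pats, function(p) p$state[1], 0L)
  m2 <- assemble_features(desc2, pats)
  cm2 <- correlate_ptm(m2)
  expect_equal(unname(cm2$r["A.45", "volume"]), 1, tolerance = 1e-12)
  expect_true(cm2$significant["A.45", "volume"])

  # zero-variance column reported as 0, unflagged, with warning
  desc3 <- do.call(rbind, desc)
  desc3[, "n_min"] <- 1
  expect_warning(cm3 <- correlate_ptm(assemble_features(desc3, pats)),
                 "zero-variance")
  expect_equal(unname(cm3$r[, "n_min"]), rep(0, 4))
  expect_false(any(cm3$significant[, "n_min"]))
})

test_that("pipeline separates planted detached and compact regimes", {
  for (seed in 1:5) {
    m <- make_feature_study(n_per_group = 8, effect_size = 5, seed = seed)
    mn <- pairwise_normalize(m, attr(m, "pairs"))
    ca <- kmeans_on_pcs(run_pca(mn), n_pcs = 3, k = 2, seed = seed)
    expect_equal(ari(ca$labels, attr(m, "group")), 1)
  }
})
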
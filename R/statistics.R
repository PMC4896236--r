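# Statistical layer: feature assembly (9 general descriptors + binary
# modification indicators), pairwise wt/modified normalization, PCA with
# loading analysis, k-means classification on leading components, and
# the site-descriptor Pearson correlation matrix.

#' Assemble the feature matrix of a modification study
#'
#' One row per system; the first nine columns are the general
#' descriptors in canonical order, followed by one 0/1 indicator column
#' per modification site. Four sites on a two-chain system give the
#' 13-column matrix of a two-serine dimer study.
#'
#' @param desc list of named descriptor vectors (length 9 each), or a
#'   matrix with 9 columns.
#' @param patterns list of `PTMPattern`, one per system, sharing one
#'   site list.
#' @param labels optional row labels; defaults to [pattern_label()].
#' @return Numeric matrix of class `FeatureMatrix` with attribute
#'   `indicator_cols` (column indices of the site indicators) and
#'   `sites` (the site table).
#' @export
assemble_features <- function(desc, patterns, labels = NULL) {
  if (is.list(desc)) desc <- do.call(rbind, desc)
  stopifnot(is.matrix(desc), ncol(desc) == 9,
            nrow(desc) == length(patterns))
  site_tab <- patterns[[1]]$sites
  states <- lapply(patterns, function(p) {
    if (!identical(p$sites$label, site_tab$label))
      stop("patterns carry inconsistent site lists")
    as.numeric(p$state)
  })
  ind <- matrix(unlist(states), nrow = length(patterns), byrow = TRUE)
  m <- cbind(desc, ind)
  colnames(m) <- c(descriptor_names(), site_tab$label)
  rownames(m) <- if (is.null(labels))
    vapply(patterns, pattern_label, "") else labels
  structure(m, class = c("FeatureMatrix", "matrix", "array"),
            indicator_cols = 9L + seq_len(nrow(site_tab)),
            sites = site_tab)
}

#' Average the descriptors of a multimer's constituent interfaces
#'
#' Higher-order assemblies (e.g. a hexamer built from three dimers) are
#' scored by the element-wise mean of the descriptor vectors of their
#' constituent interface structures.
#'
#' @param members list of named numeric descriptor vectors (equal
#'   names/length).
#' @return One descriptor vector, the element-wise mean.
#' @export
aggregate_hexamer <- function(members) {
  if (!length(members)) stop("no member descriptor vectors supplied")
  m <- do.call(rbind, members)
  colMeans(m)
}

#' Pairwise wt/modified normalization
#'
#' Within each (wild-type, modified) pair, each descriptor's two values
#' are divided by their mean, removing system-specific scale so that
#' different proteins become comparable: every normalized pair sums to
#' 2 per variable and within-pair ratios are preserved. Indicator
#' columns are left untouched. A pair whose mean is 0 for some variable
#' gets value 1 for both members, with a warning.
#'
#' @param m numeric matrix (systems x variables); a `FeatureMatrix`'s
#'   indicator columns are exempted automatically.
#' @param pairs two-column matrix (or list of length-2 vectors) of row
#'   indices or row names; pairs must be disjoint.
#' @return Matrix of the same shape.
#' @export
pairwise_normalize <- function(m, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.character(pairs)) {
    pairs <- matrix(match(pairs, rownames(m)), ncol = 2)
  }
  stopifnot(is.matrix(pairs), ncol(pairs) == 2)
  if (anyNA(pairs)) stop("pair refers to a missing row")
  if (anyDuplicated(as.vector(pairs))) stop("pairs must be disjoint")
  cols <- seq_len(ncol(m))
  ind <- attr(m, "indicator_cols")
  if (!is.null(ind)) cols <- setdiff(cols, ind)
  out <- m
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    for (v in cols) {
      mu <- (m[i, v] + m[j, v]) / 2
      if (mu == 0) {
        warning("pair mean is 0 for variable '", colnames(m)[v],
                "'; setting both values to 1")
        out[i, v] <- out[j, v] <- 1
      } else {
        out[i, v] <- m[i, v] / mu
        out[j, v] <- m[j, v] / mu
      }
    }
  }
  out
}

#' Principal component analysis of a feature matrix
#'
#' Columns are centred and, by default, scaled to unit variance before
#' decomposition — with descriptors spanning Angstrom^2, kJ/mol, counts,
#' probabilities and binaries, correlation-matrix PCA keeps any single
#' unit from dominating the components. Loadings are unit-norm
#' eigenvector columns with a deterministic sign (largest-magnitude
#' entry positive). Constant columns are dropped with a warning when
#' scaling.
#'
#' @param m numeric matrix, systems x variables.
#' @param scale. unit-variance scaling (default `TRUE`).
#' @return Object of class `PCAResult`: `loadings` (variables x PCs),
#'   `scores` (systems x PCs), `sdev`, `explained_variance` (fraction
#'   per PC), `cumulative_variance`, `center`, `scale`, `retained`
#'   (PCs with standard deviation > 1, the retention rule used for
#'   mixed descriptor/indicator matrices).
#' @export
run_pca <- function(m, scale. = TRUE) {
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) >= 2, !anyNA(m))
  sds <- apply(m, 2, sd)
  if (scale. && any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  p <- prcomp(m, center = TRUE, scale. = scale.)
  L <- p$rotation
  S <- p$x
  for (k in seq_len(ncol(L))) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) {
      L[, k] <- -L[, k]
      S[, k] <- -S[, k]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  out <- list(loadings = L, scores = S, sdev = p$sdev,
              explained_variance = ev,
              cumulative_variance = cumsum(ev),
              center = p$center, scale = p$scale,
              retained = which(p$sdev > 1))
  class(out) <- "PCAResult"
  out
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", ncol(x$loadings), "PCs;",
      sprintf("first %d retained (sdev > 1), %.1f%% of variance\n",
              length(x$retained),
              100 * x$cumulative_variance[max(1, length(x$retained))]))
  invisible(x)
}

#' K-means classification on the leading principal components
#'
#' Clusters the systems on their scores over the first `n_pcs`
#' components with the Hartigan-Wong k-means algorithm, best of
#' `restarts` seeded initializations by within-cluster sum of squares.
#' Deterministic for a fixed seed.
#'
#' @param p a `PCAResult`.
#' @param n_pcs number of leading components to use.
#' @param k number of clusters.
#' @param restarts random restarts (default 50).
#' @param seed RNG seed.
#' @return Object of class `ClusterAssignment`: `k`, `labels` (named by
#'   system), `centroids`, `inertia`, `metadata` (algorithm, seed,
#'   restarts, n_pcs).
#' @export
kmeans_on_pcs <- function(p, n_pcs = 3, k = 2, restarts = 50,
                          seed = 1) {
  stopifnot(inherits(p, "PCAResult"), n_pcs <= ncol(p$scores))
  X <- p$scores[, seq_len(n_pcs), drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of systems")
  if (k == nrow(X)) {
    # degenerate: every system its own cluster
    km <- list(cluster = seq_len(nrow(X)), centers = X,
               tot.withinss = 0)
  } else {
    km <- with_seed(seed, kmeans(X, centers = k, nstart = restarts,
                                 iter.max = 100,
                                 algorithm = "Hartigan-Wong"))
  }
  out <- list(k = k, labels = stats::setNames(km$cluster, rownames(X)),
              centroids = km$centers, inertia = km$tot.withinss,
              metadata = list(algorithm = "Hartigan-Wong", seed = seed,
                              restarts = restarts, n_pcs = n_pcs))
  class(out) <- "ClusterAssignment"
  out
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: k =", x$k, "; sizes",
      paste(tabulate(x$labels, x$k), collapse = ", "),
      sprintf("; inertia %.3f\n", x$inertia))
  invisible(x)
}

#' Elbow and silhouette report over a range of cluster counts
#'
#' Aid for choosing k: total within-cluster sum of squares and mean
#' silhouette width for each candidate k. No choice is forced.
#'
#' @param p a `PCAResult`.
#' @param n_pcs leading components to use.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed.
#' @return data.frame with columns `k`, `inertia`, `silhouette`.
#' @export
cluster_count_report <- function(p, n_pcs = 3, k_range = 2:6, seed = 1) {
  X <- p$scores[, seq_len(n_pcs), drop = FALSE]
  D <- as.matrix(dist(X))
  rows <- lapply(k_range, function(k) {
    ca <- kmeans_on_pcs(p, n_pcs, k, seed = seed)
    data.frame(k = k, inertia = ca$inertia,
               silhouette = mean_silhouette(D, ca$labels))
  })
  do.call(rbind, rows)
}

mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(ks[ks != labels[i]],
                    function(k) mean(D[i, labels == k]), 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Pearson correlation between modification sites and descriptors
#'
#' Correlates every site-indicator column with every descriptor column
#' across systems; entries with `|r|` above `threshold` are flagged as
#' significant. Zero-variance columns give r = 0 (unflagged) with a
#' warning.
#'
#' @param m a `FeatureMatrix` from [assemble_features()].
#' @param threshold significance threshold on `|r|` (default 0.30).
#' @return Object of class `CorrelationMatrix`: `r` (sites x
#'   descriptors), `significant` (logical mask), `threshold`.
#' @export
correlate_ptm <- function(m, threshold = 0.30) {
  ind <- attr(m, "indicator_cols")
  if (is.null(ind)) stop("m must be a FeatureMatrix with indicators")
  stopifnot(nrow(m) >= 3)
  mm <- unclass(as.matrix(m))
  desc <- mm[, setdiff(seq_len(ncol(mm)), ind), drop = FALSE]
  indm <- mm[, ind, drop = FALSE]
  zv <- c(apply(desc, 2, sd), apply(indm, 2, sd)) == 0
  if (any(zv))
    warning("zero-variance column(s); correlations reported as 0")
  r <- suppressWarnings(cor(indm, desc))
  r[!is.finite(r)] <- 0
  out <- list(r = r, significant = abs(r) > threshold,
              threshold = threshold)
  class(out) <- "CorrelationMatrix"
  out
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix:", nrow(x$r), "site(s) x", ncol(x$r),
      "descriptors;", sum(x$significant), "significant at |r| >",
      x$threshold, "\n")
  print(round(x$r, 2))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
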
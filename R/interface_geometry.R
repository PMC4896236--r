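# Representative-conformation selection (GROMOS neighbour-counting
# clustering) and the static interface parameters: gap volume by the
# gap-sphere construction and the gap index (volume / interface ASA).

#' GROMOS conformational clustering
#'
#' Pairwise C-alpha RMSD after optimal superposition; iteratively the
#' frame with the most neighbours within `cutoff` becomes a cluster
#' centre, it and its neighbours are removed, and the procedure repeats.
#' Ties go to the lowest frame index. The representative conformation is
#' the centre of the largest cluster.
#'
#' @param t a `TrajectoryEnsemble` (all frames are clustered; restrict
#'   to the equilibrated window first if desired, e.g. via
#'   [representative_structure()]).
#' @param cutoff neighbour RMSD cutoff in nm (default 0.3).
#' @return An object of class `ConformationClusters`: `labels` (cluster
#'   id per frame, 1-based, largest cluster first), `sizes` (descending),
#'   `centers` (frame index of each cluster centre), `representative`
#'   (centre of cluster 1), `cutoff`.
#' @export
gromos_cluster <- function(t, cutoff = 0.3) {
  stopifnot(inherits(t, "TrajectoryEnsemble"), cutoff > 0)
  D <- pairwise_rmsd(t) / 10  # Angstrom -> nm
  nf <- nrow(D)
  A <- D <= cutoff            # includes self
  labels <- integer(nf)
  centers <- integer(0)
  remaining <- seq_len(nf)
  cl <- 0L
  while (length(remaining)) {
    counts <- rowSums(A[remaining, remaining, drop = FALSE])
    ctr <- remaining[which.max(counts)]  # which.max: first max = lowest index
    members <- remaining[A[ctr, remaining]]
    cl <- cl + 1L
    labels[members] <- cl
    centers[cl] <- ctr
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(labels, cl)
  ord <- order(-sizes, seq_len(cl))  # stable: ties keep formation order
  relabel <- integer(cl)
  relabel[ord] <- seq_len(cl)
  out <- list(labels = relabel[labels], sizes = sizes[ord],
              centers = centers[ord], representative = centers[ord][1],
              cutoff = cutoff)
  class(out) <- "ConformationClusters"
  out
}

#' @export
print.ConformationClusters <- function(x, ...) {
  cat("ConformationClusters:", length(x$sizes), "cluster(s), sizes",
      paste(x$sizes, collapse = ", "), "; representative frame",
      x$representative, "\n")
  invisible(x)
}

#' Representative conformation of the equilibrated window
#'
#' Clusters the equilibrated frames with [gromos_cluster()] and returns
#' the central structure of the largest cluster — the "average
#' conformation" on which the static interface parameters (gap volume,
#' gap index) are evaluated.
#'
#' @param t a `TrajectoryEnsemble` with `eq_window` set.
#' @param cutoff GROMOS RMSD cutoff, nm.
#' @return A `StructureModel`; the selected absolute frame index is
#'   attached as attribute `frame`.
#' @export
representative_structure <- function(t, cutoff = 0.3) {
  fr <- eq_frames(t)
  sub <- trajectory_ensemble(t$topology,
                             t$xyz[fr, , drop = FALSE],
                             times = t$times[fr])
  cl <- gromos_cluster(sub, cutoff)
  idx <- fr[cl$representative]
  out <- frame_structure(t, idx)
  attr(out, "frame") <- idx
  out
}

#' Gap-sphere analysis of a two-chain interface
#'
#' Fills the cleft between the chains with spheres: for every
#' inter-chain atom pair whose surface-to-surface separation is positive
#' and at most `distance_cutoff`, a trial sphere is centred at the
#' midpoint of the inter-surface segment with radius half the
#' separation, then shrunk until it penetrates no atom; spheres that
#' keep a radius of at least `min_gap_radius` are retained. The union of
#' the retained spheres is rasterized on a cubic grid of spacing
#' `grid_interval` and the occupied-voxel volume is the gap volume. The
#' grid is aligned to the principal axes of the sphere centres, making
#' the estimate independent of the complex's pose.
#'
#' The gap index divides the gap volume by the interface accessible
#' surface area. The interface ASA is not uniquely defined; the default
#' uses the per-side convention `buried_sas(s) / 2`, with
#' `asa_mode = "total"` using the full buried area instead.
#'
#' @param s a `StructureModel` with exactly 2 chains.
#' @param grid_interval voxel edge, Angstrom (default 0.8).
#' @param distance_cutoff maximum inter-surface separation considered,
#'   Angstrom (default 5).
#' @param min_gap_radius smallest retained sphere radius, Angstrom
#'   (default 1).
#' @param asa_mode `"per_side"` (buried SASA / 2, default) or `"total"`.
#' @param n_points SASA sampling density for the interface-area term.
#' @return An object of class `GapRegion`: `spheres` (matrix x, y, z,
#'   radius), `gap_volume` (Angstrom^3), `interface_asa` (Angstrom^2),
#'   `gap_index` (Angstrom), `grid_interval`, `distance_cutoff`.
#' @export
gap_analysis <- function(s, grid_interval = 0.8, distance_cutoff = 5.0,
                         min_gap_radius = 1.0,
                         asa_mode = c("per_side", "total"),
                         n_points = 960) {
  stopifnot(inherits(s, "StructureModel"), grid_interval > 0,
            distance_cutoff > 0)
  asa_mode <- match.arg(asa_mode)
  if (length(s$chains) != 2L)
    stop("gap analysis requires exactly two chains")
  i1 <- which(s$atoms$chain == s$chains[1])
  i2 <- which(s$atoms$chain == s$chains[2])
  x1 <- s$xyz[i1, , drop = FALSE]; r1 <- s$vdw[i1]
  x2 <- s$xyz[i2, , drop = FALSE]; r2 <- s$vdw[i2]
  d <- sqrt(pmax(outer(rowSums(x1^2), rep(1, length(i2))) -
                   2 * tcrossprod(x1, x2) +
                   outer(rep(1, length(i1)), rowSums(x2^2)), 0))
  sep <- d - outer(r1, rep(1, length(i2))) -
    outer(rep(1, length(i1)), r2)
  pairs <- which(sep > 0 & sep <= distance_cutoff, arr.ind = TRUE)
  spheres <- NULL
  if (nrow(pairs)) {
    cand <- matrix(0, nrow(pairs), 4)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      u <- (x2[j, ] - x1[i, ]) / d[i, j]
      ctr <- x1[i, ] + (r1[i] + sep[i, j] / 2) * u
      cand[k, ] <- c(ctr, sep[i, j] / 2)
    }
    # shrink each trial sphere to the clearance of its nearest atom
    allxyz <- s$xyz; allr <- s$vdw
    for (k in seq_len(nrow(cand))) {
      clear <- sqrt(colSums((t(allxyz) - cand[k, 1:3])^2)) - allr
      cand[k, 4] <- min(cand[k, 4], min(clear))
    }
    spheres <- cand[cand[, 4] >= min_gap_radius, , drop = FALSE]
    if (nrow(spheres) == 0L) spheres <- NULL
  }
  asa_total <- tryCatch(buried_sas(s, n_points = n_points),
                        error = function(e) 0)
  interface_asa <- if (asa_mode == "per_side") asa_total / 2 else asa_total
  if (is.null(spheres)) {
    warning("no gap spheres found between the chains; gap volume is 0")
    gap_volume <- 0
    spheres <- matrix(numeric(0), 0, 4)
  } else {
    gap_volume <- sphere_union_volume(spheres, grid_interval)
  }
  gap_index <- if (interface_asa > 0 && gap_volume > 0)
    gap_volume / interface_asa else 0
  out <- list(spheres = spheres, gap_volume = gap_volume,
              interface_asa = interface_asa, gap_index = gap_index,
              grid_interval = grid_interval,
              distance_cutoff = distance_cutoff)
  class(out) <- "GapRegion"
  out
}

#' @export
print.GapRegion <- function(x, ...) {
  cat(sprintf(
    "GapRegion: %d sphere(s), volume %.1f A^3, interface ASA %.1f A^2, gap index %.3f\n",
    nrow(x$spheres), x$gap_volume, x$interface_asa, x$gap_index))
  invisible(x)
}

# Volume of a union of spheres by voxel counting on a grid aligned to
# the principal axes of the sphere centres (pose-independent) and
# centred on their centroid (reflection-symmetric).
sphere_union_volume <- function(spheres, h) {
  ctr <- spheres[, 1:3, drop = FALSE]
  rad <- spheres[, 4]
  mu <- colMeans(ctr)
  X <- sweep(ctr, 2, mu)
  if (nrow(ctr) >= 2) {
    ev <- eigen(crossprod(X) / nrow(ctr), symmetric = TRUE)$vectors
    X <- X %*% ev
  }
  lo <- apply(X, 2, min) - max(rad)
  hi <- apply(X, 2, max) + max(rad)
  ax <- lapply(1:3, function(k) {
    n <- ceiling((hi[k] - lo[k]) / h / 2)
    (seq(-n, n)) * h  # symmetric about the centroid
  })
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  inside <- rep(FALSE, nrow(g))
  for (k in seq_len(nrow(X))) {
    todo <- which(!inside)
    if (!length(todo)) break
    d2 <- (g[todo, 1] - X[k, 1])^2 + (g[todo, 2] - X[k, 2])^2 +
      (g[todo, 3] - X[k, 3])^2
    inside[todo[d2 <= rad[k]^2]] <- TRUE
  }
  sum(inside) * h^3
}
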
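# Essential dynamics (PCA of positional covariance) and the
# free-energy-landscape stability markers: AbsMin, the occupancy of the
# most populated region of the PC1/PC2 landscape, and the number of
# distinct regions whose occupancy reaches a fraction of it.

#' Essential dynamics of an equilibrated trajectory
#'
#' C-alpha frames in the equilibrated window are superposed on their
#' mean structure (one fixed-point iteration starting from the first
#' frame), the 3n x 3n positional covariance is built, and its
#' eigendecomposition gives the collective modes of motion. Eigenvector
#' signs follow a deterministic convention: the largest-magnitude
#' component of each mode is positive.
#'
#' @param t a `TrajectoryEnsemble` with at least 2 equilibrated frames.
#' @param selection atom indices to analyse; default all C-alpha atoms.
#' @return Object of class `EDBasis`: `mean_coords` (n x 3),
#'   `vectors` (3n x 3n, columns sorted by decreasing eigenvalue),
#'   `values` (eigenvalues, Angstrom^2), `selection`.
#' @export
essential_dynamics <- function(t, selection = calpha_indices(t)) {
  stopifnot(inherits(t, "TrajectoryEnsemble"))
  if (!length(selection)) stop("empty atom selection")
  fr <- eq_frames(t)
  if (length(fr) < 2L) stop("essential dynamics needs at least 2 frames")
  coords <- lapply(fr, function(i) frame_coords(t$xyz, i, selection))
  fitted <- lapply(coords, kabsch_fit, ref = coords[[1]])
  m1 <- Reduce(`+`, fitted) / length(fitted)
  fitted <- lapply(coords, kabsch_fit, ref = m1)
  mean_coords <- Reduce(`+`, fitted) / length(fitted)
  X <- do.call(rbind, lapply(fitted, function(m) as.vector(t(m))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  out <- list(mean_coords = mean_coords, vectors = vecs, values = vals,
              selection = selection)
  class(out) <- "EDBasis"
  out
}

#' Project equilibrated frames on the leading modes
#'
#' @param t a `TrajectoryEnsemble`.
#' @param basis an `EDBasis` from the same topology.
#' @param n_modes number of leading modes (default 2).
#' @return frames x `n_modes` score matrix (Angstrom).
#' @export
project_frames <- function(t, basis, n_modes = 2) {
  stopifnot(inherits(basis, "EDBasis"))
  fr <- eq_frames(t)
  mu <- as.vector(t(basis$mean_coords))
  V <- basis$vectors[, seq_len(n_modes), drop = FALSE]
  out <- matrix(0, length(fr), n_modes)
  for (i in seq_along(fr)) {
    m <- kabsch_fit(frame_coords(t$xyz, fr[i], basis$selection),
                    basis$mean_coords)
    out[i, ] <- (as.vector(t(m)) - mu) %*% V
  }
  out
}

#' Build the free-energy landscape grid
#'
#' Projects the equilibrated frames on the first two essential-dynamics
#' modes and bins them on an `n_bins` x `n_bins` equal-width grid
#' spanning the data range. Cell values are frame-count fractions
#' (occupancy probabilities; high occupancy corresponds to low free
#' energy). `abs_min` is the largest summed occupancy of a `box` x `box`
#' sliding window — the probability mass of the most likely
#' conformational region.
#'
#' @param t a `TrajectoryEnsemble`.
#' @param basis an `EDBasis`; computed from `t` when `NULL`.
#' @param n_bins grid size per axis (default 20).
#' @param box window edge in cells for basin statistics (default 3).
#' @return Object of class `FELGrid`: `probs` (n_bins x n_bins, sums to
#'   1), `edges` (list of two break vectors), `abs_min`, `box`,
#'   `scores` (the projections).
#' @export
build_fel <- function(t, basis = NULL, n_bins = 20, box = 3) {
  if (is.null(basis)) basis <- essential_dynamics(t)
  sc <- project_frames(t, basis, n_modes = 2)
  g <- fel_grid_from_scores(sc, n_bins = n_bins, box = box)
  g
}

#' Free-energy-landscape grid from 2-D projections
#'
#' @param scores frames x 2 matrix of reaction-coordinate values.
#' @inheritParams build_fel
#' @return A `FELGrid` (see [build_fel()]).
#' @export
fel_grid_from_scores <- function(scores, n_bins = 20, box = 3) {
  stopifnot(is.matrix(scores), ncol(scores) == 2, n_bins >= box)
  counts <- matrix(0, n_bins, n_bins)
  edges <- vector("list", 2)
  idx <- matrix(0L, nrow(scores), 2)
  for (k in 1:2) {
    rng <- range(scores[, k])
    if (diff(rng) < 1e-12) {
      # degenerate axis: all mass in the central bin
      mid <- ceiling(n_bins / 2)
      edges[[k]] <- seq(rng[1] - 0.5, rng[1] + 0.5,
                        length.out = n_bins + 1)
      idx[, k] <- mid
    } else {
      edges[[k]] <- seq(rng[1], rng[2], length.out = n_bins + 1)
      b <- findInterval(scores[, k], edges[[k]],
                        rightmost.closed = TRUE)
      idx[, k] <- pmin.int(pmax.int(b, 1L), n_bins)
    }
  }
  for (i in seq_len(nrow(idx)))
    counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
  probs <- counts / sum(counts)
  out <- list(probs = probs, edges = edges,
              abs_min = max(window_sums(probs, box)), box = box,
              scores = scores)
  class(out) <- "FELGrid"
  out
}

# Sliding box x box window sums over a probability grid; result is
# (n - box + 1)^2 positioned at the window's low corner.
window_sums <- function(p, box = 3) {
  n <- nrow(p)
  nw <- n - box + 1L
  cs <- rbind(0, apply(p, 2, cumsum))
  colsum <- cs[(box + 1):(n + 1), , drop = FALSE] -
    cs[1:nw, , drop = FALSE]            # nw x n: vertical box sums
  cs2 <- cbind(0, t(apply(colsum, 1, cumsum)))
  cs2[, (box + 1):(n + 1), drop = FALSE] - cs2[, 1:nw, drop = FALSE]
}

#' Count the distinct basins of a free-energy landscape
#'
#' Slides a `box` x `box` window over the occupancy grid; a window is a
#' basin when its summed occupancy reaches `frac` times the largest
#' window sum and it is a local maximum among all windows overlapping
#' it (non-maximum suppression, so one basin spanning several adjacent
#' windows counts once; ties break toward the lower (row, column)
#' index). At least one basin — the absolute minimum itself — is always
#' returned. Few large basins mark a stable structure; many mark a
#' metastable one.
#'
#' @param g a `FELGrid`.
#' @param box window edge in cells (default the grid's own).
#' @param frac occupancy threshold as a fraction of the deepest basin
#'   (default 0.7).
#' @return Integer basin count; the surviving window positions are
#'   attached as attribute `minima` (matrix row, col, prob).
#' @export
count_minima <- function(g, box = NULL, frac = 0.7) {
  stopifnot(inherits(g, "FELGrid"), frac > 0, frac <= 1)
  if (is.null(box)) box <- g$box
  W <- window_sums(g$probs, box)
  nw <- nrow(W)
  maxW <- max(W)
  cand <- which(W >= frac * maxW - 1e-12, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    ii <- max(1L, i - box + 1L):min(nw, i + box - 1L)
    jj <- max(1L, j - box + 1L):min(nw, j + box - 1L)
    nb <- W[ii, jj, drop = FALSE]
    w <- W[i, j]
    if (any(nb > w + 1e-15)) next
    # among equal-valued overlapping windows, the lex-smallest survives
    eq <- which(abs(nb - w) <= 1e-15, arr.ind = TRUE)
    eq_abs <- cbind(ii[eq[, 1]], jj[eq[, 2]])
    first <- eq_abs[order(eq_abs[, 1], eq_abs[, 2])[1], ]
    keep[k] <- first[1] == i && first[2] == j
  }
  minima <- cbind(cand[keep, , drop = FALSE],
                  prob = W[cand[keep, , drop = FALSE]])
  attr_n <- max(1L, sum(keep))
  structure(attr_n, minima = minima)
}

#' @export
print.FELGrid <- function(x, ...) {
  cat(sprintf("FELGrid: %dx%d, AbsMin %.3f (box %d)\n",
              nrow(x$probs), ncol(x$probs), x$abs_min, x$box))
  invisible(x)
}

#' Free-energy values of a landscape grid
#'
#' `-kT ln p` relative to the most occupied cell, for plotting only;
#' empty cells are `Inf`. All statistics in the package operate on
#' occupancy probabilities, never on these logarithms.
#'
#' @param g a `FELGrid`.
#' @param kT energy unit (default 2.494 kJ/mol, 300 K).
#' @return Matrix of free energies, kJ/mol.
#' @export
fel_energy <- function(g, kT = 2.494) {
  p <- g$probs
  out <- matrix(Inf, nrow(p), ncol(p))
  nz <- p > 0
  out[nz] <- -kT * log(p[nz] / max(p))
  out
}
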
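# Kabsch least-squares superposition and RMSD, used by equilibration
# detection, conformational clustering and essential dynamics.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `ref` minimizing the coordinate
#' RMSD, with the proper-rotation (determinant +1) correction.
#'
#' @param mobile n x 3 matrix to move.
#' @param ref n x 3 reference matrix.
#' @return The transformed `mobile` coordinates, n x 3.
#' @export
kabsch_fit <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), ncol(mobile) == 3)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(tcrossprod(s$u, s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(P %*% R, 2, cr, "+")
}

#' Coordinate RMSD after optimal superposition
#'
#' @param a,b n x 3 coordinate matrices (Angstrom).
#' @param fit superpose `a` onto `b` first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(a, b, fit = TRUE) {
  if (fit) a <- kabsch_fit(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

# Frame i of a flat frames x 3n matrix as an n x 3 block, optionally
# restricted to atom indices `sel` (applied before reshaping).
frame_coords <- function(xyz, i, sel = NULL) {
  v <- xyz[i, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

# Pairwise C-alpha RMSD matrix over the frames of an ensemble, in
# Angstrom. O(n^2) Kabsch fits; intended for the modest frame counts of
# representative-structure selection.
pairwise_rmsd <- function(t, sel = calpha_indices(t)) {
  if (!length(sel)) stop("no C-alpha atoms in topology")
  nf <- nrow(t$xyz)
  coords <- lapply(seq_len(nf), function(i) frame_coords(t$xyz, i, sel))
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- rmsd_fit(coords[[j]], coords[[i]])
    }
  }
  D
}
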
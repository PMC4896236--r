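# Solvent-accessible surface area by Shrake-Rupley sphere sampling.
# Deterministic Fibonacci point set, so results are reproducible and
# converge smoothly with n_points.

# Quasi-uniform points on the unit sphere (golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE",
                           "TRP", "PRO", "GLY")

#' Solvent-accessible surface area
#'
#' Shrake-Rupley estimate: each atom's sphere of radius `vdw + probe` is
#' sampled at `n_points` quasi-uniform points and the accessible
#' fraction (points outside every neighbouring expanded sphere) scales
#' the analytic sphere area. An isolated atom therefore returns
#' 4 pi (r + probe)^2 exactly.
#'
#' @param s a `StructureModel`.
#' @param subset `"all"` (default) or `"hydrophobic"`. The hydrophobic
#'   subset sums area only over carbon/sulfur atoms of apolar residues
#'   (ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, GLY by default); occlusion
#'   always uses all atoms.
#' @param chain optional chain identifier: compute the SASA of that
#'   chain extracted from the complex, in its complex conformation.
#' @param probe probe radius, Angstrom (water, 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @param hydrophobic_resnames residue names treated as hydrophobic.
#' @return Area in Angstrom^2.
#' @export
compute_sas <- function(s, subset = c("all", "hydrophobic"), chain = NULL,
                        probe = 1.4, n_points = 960,
                        hydrophobic_resnames = .hydrophobic_residues) {
  stopifnot(inherits(s, "StructureModel"), n_points >= 100)
  subset <- match.arg(subset)
  if (!is.null(chain)) s <- extract_chain(s, chain)
  areas <- atom_sas(s$xyz, s$vdw, probe, n_points)
  if (subset == "hydrophobic") {
    keep <- s$atoms$resname %in% hydrophobic_resnames &
      s$atoms$element %in% c("C", "S")
    if (!any(keep)) {
      warning("no hydrophobic atoms in structure; hydrophobic SAS is 0")
      return(0)
    }
    return(sum(areas[keep]))
  }
  sum(areas)
}

# Per-atom accessible areas (Angstrom^2) for coordinates/radii.
atom_sas <- function(xyz, vdw, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  re <- vdw + probe
  pts <- fibonacci_sphere(n_points)
  D2 <- as.matrix(dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (re[i] + re)^2)
    nb <- nb[nb != i]
    full <- 4 * pi * re[i]^2
    if (!length(nb)) {
      areas[i] <- full
      next
    }
    p <- pts * re[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    # n_points x n_nb squared distances to neighbour centres
    nbxyz <- xyz[nb, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rep(1, length(nb))) -
      2 * tcrossprod(p, nbxyz) +
      outer(rep(1, n_points), rowSums(nbxyz^2))
    buried <- d2 < matrix(re[nb]^2, n_points, length(nb), byrow = TRUE)
    acc <- rowSums(buried) == 0L
    areas[i] <- full * mean(acc)
  }
  areas
}

#' Buried (interface) surface area of a two-chain complex
#'
#' The area lost on complexation:
#' `SASA(monomer 1) + SASA(monomer 2) - SASA(complex)`, each monomer
#' kept in its complex conformation. Non-negative up to sampling noise;
#' zero for non-contacting chains.
#'
#' @inheritParams compute_sas
#' @return Buried area in Angstrom^2.
#' @export
buried_sas <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "StructureModel"))
  if (length(s$chains) < 2L)
    stop("interface requires two chains")
  if (length(s$chains) > 2L)
    stop("buried_sas is defined for a two-chain complex; extract the ",
         "interface pair first")
  m1 <- compute_sas(s, chain = s$chains[1], probe = probe,
                    n_points = n_points)
  m2 <- compute_sas(s, chain = s$chains[2], probe = probe,
                    n_points = n_points)
  cx <- compute_sas(s, probe = probe, n_points = n_points)
  m1 + m2 - cx
}
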
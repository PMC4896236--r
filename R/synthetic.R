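# Synthetic ground-truth generators: toy two-chain structures with a
# tunable interface separation, harmonic and multi-basin ensembles with
# planted covariance/landscape structure, and feature matrices with a
# planted detached/compact split. Every generator is a pure function of
# its seed. These are first-class study inputs, not fixtures: they
# define the conditions under which the pipeline's recovery claims are
# tested.

#' Toy two-chain dimer
#'
#' Two mirror-image poly-alanine-like chains (backbone N, H, CA, C, O
#' atoms per residue, so polar geometry is available for hydrogen-bond
#' tests) facing each other across a planar interface. `separation` is
#' the surface-to-surface distance between the chains' closest van der
#' Waals surfaces: 0 means contact, large values an unbound pair.
#'
#' @param n_res residues per chain (default 8).
#' @param separation inter-chain surface distance, Angstrom.
#' @param seed RNG seed for the small coordinate jitter that breaks the
#'   lattice symmetry.
#' @param jitter jitter standard deviation, Angstrom (default 0.05).
#' @param phospho optional site table (see [mark_phosphosites()]):
#'   those residues get the phospho-serine residue code `SEP`.
#' @return A `StructureModel` with chains A and B.
#' @export
make_toy_dimer <- function(n_res = 8, separation = 2, seed = 1,
                           jitter = 0.05, phospho = NULL) {
  stopifnot(n_res >= 2, separation >= 0)
  base <- function(i) rbind(
    N  = c(3.5 * i - 1.3, -0.3, 0.9),
    H  = c(3.5 * i - 1.3, -0.3, 1.9),
    CA = c(3.5 * i, 0.0, 0.0),
    C  = c(3.5 * i + 1.2, 0.4, 0.0),
    O  = c(3.5 * i + 1.2, 0.4, 1.1))
  names_per_res <- c("N", "H", "CA", "C", "O")
  elem_per_res <- c("N", "H", "C", "C", "O")
  one_chain <- do.call(rbind, lapply(seq_len(n_res), base))
  m <- nrow(one_chain)
  with_seed(seed, {
    xyzA <- one_chain + matrix(rnorm(3 * m, sd = jitter), m, 3)
    xyzB0 <- one_chain + matrix(rnorm(3 * m, sd = jitter), m, 3)
  })
  rad <- vdw_radius(rep(elem_per_res, n_res))
  topA <- max(xyzA[, 3] + rad)
  # mirror chain B through the interface plane; its lowest surface sits
  # `separation` above chain A's highest
  botB_surface <- max(xyzB0[, 3] + rad)  # becomes the bottom after mirroring
  cz <- topA + separation + botB_surface
  xyzB <- xyzB0
  xyzB[, 3] <- cz - xyzB0[, 3]
  atoms <- data.frame(
    serial = seq_len(2 * m),
    name = rep(names_per_res, 2 * n_res),
    element = rep(elem_per_res, 2 * n_res),
    resname = "ALA",
    resid = rep(rep(seq_len(n_res), each = length(names_per_res)), 2),
    chain = rep(c("A", "B"), each = m),
    stringsAsFactors = FALSE)
  if (!is.null(phospho)) {
    ph <- as_site_table(phospho)
    for (i in seq_len(nrow(ph))) {
      hit <- atoms$chain == ph$chain[i] & atoms$resid == ph$resid[i]
      if (!any(hit))
        stop("phospho site ", ph$label[i], " outside the toy dimer")
      atoms$resname[hit] <- "SEP"
    }
  }
  structure_model(atoms, rbind(xyzA, xyzB))
}

# Orthonormal basis of the rigid-body subspace (3 translations, 3
# infinitesimal rotations) of a coordinate set, as 3m-vectors.
rigid_basis <- function(coords) {
  m <- nrow(coords)
  ctr <- sweep(coords, 2, colMeans(coords))
  tr <- diag(3)[rep(1:3, m), ]          # 3m x 3 translations
  rot <- sapply(1:3, function(a) {
    ax <- diag(3)[a, ]
    as.vector(t(t(apply(ctr, 1, function(r) pracma_cross(ax, r)))))
  })
  qr.Q(qr(cbind(tr, rot)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# k orthonormal internal (non-rigid) displacement modes over m atoms.
internal_modes <- function(coords, k) {
  R <- rigid_basis(coords)
  M <- matrix(rnorm(3 * nrow(coords) * k), ncol = k)
  M <- M - R %*% crossprod(R, M)
  qr.Q(qr(M))[, seq_len(k), drop = FALSE]
}

# Embed C-alpha-space displacements into full-topology frames.
embed_frames <- function(s, sel, disp) {
  ref <- as.vector(t(s$xyz))
  xyz <- matrix(ref, nrow(disp), length(ref), byrow = TRUE)
  slots <- as.vector(rbind(3 * (sel - 1) + 1, 3 * (sel - 1) + 2,
                           3 * sel))
  xyz[, slots] <- xyz[, slots] + disp
  xyz
}

#' Harmonic ensemble with planted collective modes
#'
#' Generates frames `ref + sum_k sqrt(var_k) z_k mode_k` with standard
#' normal amplitudes `z`, where the modes are random orthonormal
#' C-alpha displacement vectors orthogonal to the rigid-body subspace
#' (so superposition cannot absorb them). The planted modes and
#' variances are the ground truth that essential dynamics must recover.
#'
#' @param s a `StructureModel` (the reference/topology).
#' @param mode_variances planted mode variances, Angstrom^2, descending.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return A `TrajectoryEnsemble`; attributes `planted_modes` (3m x k,
#'   C-alpha space) and `planted_variances`.
#' @export
make_harmonic_ensemble <- function(s, mode_variances = c(4, 1),
                                   n_frames = 1000, seed = 1) {
  stopifnot(inherits(s, "StructureModel"), all(mode_variances >= 0))
  sel <- calpha_indices(s)
  if (!length(sel)) stop("structure has no C-alpha atoms")
  k <- length(mode_variances)
  with_seed(seed, {
    modes <- internal_modes(s$xyz[sel, , drop = FALSE], k)
    z <- matrix(rnorm(n_frames * k), n_frames, k)
  })
  disp <- (z %*% (t(modes) * sqrt(mode_variances)))
  t <- trajectory_ensemble(s, embed_frames(s, sel, disp))
  attr(t, "planted_modes") <- modes
  attr(t, "planted_variances") <- mode_variances
  t
}

#' Specification of a multi-basin landscape
#'
#' @param k number of basins.
#' @param centers k x 2 matrix of latent basin centres (latent units =
#'   Angstrom along the embedding modes); defaults place basins at
#'   pairwise distance 8 for k up to 3.
#' @param weights basin occupancies, summing to 1 (default equal).
#' @param widths latent standard deviation per basin (default 1).
#' @param n_frames frames to sample (default 600).
#' @param seed RNG seed.
#' @return list of class `BasinSpec`.
#' @export
basin_spec <- function(k, centers = NULL, weights = NULL, widths = 1,
                       n_frames = 600, seed = 1) {
  stopifnot(k >= 1)
  if (is.null(centers)) {
    default <- list(rbind(c(0, 0)),
                    rbind(c(0, 0), c(8, 0)),
                    rbind(c(0, 0), c(8, 0), c(4, 8 * sqrt(3) / 2)))
    if (k > 3) stop("default centers are defined for k <= 3")
    centers <- default[[k]]
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == k, ncol(centers) == 2)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  widths <- rep_len(widths, k)
  if (k > 1) {
    dmin <- min(dist(centers))
    if (dmin < 6 * max(widths))
      warning("basin centres closer than 6 latent sigma; ",
              "recovery is not guaranteed")
  }
  structure(list(k = k, centers = centers, weights = weights,
                 widths = widths, n_frames = n_frames, seed = seed),
            class = "BasinSpec")
}

#' Ensemble with a planted number of metastable basins
#'
#' Samples latent 2-D coordinates from a Gaussian mixture and embeds
#' them along two fixed orthonormal internal C-alpha modes, producing a
#' trajectory whose essential-dynamics landscape has `spec$k` basins of
#' known weight — the ground truth for [count_minima()]. A minor basin
#' whose weight falls below the occupancy threshold (0.7 of the deepest
#' basin by default) is, by design, not counted.
#'
#' @param s a `StructureModel`.
#' @param spec a [basin_spec()].
#' @return A `TrajectoryEnsemble`; attributes `latent` (n x 2 latent
#'   samples), `components` (basin of each frame), `planted_modes`.
#' @export
make_basin_ensemble <- function(s, spec) {
  stopifnot(inherits(s, "StructureModel"), inherits(spec, "BasinSpec"))
  sel <- calpha_indices(s)
  if (!length(sel)) stop("structure has no C-alpha atoms")
  with_seed(spec$seed, {
    modes <- internal_modes(s$xyz[sel, , drop = FALSE], 2)
    comp <- sample.int(spec$k, spec$n_frames, replace = TRUE,
                       prob = spec$weights)
    latent <- spec$centers[comp, , drop = FALSE] +
      matrix(rnorm(2 * spec$n_frames), ncol = 2) * spec$widths[comp]
  })
  disp <- latent %*% t(modes)
  t <- trajectory_ensemble(s, embed_frames(s, sel, disp))
  attr(t, "latent") <- latent
  attr(t, "components") <- comp
  attr(t, "planted_modes") <- modes
  t
}

#' Feature study with a planted detached/compact split
#'
#' Emulates a wt/modified validation panel: `n_per_group` "detached"
#' systems (raised total and hydrophobic SASA, gap index, gap volume and
#' basin count; lowered buried SASA, hydrogen bonds, LJ energy and
#' deepest-basin occupancy) paired with `n_per_group` "compact" systems
#' showing the reverse shifts. Values are generated on realistic
#' descriptor scales with 5% relative noise; each pair additionally
#' carries a shared random size factor that pairwise normalization is
#' expected to remove. `effect_size` is the group separation in noise
#' standard deviations.
#'
#' @param n_per_group systems per group (default 8).
#' @param effect_size separation in sigma units (0 = no signal).
#' @param seed RNG seed.
#' @return Numeric matrix (2 n x 9, descriptor columns) with attributes
#'   `group` (factor detached/compact), `pairs` (n x 2 row-index
#'   matrix pairing detached with compact systems).
#' @export
make_feature_study <- function(n_per_group = 8, effect_size = 5,
                               seed = 1) {
  stopifnot(n_per_group >= 1, effect_size >= 0)
  baseline <- c(total_sas = 12000, hydrophobic_sas = 4500,
                buried_sas = 900, hb = 12, gap_index = 2,
                volume = 1500, e_lj = 250, abs_min = 0.15, n_min = 3)
  # +1: larger when the interface detaches; -1: larger when compact
  direction <- c(total_sas = 1, hydrophobic_sas = 1, buried_sas = -1,
                 hb = -1, gap_index = 1, volume = 1, e_lj = -1,
                 abs_min = -1, n_min = 1)
  cv <- 0.05
  n <- n_per_group
  with_seed(seed, {
    noise <- matrix(rnorm(2 * n * 9), 2 * n, 9)
    size_factor <- exp(rnorm(n, sd = 0.2))
  })
  shift <- rbind(matrix(rep(direction * effect_size / 2, each = n), n),
                 matrix(rep(-direction * effect_size / 2, each = n), n))
  vals <- matrix(rep(baseline, each = 2 * n), 2 * n) *
    (1 + cv * (shift + noise))
  vals <- vals * rep(size_factor, 2)  # shared within each pair
  colnames(vals) <- names(baseline)
  rownames(vals) <- c(paste0("sys", seq_len(n), "_Op"),
                      paste0("sys", seq_len(n), "_Cl"))
  attr(vals, "group") <- factor(rep(c("detached", "compact"), each = n),
                                levels = c("detached", "compact"))
  attr(vals, "pairs") <- cbind(seq_len(n), n + seq_len(n))
  vals
}
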
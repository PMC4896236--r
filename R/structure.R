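# Containers: StructureModel (single conformation) and TrajectoryEnsemble
# (frames over a shared topology), plus van der Waals radius assignment.

# Bondi-style van der Waals radii (Angstrom)
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)
.vdw_default <- 1.70

#' Construct a structure model
#'
#' A `StructureModel` holds one conformation of a (possibly multimeric)
#' protein: an atom table, an n x 3 coordinate matrix in Angstrom, and a
#' van der Waals radius per atom. It is the unit every interface
#' descriptor consumes.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, coordinates in Angstrom.
#' @param vdw optional numeric vector of radii (Angstrom); looked up from
#'   a bundled element table when `NULL`. Unknown elements fall back to
#'   1.7 Angstrom with a warning.
#' @return An object of class `StructureModel` with components `atoms`,
#'   `xyz`, `vdw` and `chains` (ordered unique chain identifiers).
#' @export
structure_model <- function(atoms, xyz, vdw = NULL) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(xyz) == nrow(atoms))
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in structure")
  need <- c("serial", "name", "element", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(vdw)) vdw <- vdw_radius(atoms$element)
  if (any(vdw <= 0)) stop("van der Waals radii must be positive")
  s <- list(atoms = atoms, xyz = unname(xyz), vdw = as.numeric(vdw),
            chains = unique(atoms$chain))
  class(s) <- "StructureModel"
  s
}

#' Van der Waals radius by element symbol
#'
#' @param element character vector of element symbols.
#' @return Numeric vector of radii in Angstrom; unknown symbols get the
#'   1.7 Angstrom default with one warning.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  r <- .vdw_table[key]
  if (anyNA(r)) {
    unk <- unique(key[is.na(r)])
    warning("unknown element(s) ", paste(unk, collapse = ", "),
            "; using default vdW radius ", .vdw_default, " A")
    r[is.na(r)] <- .vdw_default
  }
  unname(r)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s) [",
      paste(x$chains, collapse = ", "), "]\n")
  invisible(x)
}

#' Number of atoms in a structure or ensemble
#' @param x a `StructureModel` or `TrajectoryEnsemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "TrajectoryEnsemble")) x <- x$topology
  nrow(x$atoms)
}

#' Extract one chain from a complex
#'
#' The chain keeps the conformation it has inside the complex; this is
#' the "monomer in complex geometry" used by the buried-surface
#' computation.
#'
#' @param s a `StructureModel`.
#' @param chain chain identifier present in `s`.
#' @return A `StructureModel` restricted to that chain.
#' @export
extract_chain <- function(s, chain) {
  stopifnot(inherits(s, "StructureModel"))
  keep <- s$atoms$chain == chain
  if (!any(keep)) stop("chain '", chain, "' not present")
  structure_model(s$atoms[keep, , drop = FALSE],
                  s$xyz[keep, , drop = FALSE], s$vdw[keep])
}

#' Construct a trajectory ensemble
#'
#' Ordered frames sharing a topology. Coordinates are stored bio3d-style
#' as an `n_frames` x `3 n_atoms` matrix (x1, y1, z1, x2, ...). The
#' equilibrated window `eq_window` is an inclusive 1-based frame-index
#' interval `c(first, last)`; descriptor averages use only those frames.
#'
#' @param topology a `StructureModel`.
#' @param xyz numeric matrix, frames x (3 * n_atoms), Angstrom.
#' @param times optional numeric vector of frame times (ps).
#' @param eq_window integer length-2 `c(first, last)`, defaults to the
#'   full frame range.
#' @return An object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(topology, xyz, times = NULL,
                                eq_window = NULL) {
  stopifnot(inherits(topology, "StructureModel"), is.matrix(xyz))
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    stop("frame width does not match topology atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frames")
  nf <- nrow(xyz)
  if (is.null(eq_window)) eq_window <- c(1L, nf)
  eq_window <- as.integer(eq_window)
  if (length(eq_window) != 2L || eq_window[1] < 1L ||
      eq_window[2] > nf || eq_window[1] > eq_window[2])
    stop("eq_window must be c(first, last) within 1..n_frames")
  if (is.null(times)) times <- seq_len(nf) - 1
  t <- list(topology = topology, xyz = unname(xyz), times = times,
            eq_window = eq_window)
  class(t) <- "TrajectoryEnsemble"
  t
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat("TrajectoryEnsemble:", nrow(x$xyz), "frames x",
      nrow(x$topology$atoms), "atoms; eq_window [",
      x$eq_window[1], ",", x$eq_window[2], "]\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param t a `TrajectoryEnsemble`.
#' @return integer frame count.
#' @export
n_frames <- function(t) nrow(t$xyz)

#' Coordinates of one frame as a StructureModel
#' @param t a `TrajectoryEnsemble`.
#' @param i frame index (1-based).
#' @return A `StructureModel` with the topology's atoms at frame `i`.
#' @export
frame_structure <- function(t, i) {
  stopifnot(inherits(t, "TrajectoryEnsemble"), i >= 1, i <= nrow(t$xyz))
  xyz <- matrix(t$xyz[i, ], ncol = 3, byrow = TRUE)
  structure_model(t$topology$atoms, xyz, t$topology$vdw)
}

#' Indices of C-alpha atoms
#' @param s a `StructureModel` or `TrajectoryEnsemble`.
#' @return integer vector of atom indices with name `CA`.
#' @export
calpha_indices <- function(s) {
  if (inherits(s, "TrajectoryEnsemble")) s <- s$topology
  which(s$atoms$name == "CA")
}

# Guess element symbol from a PDB atom name (digits stripped; two-letter
# symbols only when they match a known element, so "CA" stays carbon).
infer_element <- function(name) {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  one <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "SE") , two, one)
}

#' Read a structure or ensemble from a PDB file
#'
#' Single-MODEL files yield a `StructureModel`; multi-MODEL files yield a
#' `TrajectoryEnsemble` whose equilibrated window defaults to the full
#' frame range. Van der Waals radii are assigned from a bundled element
#' table, inferring the element from the atom name when the element
#' column is absent.
#'
#' @param path path to a PDB file.
#' @return `StructureModel` or `TrajectoryEnsemble`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(trimws(elesy) == ""))
    elesy <- infer_element(at$elety)
  else {
    blank <- is.na(elesy) | trimws(elesy) == ""
    elesy[blank] <- infer_element(at$elety[blank])
  }
  atoms <- data.frame(serial = at$eleno, name = at$elety,
                      element = toupper(trimws(elesy)),
                      resname = at$resid, resid = at$resno,
                      chain = at$chain, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  nf <- nrow(pdb$xyz)
  topo <- structure_model(atoms,
                          matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
  if (nf == 1L) return(topo)
  trajectory_ensemble(topo, unclass(pdb$xyz))
}

#' Write a structure or ensemble to a PDB file
#'
#' Multi-frame ensembles are written as multi-MODEL PDB. Coordinates are
#' recorded to 0.001 Angstrom (the PDB fixed-format precision), so a
#' write/read round trip preserves them to that tolerance and preserves
#' chain and residue identity exactly.
#'
#' @param x a `StructureModel` or `TrajectoryEnsemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "StructureModel")) {
    topo <- x
    xyz <- matrix(as.vector(t(x$xyz)), nrow = 1)
  } else if (inherits(x, "TrajectoryEnsemble")) {
    topo <- x$topology
    xyz <- x$xyz
  } else stop("x must be a StructureModel or TrajectoryEnsemble")
  a <- topo$atoms
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial,
                   elety = a$name, resid = a$resname, resno = a$resid,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}
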
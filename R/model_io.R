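# Phosphosite bookkeeping and equilibrated-window selection.

.phospho_resnames <- c("SEP", "TPO", "PTR")

#' Describe phosphosites of a structure as a binary pattern
#'
#' Each site is a (chain, residue-number) pair; a site is scored 1 when
#' its residue carries a phospho residue code (SEP for phospho-serine;
#' TPO/PTR accepted) or is listed in `flagged`, else 0. Site order is
#' preserved, and site labels follow the chain.resid convention (e.g.
#' `A.45`).
#'
#' @param s a `StructureModel`.
#' @param sites data.frame with columns `chain` and `resid`, or a list of
#'   `c(chain, resid)` pairs.
#' @param flagged optional subset of `sites` (same format) to force to 1,
#'   for topologies that keep the unmodified residue name.
#' @return An object of class `PTMPattern`: list with `sites`
#'   (data.frame chain, resid, label) and `state` (0/1 integer vector).
#' @export
mark_phosphosites <- function(s, sites, flagged = NULL) {
  stopifnot(inherits(s, "StructureModel"))
  sites <- as_site_table(sites)
  flagged <- if (is.null(flagged)) sites[0, ] else as_site_table(flagged)
  state <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- s$atoms$chain == sites$chain[i] & s$atoms$resid == sites$resid[i]
    if (!any(hit))
      stop("site ", sites$chain[i], ".", sites$resid[i],
           " not found in structure")
    resname <- unique(s$atoms$resname[hit])[1]
    forced <- any(flagged$chain == sites$chain[i] &
                    flagged$resid == sites$resid[i])
    state[i] <- as.integer(resname %in% .phospho_resnames || forced)
  }
  ptm_pattern(sites, state)
}

#' Construct a PTM pattern directly from a binary state vector
#'
#' @param sites site table (see [mark_phosphosites()]).
#' @param state 0/1 vector, one entry per site.
#' @return A `PTMPattern`.
#' @export
ptm_pattern <- function(sites, state) {
  sites <- as_site_table(sites)
  state <- as.integer(state)
  if (length(state) != nrow(sites))
    stop("state length must match number of sites")
  if (!all(state %in% c(0L, 1L))) stop("state entries must be 0 or 1")
  p <- list(sites = sites, state = state)
  class(p) <- "PTMPattern"
  p
}

#' @export
print.PTMPattern <- function(x, ...) {
  cat("PTMPattern:", pattern_label(x), "\n")
  invisible(x)
}

#' Human-readable label of a PTM pattern
#'
#' Phosphorylated sites joined by `-` (e.g. `A.45-B.59`); the empty
#' pattern is labelled `noP`.
#' @param p a `PTMPattern`.
#' @return character scalar.
#' @export
pattern_label <- function(p) {
  on <- p$sites$label[p$state == 1L]
  if (!length(on)) "noP" else paste(on, collapse = "-")
}

as_site_table <- function(sites) {
  if (is.data.frame(sites)) {
    stopifnot(all(c("chain", "resid") %in% names(sites)))
    out <- data.frame(chain = as.character(sites$chain),
                      resid = as.integer(sites$resid),
                      stringsAsFactors = FALSE)
  } else if (is.list(sites)) {
    out <- data.frame(chain = vapply(sites, function(x) as.character(x[1]), ""),
                      resid = vapply(sites, function(x) as.integer(x[2]), 0L),
                      stringsAsFactors = FALSE)
  } else stop("sites must be a data.frame or list of (chain, resid) pairs")
  out$label <- if (nrow(out)) paste0(out$chain, ".", out$resid)
               else character(0)
  out
}

#' Enumerate all binary modification patterns of a site list
#'
#' For N sites returns all 2^N on/off combinations in lexicographic
#' order of the state vector (first site varying slowest), so four sites
#' give the 16 patterns of a two-chain, two-serine study.
#'
#' @param sites site table (see [mark_phosphosites()]).
#' @return List of `PTMPattern`, length `2^N`.
#' @export
enumerate_patterns <- function(sites) {
  sites <- as_site_table(sites)
  n <- nrow(sites)
  if (n < 1L) stop("at least one site is required")
  grid <- expand.grid(rep(list(c(0L, 1L)), n))[, n:1, drop = FALSE]
  lapply(seq_len(nrow(grid)),
         function(i) ptm_pattern(sites, as.integer(grid[i, ])))
}

#' Select the equilibrated portion of a trajectory
#'
#' Computes the C-alpha RMSD of every frame to `reference` after optimal
#' superposition, then scans sliding windows of `window` frames fitting
#' a linear trend: the equilibrated window starts at the first frame
#' from which every subsequent window's absolute RMSD slope stays within
#' `slope_tol` through the end of the trajectory — a deterministic
#' surrogate for judging the plateau of an RMSD plot by eye. If no such
#' frame exists the last half of the trajectory is used, with a warning.
#'
#' @param t a `TrajectoryEnsemble`.
#' @param reference a `StructureModel` (defaults to the topology).
#' @param window sliding-window length in frames; default 10% of the
#'   trajectory (minimum 3).
#' @param slope_tol maximum absolute RMSD slope, nm per frame
#'   (default 1e-4).
#' @return `t` with `eq_window` set; the RMSD series (nm) is attached as
#'   attribute `rmsd_nm`.
#' @export
select_equilibrated <- function(t, reference = t$topology,
                                window = NULL, slope_tol = 1e-4) {
  stopifnot(inherits(t, "TrajectoryEnsemble"))
  sel <- calpha_indices(t)
  if (!length(sel)) stop("no C-alpha atoms in topology")
  nf <- nrow(t$xyz)
  if (is.null(window)) window <- max(3L, ceiling(0.1 * nf))
  if (nf <= window) stop("trajectory must be longer than the window")
  ref <- t$topology$xyz[sel, , drop = FALSE]
  if (!identical(reference, t$topology)) {
    rsel <- calpha_indices(reference)
    if (length(rsel) != length(sel))
      stop("reference C-alpha count does not match trajectory")
    ref <- reference$xyz[rsel, , drop = FALSE]
  }
  rmsd_nm <- vapply(seq_len(nf), function(i) {
    rmsd_fit(frame_coords(t$xyz, i, sel), ref) / 10
  }, 0)
  n_win <- nf - window + 1L
  x <- seq_len(window)
  sxx <- sum((x - mean(x))^2)
  slopes <- vapply(seq_len(n_win), function(i) {
    y <- rmsd_nm[i:(i + window - 1L)]
    sum((x - mean(x)) * (y - mean(y))) / sxx
  }, 0)
  flat <- abs(slopes) <= slope_tol
  # first window index from which flatness holds to the end
  ok <- rev(cumprod(rev(flat))) > 0
  if (any(ok)) {
    start <- which(ok)[1]
  } else {
    warning("no RMSD plateau found; falling back to the last half")
    start <- floor(nf / 2) + 1L
  }
  t$eq_window <- c(as.integer(start), nf)
  attr(t, "rmsd_nm") <- rmsd_nm
  t
}

# Frame indices of the equilibrated window.
eq_frames <- function(t) seq.int(t$eq_window[1], t$eq_window[2])
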
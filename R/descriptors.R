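# Assembly of the nine-descriptor vector for one system: five
# trajectory-averaged terms (total/hydrophobic/buried SASA, inter-chain
# hydrogen bonds, inter-chain LJ energy), two static interface terms
# evaluated on the representative conformation (gap volume, gap index),
# and two landscape stability markers (AbsMin, number of basins).

# canonical descriptor order; display names follow the field's labels
.descriptor_names <- c("total_sas", "hydrophobic_sas", "buried_sas",
                       "hb", "gap_index", "volume", "e_lj",
                       "abs_min", "n_min")
.descriptor_labels <- c("Total SAS", "Hydrophobic SAS", "Buried SAS",
                        "HB", "Gap_Index", "Volume", "E_LJ",
                        "AbsMin", "#Min")

#' Names of the nine general descriptors
#' @param display return the display labels used in tables (default
#'   machine-friendly names).
#' @return character vector of length 9.
#' @export
descriptor_names <- function(display = FALSE) {
  if (display) .descriptor_labels else .descriptor_names
}

#' Descriptor configuration
#'
#' Bundles the tunable parameters of the descriptor layer.
#'
#' @param probe SASA probe radius, Angstrom.
#' @param n_points SASA sphere-sampling density.
#' @param hbond an [hbond_criteria()] object.
#' @param lj an [lj_params()] object.
#' @param lj_cut LJ pair cutoff, Angstrom.
#' @param cluster_cutoff GROMOS RMSD cutoff, nm.
#' @param grid_interval gap-sphere voxel edge, Angstrom.
#' @param distance_cutoff gap-sphere pair cutoff, Angstrom.
#' @param n_bins landscape grid size.
#' @param box landscape window edge, cells.
#' @param minima_frac basin threshold as a fraction of the deepest
#'   basin's occupancy.
#' @param stride analyse every `stride`-th equilibrated frame in the
#'   trajectory averages (default 1 = all).
#' @return list of class `descriptor_config`.
#' @export
descriptor_config <- function(probe = 1.4, n_points = 960,
                              hbond = hbond_criteria(),
                              lj = lj_params(), lj_cut = 10,
                              cluster_cutoff = 0.3,
                              grid_interval = 0.8, distance_cutoff = 5,
                              n_bins = 20, box = 3, minima_frac = 0.7,
                              stride = 1L) {
  structure(as.list(environment()), class = "descriptor_config")
}

#' Trajectory-averaged structural and energetic descriptors
#'
#' Averages the per-frame terms — total, hydrophobic and buried SASA,
#' inter-chain hydrogen-bond count and inter-chain LJ energy — over the
#' frames of the equilibrated window. The hydrogen-bond entry is the
#' mean count per frame and is therefore real-valued.
#'
#' @param t a `TrajectoryEnsemble` with `eq_window` set.
#' @param cfg a [descriptor_config()].
#' @return Named numeric vector: `total_sas`, `hydrophobic_sas`,
#'   `buried_sas`, `hb`, `e_lj`.
#' @export
trajectory_mean_descriptors <- function(t, cfg = descriptor_config()) {
  stopifnot(inherits(t, "TrajectoryEnsemble"))
  fr <- eq_frames(t)
  fr <- fr[seq(1, length(fr), by = max(1L, as.integer(cfg$stride)))]
  if (!length(fr)) stop("equilibrated window is empty")
  acc <- matrix(0, length(fr), 5,
                dimnames = list(NULL, c("total_sas", "hydrophobic_sas",
                                        "buried_sas", "hb", "e_lj")))
  for (i in seq_along(fr)) {
    s <- frame_structure(t, fr[i])
    acc[i, "total_sas"] <- compute_sas(s, probe = cfg$probe,
                                       n_points = cfg$n_points)
    acc[i, "hydrophobic_sas"] <- compute_sas(s, subset = "hydrophobic",
                                             probe = cfg$probe,
                                             n_points = cfg$n_points)
    acc[i, "buried_sas"] <- buried_sas(s, probe = cfg$probe,
                                       n_points = cfg$n_points)
    acc[i, "hb"] <- count_interchain_hbonds(s, cfg$hbond)
    acc[i, "e_lj"] <- interchain_lj_energy(s, cfg$lj, cfg$lj_cut)
  }
  colMeans(acc)
}

#' Full nine-descriptor vector for one system
#'
#' Runs the whole descriptor pipeline on one conformational ensemble:
#' trajectory averages over the equilibrated window, gap-sphere analysis
#' of the representative conformation selected by GROMOS clustering, and
#' the landscape markers from essential dynamics.
#'
#' @param t a `TrajectoryEnsemble` with `eq_window` set.
#' @param cfg a [descriptor_config()].
#' @return Named numeric vector of length 9 in the canonical order
#'   (see [descriptor_names()]).
#' @export
compute_descriptors <- function(t, cfg = descriptor_config()) {
  avg <- trajectory_mean_descriptors(t, cfg)
  rep_s <- representative_structure(t, cfg$cluster_cutoff)
  gap <- suppressWarnings(
    gap_analysis(rep_s, grid_interval = cfg$grid_interval,
                 distance_cutoff = cfg$distance_cutoff,
                 n_points = cfg$n_points))
  fel <- build_fel(t, n_bins = cfg$n_bins, box = cfg$box)
  nm <- as.integer(count_minima(fel, frac = cfg$minima_frac))
  out <- c(avg["total_sas"], avg["hydrophobic_sas"], avg["buried_sas"],
           avg["hb"], gap_index = gap$gap_index, volume = gap$gap_volume,
           avg["e_lj"], abs_min = fel$abs_min, n_min = nm)
  names(out) <- .descriptor_names
  out
}

#' Write descriptor vectors as a CSV table
#'
#' One row per system, columns carrying the standard display labels.
#'
#' @param desc named list of descriptor vectors (names = system labels)
#'   or a matrix with 9 columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(desc, path) {
  if (is.list(desc)) desc <- do.call(rbind, desc)
  stopifnot(ncol(desc) == 9)
  df <- as.data.frame(desc)
  names(df) <- .descriptor_labels
  df <- cbind(system = rownames(desc), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
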
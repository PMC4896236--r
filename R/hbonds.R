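# Inter-chain hydrogen bonds by geometric criteria.

#' Hydrogen-bond geometric criteria
#'
#' @param da_cutoff maximum donor-acceptor distance, Angstrom.
#' @param angle_cutoff maximum hydrogen-donor-acceptor angle, degrees
#'   (the angle at the donor between the D-H and D-A directions).
#' @return list of class `HBondCriteria`.
#' @export
hbond_criteria <- function(da_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(da_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 90)
  structure(list(da_cutoff = da_cutoff, angle_cutoff = angle_cutoff),
            class = "HBondCriteria")
}

#' Count hydrogen bonds between different chains
#'
#' Donors are N/O atoms carrying a hydrogen (an H atom of the same chain
#' within 1.25 Angstrom); acceptors are N/O atoms. A donor-acceptor pair
#' on different chains is counted once when the D-A distance is within
#' `criteria$da_cutoff` and some donor hydrogen makes an H-D-A angle
#' within `criteria$angle_cutoff`. When the structure contains no
#' hydrogens (crystal-structure case) a heavy-atom fallback counts
#' N/O-N/O cross-chain pairs by distance alone.
#'
#' @param s a `StructureModel` with at least 2 chains.
#' @param criteria an [hbond_criteria()] object.
#' @return Integer bond count.
#' @export
count_interchain_hbonds <- function(s, criteria = hbond_criteria()) {
  stopifnot(inherits(s, "StructureModel"),
            inherits(criteria, "HBondCriteria"))
  if (length(s$chains) < 2L) stop("interface requires two chains")
  el <- s$atoms$element
  polar <- which(el %in% c("N", "O"))
  if (!length(polar)) return(0L)
  hyd <- which(el == "H")
  have_h <- length(hyd) > 0L
  count <- 0L
  for (d in polar) {
    if (have_h) {
      dh <- hyd[s$atoms$chain[hyd] == s$atoms$chain[d]]
      if (length(dh)) {
        dist_h <- sqrt(colSums((t(s$xyz[dh, , drop = FALSE]) - s$xyz[d, ])^2))
        dh <- dh[dist_h <= 1.25]
      }
      if (!length(dh)) next  # not a donor
    }
    acc <- polar[s$atoms$chain[polar] != s$atoms$chain[d]]
    if (!have_h) acc <- acc[acc > d]  # unordered pairs counted once
    if (!length(acc)) next
    da <- sqrt(colSums((t(s$xyz[acc, , drop = FALSE]) - s$xyz[d, ])^2))
    acc <- acc[da <= criteria$da_cutoff & da > 0]
    if (!length(acc)) next
    if (!have_h) {
      count <- count + length(acc)
      next
    }
    for (a in acc) {
      v_da <- s$xyz[a, ] - s$xyz[d, ]
      ang <- vapply(dh, function(h) {
        v_dh <- s$xyz[h, ] - s$xyz[d, ]
        cosang <- sum(v_da * v_dh) /
          sqrt(sum(v_da^2) * sum(v_dh^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }, 0)
      if (any(ang <= criteria$angle_cutoff)) count <- count + 1L
    }
  }
  count
}
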
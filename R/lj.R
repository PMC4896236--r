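# Inter-chain Lennard-Jones interaction energy (12-6, Lorentz-Berthelot
# combination). Reported as an absolute value: only relative differences
# between modification variants enter the classification.

# Minimal per-element 12-6 parameters: sigma (Angstrom), epsilon
# (kJ/mol). Coarse but adequate for ranking interface variants.
.lj_table <- data.frame(
  element = c("H", "C", "N", "O", "S", "P"),
  sigma   = c(2.50, 3.40, 3.25, 2.96, 3.56, 3.74),
  epsilon = c(0.066, 0.360, 0.711, 0.880, 1.046, 0.837),
  stringsAsFactors = FALSE
)

#' Lennard-Jones parameter set
#'
#' @param table data.frame with columns `element`, `sigma` (Angstrom)
#'   and `epsilon` (kJ/mol). Defaults to a bundled per-element table.
#' @return list of class `LJParameterSet`.
#' @export
lj_params <- function(table = .lj_table) {
  stopifnot(all(c("element", "sigma", "epsilon") %in% names(table)),
            all(table$sigma > 0), all(table$epsilon > 0))
  structure(list(table = table), class = "LJParameterSet")
}

#' Inter-chain Lennard-Jones energy
#'
#' Sums `4 eps [(sig/r)^12 - (sig/r)^6]` over all atom pairs on
#' different chains within `r_cut`, with Lorentz-Berthelot combination
#' (arithmetic sigma, geometric epsilon), and returns the absolute
#' value. Atoms whose element has no entry in the parameter table get
#' carbon parameters with a warning.
#'
#' @param s a `StructureModel` with at least 2 chains.
#' @param params an [lj_params()] object.
#' @param r_cut pair cutoff, Angstrom (default 10).
#' @return `|E_LJ|` in kJ/mol.
#' @export
interchain_lj_energy <- function(s, params = lj_params(), r_cut = 10) {
  stopifnot(inherits(s, "StructureModel"),
            inherits(params, "LJParameterSet"))
  if (length(s$chains) < 2L) stop("interface requires two chains")
  tab <- params$table
  idx <- match(s$atoms$element, tab$element)
  if (anyNA(idx)) {
    warning("element(s) without LJ parameters: ",
            paste(unique(s$atoms$element[is.na(idx)]), collapse = ", "),
            "; using carbon defaults")
    idx[is.na(idx)] <- match("C", tab$element)
  }
  sig <- tab$sigma[idx]
  eps <- tab$epsilon[idx]
  e <- 0
  chains <- s$chains
  for (ci in seq_along(chains)) {
    ai <- which(s$atoms$chain == chains[ci])
    for (cj in seq_len(ci - 1L)) {
      aj <- which(s$atoms$chain == chains[cj])
      d2 <- outer(rowSums(s$xyz[ai, , drop = FALSE]^2),
                  rep(1, length(aj))) -
        2 * tcrossprod(s$xyz[ai, , drop = FALSE],
                       s$xyz[aj, , drop = FALSE]) +
        outer(rep(1, length(ai)),
              rowSums(s$xyz[aj, , drop = FALSE]^2))
      d <- sqrt(pmax(d2, 0))  # guard tiny negatives from cancellation
      if (any(d < 1e-3))
        stop("clashing atoms between chains (inter-atom distance ~ 0)")
      within <- d <= r_cut
      if (!any(within)) next
      sr <- (outer(sig[ai], sig[aj], "+") / 2)[within] / d[within]
      epair <- sqrt(outer(eps[ai], eps[aj]))[within]
      e <- e + sum(4 * epair * (sr^12 - sr^6))
    }
  }
  abs(e)
}
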
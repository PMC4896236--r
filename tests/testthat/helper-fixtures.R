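# Fixture builders and independent oracles, all generated in code.

# minimal structure from explicit atoms
mini_structure <- function(xyz, element, chain,
                           name = element, resname = "GLY",
                           resid = seq_along(element), vdw = NULL) {
  atoms <- data.frame(serial = seq_along(element), name = name,
                      element = element, resname = resname,
                      resid = resid, chain = chain,
                      stringsAsFactors = FALSE)
  structure_model(atoms, xyz, vdw = vdw)
}

# two parallel atom slabs with a fixed inter-surface gap (rectangular so
# the principal axes of the gap spheres are non-degenerate)
make_slab <- function(nx = 8, ny = 12, gap = 3, spacing = 2) {
  g <- expand.grid(x = seq(0, by = spacing, length.out = nx),
                   y = seq(0, by = spacing, length.out = ny))
  r <- 1.7
  xyz <- rbind(cbind(g$x, g$y, 0), cbind(g$x, g$y, 2 * r + gap))
  n <- nx * ny
  mini_structure(xyz, element = rep("C", 2 * n),
                 chain = rep(c("A", "B"), each = n),
                 resname = "SLB")
}

# apply a rigid rotation + translation to a structure
rigid_move <- function(s, angles = c(0.7, 0.4), shift = c(5, -3, 11)) {
  th <- angles[1]; ph <- angles[2]
  R1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  s$xyz <- sweep(s$xyz %*% R1 %*% R2, 2, shift, "+")
  s
}

# analytic accessible area of two intersecting probe-expanded spheres
two_sphere_sas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# brute-force inter-chain 12-6 energy: naive double loop
lj_brute <- function(s, r_cut = 10) {
  tab <- ptmscope::lj_params()$table
  idx <- match(s$atoms$element, tab$element)
  e <- 0
  for (i in seq_len(nrow(s$atoms))) {
    for (j in seq_len(i - 1)) {
      if (s$atoms$chain[i] == s$atoms$chain[j]) next
      r <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
      if (r > r_cut) next
      sig <- (tab$sigma[idx[i]] + tab$sigma[idx[j]]) / 2
      eps <- sqrt(tab$epsilon[idx[i]] * tab$epsilon[idx[j]])
      e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
  }
  abs(e)
}

# reference GROMOS clustering straight from an RMSD matrix (nm)
gromos_reference <- function(D, cutoff) {
  nf <- nrow(D)
  labels <- integer(nf)
  remaining <- seq_len(nf)
  cl <- 0
  while (length(remaining)) {
    best <- remaining[1]; nbest <- -1
    for (f in remaining) {
      nn <- sum(D[f, remaining] <= cutoff)
      if (nn > nbest) { nbest <- nn; best <- f }
    }
    members <- remaining[D[best, remaining] <= cutoff]
    cl <- cl + 1
    labels[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  labels
}

# ensemble whose frames alternate between two fixed conformations
# separated by `rmsd_A` Angstrom of C-alpha RMSD (breathing-mode
# displacement, orthogonal to rigid-body motion)
two_conformer_ensemble <- function(s, n_major = 6, n_minor = 4,
                                   rmsd_A = 10) {
  sel <- calpha_indices(s)
  ref <- as.vector(t(s$xyz))
  mode <- rep(0, length(ref))
  sgn <- rep_len(c(1, -1), length(sel))
  sgn <- sgn - mean(sgn)
  mode[3 * sel] <- sgn                   # z displacements
  mode <- mode / sqrt(sum(mode[3 * sel]^2) / length(sel))  # unit rmsd
  xyz <- rbind(matrix(ref, n_major, length(ref), byrow = TRUE),
               matrix(ref + rmsd_A * mode, n_minor, length(ref),
                      byrow = TRUE))
  trajectory_ensemble(s, xyz)
}

# adjusted Rand index (prefers mclust when present)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  (nij - ai * bj / n2) / ((ai + bj) / 2 - ai * bj / n2)
}

# four-site table of a two-chain, two-serine study
four_sites <- function() {
  data.frame(chain = c("A", "A", "B", "B"), resid = c(45, 59, 45, 59))
}
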
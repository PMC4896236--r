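test_that("SASA matches analytic sphere areas", {
  # isolated probe-expanded sphere
  s1 <- mini_structure(matrix(c(0, 0, 0), 1), "O", "A", vdw = 1.4)
  expect_equal(compute_sas(s1), 4 * pi * 2.8^2, tolerance = 1e-6)

  # two distant atoms: no occlusion
  s2 <- mini_structure(rbind(c(0, 0, 0), c(100, 0, 0)), c("O", "C"), "A")
  expect_equal(compute_sas(s2),
               4 * pi * (1.52 + 1.4)^2 + 4 * pi * (1.7 + 1.4)^2,
               tolerance = 1e-6)

  # two overlapping spheres vs the closed-form union area
  s3 <- mini_structure(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"), "A")
  expect_equal(compute_sas(s3, n_points = 960),
               two_sphere_sas(1.7, 1.7, 2),
               tolerance = 0.01)
})

test_that("hydrophobic SASA never exceeds total SASA", {
  for (seed in 1:5) {
    s <- make_toy_dimer(n_res = 4, separation = runif(1, 0, 6),
                        seed = seed)
    tot <- compute_sas(s, n_points = 240)
    hyd <- compute_sas(s, subset = "hydrophobic", n_points = 240)
    expect_gte(hyd, 0)
    expect_lte(hyd, tot)
  }
})

test_that("buried SASA follows the monomer/complex decomposition", {
  far <- make_toy_dimer(n_res = 4, separation = 100, seed = 2)
  expect_lt(abs(buried_sas(far, n_points = 240)), 0.5)

  s <- make_toy_dimer(n_res = 4, separation = 1, seed = 2)
  b <- buried_sas(s, n_points = 240)
  expect_gt(b, 0)
  # compositional oracle: three independent SASA calls
  oracle <- compute_sas(s, chain = "A", n_points = 240) +
    compute_sas(s, chain = "B", n_points = 240) -
    compute_sas(s, n_points = 240)
  expect_equal(b, oracle, tolerance = 1e-10)

  expect_error(buried_sas(extract_chain(s, "A")), "two chains")
})

test_that("buried SASA decreases monotonically with chain separation", {
  seps <- seq(0, 20, by = 2)
  b <- vapply(seps, function(sp) {
    buried_sas(make_toy_dimer(n_res = 4, separation = sp, seed = 3),
               n_points = 240)
  }, 0)
  expect_true(all(diff(b) <= 1e-6))
  expect_lt(b[length(b)], 0.5)
})

test_that("hydrogen bonds obey the geometric criteria and chain rule", {
  # N-H...O across chains: d = 2.85 A, small angle -> one bond
  tri <- mini_structure(rbind(c(0, 0, 0), c(0, 0, 1), c(0.4, 0, 2.82)),
                        c("N", "H", "O"), c("A", "A", "B"))
  expect_equal(count_interchain_hbonds(tri), 1L)

  # identical donor/acceptor geometry within one chain: not counted
  intra <- mini_structure(rbind(c(0, 0, 0), c(0, 0, 1), c(0.4, 0, 2.82),
                                c(50, 0, 0)),
                          c("N", "H", "O", "C"),
                          c("A", "A", "A", "B"))
  expect_equal(count_interchain_hbonds(intra), 0L)

  # beyond the distance cutoff
  farp <- mini_structure(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 4.0)),
                         c("N", "H", "O"), c("A", "A", "B"))
  expect_equal(count_interchain_hbonds(farp), 0L)

  # bad angle: acceptor perpendicular to the D-H direction
  bad <- mini_structure(rbind(c(0, 0, 0), c(0, 0, 1), c(2.9, 0, 0)),
                        c("N", "H", "O"), c("A", "A", "B"))
  expect_equal(count_interchain_hbonds(bad), 0L)

  # heavy-atom fallback when no hydrogens are present
  heavy <- mini_structure(rbind(c(0, 0, 0), c(0, 0, 3.2)),
                          c("N", "O"), c("A", "B"))
  expect_equal(count_interchain_hbonds(heavy), 1L)
})

test_that("LJ energy has its 12-6 root and minimum where expected", {
  tab <- lj_params()$table
  sig <- tab$sigma[tab$element == "C"]
  eps <- tab$epsilon[tab$element == "C"]
  at_r <- function(r) mini_structure(rbind(c(0, 0, 0), c(r, 0, 0)),
                                     c("C", "C"), c("A", "B"))
  expect_equal(interchain_lj_energy(at_r(sig)), 0, tolerance = 1e-10)
  expect_equal(interchain_lj_energy(at_r(2^(1 / 6) * sig)), eps,
               tolerance = 1e-10)
  expect_error(interchain_lj_energy(at_r(1e-9)), "clash")
})

test_that("LJ energy matches a brute-force pair loop and is invariant", {
  s <- make_toy_dimer(n_res = 2, separation = 1, seed = 4)  # 10 atoms/chain
  e <- interchain_lj_energy(s)
  expect_equal(e, lj_brute(s), tolerance = 1e-10)

  # rigid motion invariance
  expect_equal(interchain_lj_energy(rigid_move(s)), e, tolerance = 1e-8)

  # chain relabeling symmetry
  s2 <- s
  s2$atoms$chain <- ifelse(s$atoms$chain == "A", "B", "A")
  s2$chains <- rev(s$chains)
  expect_equal(interchain_lj_energy(s2), e, tolerance = 1e-12)
})

test_that("trajectory averages equal per-frame recomputation", {
  s <- make_toy_dimer(n_res = 3, separation = 1.5, seed = 5)
  cfg <- descriptor_config(n_points = 120)

  # constant ensemble: mean equals the single-frame value
  ref <- as.vector(t(s$xyz))
  tc <- trajectory_ensemble(s, matrix(ref, 4, length(ref), byrow = TRUE))
  mc <- trajectory_mean_descriptors(tc, cfg)
  expect_equal(unname(mc["total_sas"]), compute_sas(s, n_points = 120),
               tolerance = 1e-10)
  expect_equal(unname(mc["buried_sas"]), buried_sas(s, n_points = 120),
               tolerance = 1e-10)

  # jittered ensemble vs mean-of-frames oracle
  t <- make_harmonic_ensemble(s, c(0.5, 0.2), n_frames = 6, seed = 6)
  m <- trajectory_mean_descriptors(t, cfg)
  per_frame <- sapply(1:6, function(i) {
    f <- frame_structure(t, i)
    c(compute_sas(f, n_points = 120), buried_sas(f, n_points = 120),
      interchain_lj_energy(f))
  })
  expect_equal(unname(m["total_sas"]), mean(per_frame[1, ]),
               tolerance = 1e-10)
  expect_equal(unname(m["buried_sas"]), mean(per_frame[2, ]),
               tolerance = 1e-10)
  expect_equal(unname(m["e_lj"]), mean(per_frame[3, ]),
               tolerance = 1e-10)

  # averaging only uses the equilibrated window
  t$eq_window <- c(3L, 6L)
  m2 <- trajectory_mean_descriptors(t, cfg)
  expect_equal(unname(m2["total_sas"]), mean(per_frame[1, 3:6]),
               tolerance = 1e-10)
})

test_that("full descriptor vector is complete and within bounds", {
  s <- make_toy_dimer(n_res = 4, separation = 1.5, seed = 7)
  t <- make_harmonic_ensemble(s, c(1, 0.5), n_frames = 30, seed = 7)
  d <- compute_descriptors(t, descriptor_config(n_points = 120))
  expect_named(d, descriptor_names())
  expect_gte(d["total_sas"], d["hydrophobic_sas"])
  expect_gte(d["e_lj"], 0)
  expect_gt(d["abs_min"], 0)
  expect_lte(d["abs_min"], 1)
  expect_gte(d["n_min"], 1)
})
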
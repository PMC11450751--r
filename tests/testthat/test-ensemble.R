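rigid_copy <- function(structure, theta = 0.6, shift = c(3, -2, 5)) {
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  set_coords(structure, sweep(coords(structure$atoms) %*% t(R), 2, shift, `+`))
}

test_that("superposition is exact on self and on rigid copies", {
  s <- build_peptide("ADKLY", "A")
  self <- superpose(s, s)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  moved <- rigid_copy(s)
  sp <- superpose(moved, s)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # the fit never returns a reflection, even for a mirrored target
  mirr <- set_coords(s, coords(s$atoms) %*% diag(c(-1, 1, 1)))
  expect_equal(det(superpose(mirr, s)$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(build_peptide("AD", "A"), s), "mismatch")
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  s <- build_peptide("ADKLYT", "A")
  set.seed(9)
  pert <- set_coords(s, coords(s$atoms) +
                       matrix(rnorm(nrow(s$atoms) * 3, sd = 0.5), ncol = 3))
  ours <- superpose(pert, s)$rmsd
  ref <- bio3d::rmsd(as.vector(t(coords(s$atoms))),
                     as.vector(t(coords(pert$atoms))), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("rmsd_series starts at zero and is rigid-motion invariant", {
  base <- build_peptide("ADKLY", "A")
  const <- as_trajectory(list(base, base, base))
  expect_equal(rmsd_series(const), rep(0, 3), tolerance = 1e-9)
  ens <- make_conformers(base, ensemble_spec(k_modes = 2, n_frames = 4,
                                             sigma = 0.2, seed = 3))
  rs <- rmsd_series(ens$trajectory)
  expect_equal(rs[1], 0, tolerance = 1e-6)
  moved <- as_trajectory(lapply(ens$trajectory$frames, rigid_copy))
  expect_equal(rmsd_series(moved), rs, tolerance = 1e-6)
  expect_error(rmsd_series(as_trajectory(list())), "empty")
})

test_that("two-frame RMSD matches the hand value for a single moved atom", {
  # 5 identical CA atoms; one frame moves one atom by 1 A along x.  With
  # superposition disabled by symmetry this cannot be arranged exactly, so
  # check against the brute-force optimal-fit value computed independently.
  base <- build_peptide("GGGGG", "A")
  x <- coords(base$atoms)
  sel <- atom_res_keys(base$atoms) == "A:3" & base$atoms$elety == "CA"
  x2 <- x; x2[sel, 1] <- x2[sel, 1] + 1
  f2 <- set_coords(base, x2)
  rs <- rmsd_series(as_trajectory(list(base, f2)), selection = "c_alpha")
  ref <- bio3d::rmsd(as.vector(t(x[base$atoms$elety == "CA", ])),
                     as.vector(t(x2[base$atoms$elety == "CA", ])), fit = TRUE)
  expect_equal(rs[2], ref, tolerance = 1e-3)
  # without any fit the displacement would give sqrt(1/5); the fitted value
  # can only be smaller
  expect_lte(rs[2], sqrt(1 / 5) + 1e-9)
})

test_that("rmsf is zero for constant input and recovers a planted
           oscillation", {
  base <- build_peptide("GGGGG", "A")
  expect_warning(rf1 <- rmsf_per_residue(as_trajectory(list(base))),
                 "single-frame")
  expect_equal(rf1$rmsf, rep(0, 5), tolerance = 1e-9)
  const <- as_trajectory(list(base, base, base))
  expect_equal(rmsf_per_residue(const)$rmsf, rep(0, 5), tolerance = 1e-9)

  # one residue oscillating +-d along x in a long chain: its RMSF tends to d
  # (exact up to the tiny refitting of the shared frame)
  long <- build_peptide(strrep("G", 15), "A")
  d <- 0.6
  frames <- lapply(1:10, function(k) {
    x <- coords(long$atoms)
    sel <- atom_res_keys(long$atoms) == "A:8"
    x[sel, 1] <- x[sel, 1] + d * (-1)^k
    set_coords(long, x)
  })
  rf <- rmsf_per_residue(as_trajectory(frames))
  expect_lt(abs(rf$rmsf[rf$resno == 8] - d), 0.05)
  expect_lt(max(rf$rmsf[rf$resno != 8]), 0.1)
  # matches the brute-force definition computed on the fitted coordinates
  expect_gt(rf$rmsf[rf$resno == 8], max(rf$rmsf[rf$resno != 8]))
})

test_that("featurization yields bounded dihedral features and stable
           column counts", {
  s <- build_peptide("ADKLYSGT", "A")
  tr <- as_trajectory(list(s, s))
  X <- featurize(tr)
  n_dihed <- 8 - 2           # both neighbours required
  n_pairs <- choose(8, 2)
  expect_equal(ncol(X), 4 * n_dihed + n_pairs)
  ang <- X[, grep("^(phi|psi)_", colnames(X)), drop = FALSE]
  expect_true(all(ang >= -1 & ang <= 1))
  # the extended strand has phi/psi near 180 degrees: sines vanish
  expect_lt(max(abs(X[1, grep("_sin_", colnames(X))])), 1e-6)
  # identical frames give zero-variance columns
  expect_equal(max(apply(X, 2, stats::sd)), 0)
  expect_error(featurize(tr, residues = "A:99"), "unknown residue")
})

test_that("select_representatives recovers planted partitions and picks
           hub frames", {
  ens <- make_conformers(build_peptide("ADKLYSGT", "A"),
                         ensemble_spec(k_modes = 3, n_frames = 15,
                                       sigma = 0.25, seed = 5))
  X <- featurize(ens$trajectory)
  em <- select_representatives(X, k_range = 2:6, seed = 1)
  expect_equal(em$n_clusters, 3L)
  expect_gt(mclust::adjustedRandIndex(em$labels, ens$labels), 0.95)
  # representatives are members of their own clusters, nearest to the mean
  for (cl in seq_len(em$n_clusters)) {
    rep_idx <- em$representatives[cl]
    expect_equal(em$labels[rep_idx], cl)
    mu <- colMeans(em$space[em$labels == cl, , drop = FALSE])
    d_rep <- sum((em$space[rep_idx, ] - mu)^2)
    d_all <- apply(em$space[em$labels == cl, , drop = FALSE], 1,
                   function(r) sum((r - mu)^2))
    expect_lte(d_rep, min(d_all) + 1e-12)
  }
  # determinism under a fixed seed
  em2 <- select_representatives(X, k_range = 2:6, seed = 1)
  expect_identical(em$labels, em2$labels)
  expect_identical(em$representatives, em2$representatives)
  # optional PCA reduction still recovers the partition
  em3 <- select_representatives(X, k_range = 2:6, reduce = TRUE,
                                n_components = 3, seed = 1)
  expect_equal(em3$n_clusters, 3L)
  expect_gt(mclust::adjustedRandIndex(em3$labels, ens$labels), 0.95)
})

test_that("a single blob favours the smallest candidate k; identical frames
           degrade to one cluster with a warning", {
  ens <- make_conformers(build_peptide("ADKLYSGT", "A"),
                         ensemble_spec(k_modes = 1, n_frames = 24,
                                       sigma = 0.3, seed = 2))
  em <- select_representatives(featurize(ens$trajectory), k_range = 2:5,
                               seed = 1)
  expect_equal(em$n_clusters, 2L)
  s <- build_peptide("ADKL", "A")
  Xc <- featurize(as_trajectory(list(s, s, s, s)))
  expect_warning(em1 <- select_representatives(Xc, k_range = 2:3, seed = 1),
                 "degenerate")
  expect_equal(em1$n_clusters, 1L)
})
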
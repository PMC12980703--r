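# Trajectory model, superposition, PCA, projection and RMSF.

test_that("bead_ensemble validates its invariants", {
  expect_error(bead_ensemble(array(0, c(3, 1, 3))), "2 beads")
  expect_error(bead_ensemble(array(0, c(2, 4, 3)), frame_weights = c(-1, 1)),
               "non-negative")
  ens <- tiny_ensemble()
  expect_s3_class(ens, "BeadEnsemble")
  expect_equal(n_frames(ens), 6)
  expect_equal(n_beads(ens), 5)
  expect_equal(sum(ens$frame_weights), 6)
})

test_that("GRO write-then-read round-trips coordinates at format precision", {
  ens <- tiny_ensemble(F = 3, B = 5)
  path <- tempfile(fileext = ".gro")
  write_gro(ens, path)
  back <- load_ensemble(path)
  expect_equal(n_frames(back), 3)
  expect_equal(n_beads(back), 5)
  expect_lt(max(abs(back$coords - ens$coords)), 0.0005 + 1e-12)
  # determinism: reading twice gives identical arrays
  expect_identical(back$coords, load_ensemble(path)$coords)
})

test_that("load_ensemble reads multi-model PDB and applies bead selections", {
  ens <- tiny_ensemble(F = 3, B = 5)
  gro <- tempfile(fileext = ".gro")
  write_gro(ens, gro)
  sel <- load_ensemble(gro, bead_selection = list(from = 0, to = 3))
  expect_equal(n_beads(sel), 3)
  sel2 <- load_ensemble(gro, bead_selection = c(0L, 2L, 4L))
  expect_equal(sel2$coords[, 2, ], ens$coords[, 3, ], tolerance = 1e-3)
  expect_error(load_ensemble(gro, bead_selection = "NOPE"), "0 beads")
  expect_error(load_ensemble(tempfile(fileext = ".gro")), "not found")

  # PDB via bio3d (Angstrom -> nm)
  pdb <- tempfile(fileext = ".pdb")
  lines <- character(0)
  for (f in 1:2) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (b in 1:5)
      lines <- c(lines, sprintf(
        "ATOM  %5d  BB  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        b, b, ens$coords[f, b, 1] * 10, ens$coords[f, b, 2] * 10,
        ens$coords[f, b, 3] * 10))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), pdb)
  pens <- load_ensemble(pdb)
  expect_equal(n_frames(pens), 2)
  expect_equal(pens$coords[1, , ], ens$coords[1, , ], tolerance = 1e-3)
})

test_that("superposition recovers rigid transforms and never hurts RMSD", {
  ens <- tiny_ensemble(F = 8, B = 10, sd = 0.08, seed = 3)
  ref <- ens$coords[1, , , drop = TRUE]
  # frame equal to reference -> unchanged
  same <- bead_ensemble(array(rep(ref, each = 1), c(1, 10, 3)))
  same$coords[1, , ] <- ref
  fit <- superpose(same, ref)
  expect_equal(fit$coords[1, , ], ref, tolerance = 1e-12)

  # known rotation + translation recovered exactly
  R <- random_rotation(7)
  moved <- bead_ensemble(array(0, c(1, 10, 3)))
  moved$coords[1, , ] <- ref %*% t(R) + matrix(c(1, -2, 0.5), 10, 3,
                                               byrow = TRUE)
  rec <- superpose(moved, ref)
  expect_lt(max(abs(rec$coords[1, , ] - ref)), 1e-10)

  # optimality: post-fit RMSD <= identity-transform RMSD, every frame
  fit_all <- superpose(ens, ref)
  expect_true(all(goperturb:::rmsd_to(fit_all, ref) <=
                    goperturb:::rmsd_to(ens, ref) + 1e-12))

  # degenerate (collinear) reference flagged but still returned
  degen <- matrix(0, 10, 3); degen[, 1] <- seq_len(10)
  expect_warning(out <- superpose(ens, degen), "degenerate")
  expect_true(attr(out, "degenerate_reference"))
})

test_that("PCA recovers structure: trace, single direction, known covariance", {
  # frames displaced along a single 3B-direction -> one nonzero eigenvalue
  B <- 4
  base <- matrix(rnorm(B * 3), ncol = 3)
  dirv <- random_orthonormal(3 * B, 1, seed = 2)[, 1]
  coords <- array(0, c(10, B, 3))
  amps <- seq(-0.9, 0.9, length.out = 10)
  for (f in 1:10)
    coords[f, , ] <- base + matrix(dirv * amps[f], ncol = 3, byrow = TRUE)
  ens <- bead_ensemble(coords)
  sub <- compute_pca(ens, 3)
  expect_equal(variance_fraction(sub, 1), 1, tolerance = 1e-10)
  expect_equal(sub$eigenvalues[1], mean(amps^2) - mean(amps)^2,
               tolerance = 1e-10)

  # eigenvalue sum equals total aligned-coordinate variance
  ens2 <- tiny_ensemble(F = 30, B = 5, sd = 0.1, seed = 5)
  ens2 <- superpose(ens2, ens2$coords[1, , , drop = TRUE])
  sub2 <- compute_pca(ens2, 15)
  X <- goperturb:::flatten_frames(ens2)
  total_var <- sum(apply(X, 2, function(c) mean((c - mean(c))^2)))
  expect_equal(sub2$total_variance, total_var, tolerance = 1e-8)

  # sampling oracle: Gaussian frames with known anisotropic covariance
  B <- 3; F <- 5000
  sds <- c(0.3, 0.15, 0.05, rep(0.01, 6))
  coords <- with_seed(11, {
    arr <- array(0, c(F, B, 3))
    for (f in seq_len(F)) arr[f, , ] <- matrix(rnorm(9, sd = sds), ncol = 3,
                                               byrow = TRUE)
    arr
  })
  # no superposition: displacements are the signal itself
  sub3 <- compute_pca(bead_ensemble(coords), 3)
  expect_equal(sub3$eigenvalues[1:2], sds[1:2]^2, tolerance = 0.05)
  expect_error(compute_pca(tiny_ensemble(F = 3), 5), "more frames")
})

test_that("variance_fraction follows the eigenvalue arithmetic", {
  sub <- list(eigenvalues = c(4, 1), total_variance = 5)
  expect_equal(variance_fraction(sub, 1), 0.8)
  expect_equal(variance_fraction(sub, 2), 1)
  expect_error(variance_fraction(sub, 3), "out of range")
})

test_that("projection is exact on eigen-directions and round-trips", {
  ens <- tiny_ensemble(F = 20, B = 5, sd = 0.07, seed = 9)
  ens <- superpose(ens, ens$coords[1, , , drop = TRUE])
  sub <- compute_pca(ens, 15)

  # mean structure projects to zero
  mens <- bead_ensemble(array(0, c(1, 5, 3)))
  mens$coords[1, , ] <- sub$mean_structure
  expect_lt(max(abs(project(mens, sub, superpose_first = FALSE)$points)), 1e-10)

  # mean + c * eigenvector 1 -> (c, 0, 0, ...)
  cns <- 0.17
  shifted <- mens
  shifted$coords[1, , ] <- sub$mean_structure +
    matrix(sub$eigenvectors[, 1] * cns, ncol = 3, byrow = TRUE)
  pr <- project(shifted, sub, superpose_first = FALSE)
  expect_equal(pr$points[1, 1], cns, tolerance = 1e-10)
  expect_lt(max(abs(pr$points[1, -1])), 1e-10)

  # full-rank reconstruction round-trip
  pr_all <- project(ens, sub, superpose_first = FALSE)
  rec <- reconstruct_frame(sub, pr_all$points[4, ])
  expect_lt(max(abs(rec - ens$coords[4, , ])), 1e-8)
})

test_that("rmsf matches the closed-form Gaussian oracle and drops rigid motion", {
  # static trajectory -> zeros
  static <- bead_ensemble(array(rep(1:15, each = 4) / 10, c(4, 5, 3)))
  expect_equal(rmsf(static), rep(0, 5), tolerance = 1e-12)

  # isotropic jitter sigma = 0.05 -> rmsf = sqrt(3) * 0.05 within 3%
  F <- 10000; B <- 4
  coords <- with_seed(13, {
    base <- matrix(seq_len(B * 3), ncol = 3)
    arr <- array(0, c(F, B, 3))
    for (f in seq_len(F)) arr[f, , ] <- base + matrix(rnorm(B * 3, sd = 0.05),
                                                      ncol = 3)
    arr
  })
  prof <- rmsf(bead_ensemble(coords))
  expect_equal(prof, rep(sqrt(3) * 0.05, B), tolerance = 0.03)

  # rigid-body copies of one frame vanish after superposition
  base <- tiny_ensemble(F = 1, B = 6, sd = 0.2, seed = 21)$coords[1, , ]
  arr <- array(0, c(5, 6, 3))
  for (f in 1:5) {
    R <- random_rotation(30 + f)
    arr[f, , ] <- base %*% t(R) + matrix(rnorm(3), 6, 3, byrow = TRUE)
  }
  moved <- superpose(bead_ensemble(arr), base)
  expect_lt(max(rmsf(moved)), 1e-8)
  expect_warning(rmsf(bead_ensemble(arr[1, , , drop = FALSE])), "single-frame")
})

test_that("rmsf_aue is the mean unsigned difference", {
  expect_equal(rmsf_aue(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(rmsf_aue(rep(0.1, 4), rep(0.12, 4)), 0.02)
  expect_equal(rmsf_aue(c(0.1, 0.2, 0.3), c(0.2, 0.2, 0.1)), 0.1)
  expect_error(rmsf_aue(1:3, 1:4), "length")
})

test_that("rmsf is invariant under global rotation when superposed first", {
  ens <- tiny_ensemble(F = 40, B = 5, sd = 0.06, seed = 17)
  ref <- ens$coords[1, , , drop = TRUE]
  prof1 <- rmsf(superpose(ens, ref))
  R <- random_rotation(5)
  rot <- ens
  for (f in seq_len(n_frames(ens))) rot$coords[f, , ] <- ens$coords[f, , ] %*% t(R)
  prof2 <- rmsf(superpose(rot, ref))
  expect_equal(prof1, prof2, tolerance = 1e-8)
})
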
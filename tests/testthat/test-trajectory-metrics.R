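make_rigid_pair <- function(n = 10, seed = 3) {
  set.seed(seed)
  ref <- matrix(rnorm(n * 3, sd = 4), ncol = 3)
  ang <- pi / 2
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  list(ref = ref, moved = sweep(ref %*% t(Rz), 2, c(5, 5, 5), `+`))
}

test_that("superposition recovers rigid motions exactly", {
  p <- make_rigid_pair()
  expect_equal(kabsch_superpose(p$ref, p$ref)$rmsd, 0, tolerance = 1e-12)
  fit <- kabsch_superpose(p$moved, p$ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$coords, p$ref, tolerance = 1e-10)
})

test_that("superposition RMSD matches a rotation grid search and never
           exceeds the unfitted centered RMSD", {
  set.seed(41)
  for (rep in 1:4) {
    A <- matrix(rnorm(30, sd = 3), ncol = 3)
    B <- matrix(rnorm(30, sd = 3), ncol = 3)
    got <- kabsch_superpose(A, B)$rmsd
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    centered <- sqrt(mean(rowSums((Ac - Bc)^2)))
    expect_lte(got, centered + 1e-12)
    expect_equal(got, gridsearch_rmsd(A, B), tolerance = 1e-3)
    expect_lte(got, gridsearch_rmsd(A, B) + 1e-6)  # optimum, not just close
  }
})

test_that("superposition rejects degenerate geometry", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 masked atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + rnorm(15, sd = 1e-14), line),
               "collinear")
})

test_that("superposition agrees with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(17)
  A <- matrix(rnorm(36, sd = 2), ncol = 3)
  B <- matrix(rnorm(36, sd = 2), ncol = 3)
  got <- kabsch_superpose(A, B)$rmsd
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)),
                   mobile = matrix(as.vector(t(A)), nrow = 1)))
  want <- bio3d::rmsd(as.vector(t(B)), xyz_fit)
  # bio3d rounds fitted coordinates to PDB precision
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("RMSD series is zero for constant or rigidly rotating trajectories", {
  tr <- make_trajectory(n_residues = 8, n_frames = 6, sigma = 0, seed = 5)
  expect_equal(rmsd_series(tr)$rmsd, rep(0, 6), tolerance = 1e-10)

  # frames that are rigid motions of frame 0
  rot <- make_trajectory(n_residues = 8, n_frames = 6, sigma = 0,
                         rotate = TRUE, seed = 5)
  expect_equal(rmsd_series(rot)$rmsd, rep(0, 6), tolerance = 1e-8)
})

test_that("RMSD series starts at zero and matches frame-wise recomputation", {
  tr <- make_trajectory(n_residues = 10, n_frames = 20, sigma = 1, seed = 6)
  s <- rmsd_series(tr, "calpha")
  expect_equal(s$rmsd[1], 0, tolerance = 1e-12)
  expect_equal(s$frame, 0:19)
  expect_equal(s$time, (0:19) * tr$dt)
  mask <- select_atoms(tr, "calpha")
  ref <- matrix(tr$coords[1, , ], ncol = 3)
  direct <- vapply(1:20, function(f) {
    kabsch_superpose(matrix(tr$coords[f, , ], ncol = 3), ref, mask)$rmsd
  }, numeric(1))
  expect_equal(s$rmsd, direct)
})

test_that("two-frame oscillation of one residue gives RMSF ~ amplitude", {
  set.seed(8)
  n <- 100
  ref <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
  a <- 0.3
  f1 <- ref; f2 <- ref
  f1[7, 1] <- ref[7, 1] + a
  f2[7, 1] <- ref[7, 1] - a
  tr <- md_trajectory(list(f1, f2),
                      tibble::tibble(name = "CA", resid = 1:n), dt = 1)
  r <- rmsf_per_residue(tr, "calpha")
  expect_equal(r$rmsf[7], a, tolerance = 0.02)        # fit leakage is O(1/n)
  expect_lt(max(r$rmsf[-7]), 0.02 * a + 0.01)
  expect_equal(rmsf_per_residue(make_trajectory(n_residues = 5, n_frames = 4,
                                                sigma = 0, seed = 1))$rmsf,
               rep(0, 5), tolerance = 1e-10)
  expect_error(rmsf_per_residue(make_trajectory(n_residues = 5, n_frames = 1,
                                                seed = 1)), "2 frames")
})

test_that("planted fluctuation amplitudes are recovered by RMSF", {
  sig <- seq(0.7, 1.5, length.out = 60)
  tr <- make_trajectory(n_residues = 60, n_frames = 800, sigma = sig,
                        seed = 14)
  r <- rmsf_per_residue(tr, "calpha")
  expect_lt(mean(abs(r$rmsf / sig - 1)), 0.05)
})

test_that("identical and opposed residue motions give correlation +-1", {
  # displacement patterns with zero net translation and zero net torque,
  # so the superposition fit stays at the identity: residues 1,2 move
  # identically (5,6 compensate, with r1+r2 = r5+r6), and 3,4 move
  # oppositely along their separation axis
  set.seed(10)
  ref <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0), c(6, 5, 0),
               c(1, 1, 2), c(3, -1, -2), matrix(rnorm(12, sd = 5), ncol = 3))
  nf <- 40
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    d1 <- rnorm(3, sd = 0.05)
    d2 <- rnorm(1, sd = 0.05) * c(1, 0, 0)  # along r4 - r3
    fr <- ref
    fr[1, ] <- fr[1, ] + d1
    fr[2, ] <- fr[2, ] + d1
    fr[5, ] <- fr[5, ] - d1
    fr[6, ] <- fr[6, ] - d1
    fr[3, ] <- fr[3, ] + d2
    fr[4, ] <- fr[4, ] - d2
    frames[[f]] <- fr
  }
  tr <- md_trajectory(frames, tibble::tibble(name = "CA", resid = 1:10), 1)
  C <- dccm(tr, "calpha")  # fit is the identity to second order in |d|
  expect_equal(C[1, 2], 1, tolerance = 1e-5)
  expect_equal(C[3, 4], -1, tolerance = 1e-5)
  expect_equal(C[1, 5], -1, tolerance = 1e-5)
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(unname(diag(unclass(C))), rep(1, 10))
  expect_equal(unclass(C), t(unclass(C)))
})

test_that("constant trajectory flags all residues as zero-variance", {
  tr <- make_trajectory(n_residues = 6, n_frames = 5, sigma = 0, seed = 3)
  expect_warning(C <- dccm(tr, "calpha"), "zero variance")
  expect_equal(unname(diag(unclass(C))), rep(1, 6))
  expect_true(all(unclass(C)[upper.tri(C)] == 0))
  expect_equal(attr(C, "flagged_residues"), 1:6)
})

test_that("planted block correlation is recovered by the DCCM", {
  tr <- make_trajectory(n_residues = 100, n_frames = 600, sigma = 1,
                        blocks = list(list(i = 20:25, j = 20:25, rho = 0.8)),
                        seed = 18)
  C <- dccm(tr, "calpha")
  blk <- unclass(C)[20:25, 20:25]
  expect_equal(mean(blk[upper.tri(blk)]), 0.8, tolerance = 0.1)
  off <- unclass(C)[40:60, 70:90]
  expect_lt(mean(abs(off)), 0.1)
})

test_that("PCA variance fractions are normalised, ordered and recoverable", {
  tr <- make_mode_trajectory(n_residues = 40, n_frames = 800,
                             mode_variances = c(9, 1), seed = 19)
  p <- pca_trajectory(tr, "calpha")
  vf <- p$variance_fraction
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  expect_true(all(diff(vf) <= 1e-12))
  expect_true(all(vf >= 0))
  expect_equal(vf[1], 0.9, tolerance = 0.03)
  expect_equal(vf[1] + vf[2], 1, tolerance = 1e-6)  # two planted modes only
  # projections are centred
  expect_lt(max(abs(colMeans(p$projections))), 1e-9)
  expect_error(pca_trajectory(make_trajectory(n_residues = 5, n_frames = 4,
                                              sigma = 0, seed = 1)),
               "covariance")
})

test_that("planar fluctuations put no variance on z-loaded components", {
  # planar reference + planar displacement field orthogonal to the in-plane
  # rigid motions, so the fit is the identity and z never moves
  set.seed(25)
  n <- 12
  ref <- cbind(matrix(rnorm(n * 2, sd = 4), ncol = 2), 0)
  cen <- sweep(ref, 2, colMeans(ref))
  rigid_planar <- cbind(c(rep(1, n), rep(0, n), rep(0, n)),
                        c(rep(0, n), rep(1, n), rep(0, n)),
                        c(-cen[, 2], cen[, 1], rep(0, n)))
  Qr <- qr.Q(qr(rigid_planar))
  nf <- 60
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    v <- c(rnorm(2 * n, sd = 0.1), rep(0, n))
    v <- v - Qr %*% crossprod(Qr, v)
    frames[[f]] <- ref + matrix(v, ncol = 3)
  }
  tr <- md_trajectory(frames, tibble::tibble(name = "CA", resid = 1:n), 1)
  p <- pca_trajectory(tr, "calpha")
  # z coordinates occupy the last n covariance rows (axis-major layout);
  # an independent eigendecomposition of the raw (unaligned) coordinates is
  # valid here because the field was built to leave the fit at the identity
  X <- matrix(tr$coords[, , ], nrow = nf)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nf - 1), symmetric = TRUE)
  lam_raw <- pmax(ev$values, 0)
  z_rows <- (2 * n + 1):(3 * n)
  z_frac <- colSums(ev$vectors[z_rows, , drop = FALSE]^2)
  expect_lt(sum(lam_raw[z_frac > 0.5]) / sum(lam_raw), 1e-9)
  expect_equal(p$eigenvalues[1:5], lam_raw[1:5], tolerance = 1e-4)
})

test_that("RMSD, RMSF, DCCM and PCA are invariant under global rigid motion", {
  tr <- make_trajectory(n_residues = 20, n_frames = 80, sigma = 1,
                        blocks = list(list(i = 3:6, j = 3:6, rho = 0.6)),
                        seed = 33)
  tr2 <- rigid_motion(tr)
  expect_equal(rmsd_series(tr2)$rmsd, rmsd_series(tr)$rmsd, tolerance = 1e-6)
  expect_equal(rmsf_per_residue(tr2)$rmsf, rmsf_per_residue(tr)$rmsf,
               tolerance = 1e-6)
  expect_equal(unclass(dccm(tr2)), unclass(dccm(tr)), tolerance = 1e-6)
  expect_equal(pca_trajectory(tr2)$variance_fraction,
               pca_trajectory(tr)$variance_fraction, tolerance = 1e-6)
})

test_that("residue cross-correlations agree with the bio3d implementation", {
  skip_if_not_installed("bio3d")
  tr <- make_trajectory(n_residues = 15, n_frames = 120, sigma = 1,
                        blocks = list(list(i = 2:5, j = 2:5, rho = 0.7)),
                        seed = 44)
  mask <- select_atoms(tr, "calpha")
  # hand bio3d the already-superposed coordinates so both sides see the
  # same frames and only the correlation computation is compared
  al <- proxidyn:::.align_to_mean(tr, mask)
  xyz <- t(vapply(seq_len(n_frames(tr)), function(f) {
    as.vector(t(matrix(al$coords[f, , ], ncol = 3)))
  }, numeric(3 * 15)))
  want <- bio3d::dccm(xyz)
  got <- dccm(tr, "calpha")
  expect_equal(unclass(got), unclass(want), tolerance = 1e-6,
               ignore_attr = TRUE)
})
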
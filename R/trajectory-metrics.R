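#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation of `mobile` that minimises the
#' RMSD to `reference` over the masked atoms (reflections are corrected via
#' the determinant sign), then applies the transform to every atom of
#' `mobile`.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices with identical
#'   atom ordering.
#' @param mask Integer atom indices used to fit the transform (default: all).
#' @return A list with `coords` (the transformed mobile frame) and `rmsd`
#'   (the minimised masked RMSD, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, identical(dim(mobile), dim(reference)))
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (length(mask) < 3L) {
    stop("superposition needs at least 3 masked atoms", call. = FALSE)
  }
  P <- mobile[mask, , drop = FALSE]
  Q <- reference[mask, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))             # H = Pc' Qc
  # collinear masked atoms leave the rotation about the line undetermined
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-300)) {
    stop("degenerate (collinear) masked geometry", call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u) # p -> R p
  out <- sweep(mobile, 2, cp) %*% t(R)
  out <- sweep(out, 2, cq, FUN = "+")
  rmsd <- sqrt(mean(rowSums((out[mask, , drop = FALSE] - Q)^2)))
  list(coords = out, rmsd = rmsd)
}

# Superpose every frame of a trajectory onto a reference frame matrix using
# the mask; returns the aligned coordinate array.
.align_frames <- function(traj, ref, mask) {
  arr <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    arr[f, , ] <- kabsch_superpose(frame_coords(traj, f), ref, mask)$coords
  }
  arr
}

# Align to frame 1, compute the mean structure, re-align to the mean
# (one iteration); returns list(coords = aligned array, mean = mean matrix).
.align_to_mean <- function(traj, mask) {
  a1 <- .align_frames(traj, frame_coords(traj, 1), mask)
  mean1 <- apply(a1, c(2, 3), mean)
  t2 <- md_trajectory(a1, traj$atoms, traj$dt)
  a2 <- .align_frames(t2, mean1, mask)
  list(coords = a2, mean = apply(a2, c(2, 3), mean))
}

#' Per-frame RMSD relative to the first frame
#'
#' Each frame is superposed on frame 1 over the masked atoms before the RMSD
#' is taken over those atoms; the first value is therefore 0.
#'
#' @param traj An [md_trajectory()].
#' @inheritParams select_atoms
#' @return A tibble with `frame` (0-based), `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection = "backbone", residues = NULL) {
  mask <- select_atoms(traj, selection, residues)
  ref <- frame_coords(traj, 1)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f), ref, mask)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)) - 1L,
                 time = (seq_len(n_frames(traj)) - 1L) * traj$dt,
                 rmsd = vals)
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed on the mean structure (align to frame 1, compute
#' mean, re-align to the mean), then for every masked atom
#' `RMSF = sqrt(mean_frames |r - <r>|^2)`; a residue's value is the
#' root-mean-square of its atoms' RMSFs.
#'
#' @inheritParams rmsd_series
#' @return A tibble with `resid` and `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = "backbone", residues = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames", call. = FALSE)
  mask <- select_atoms(traj, selection, residues)
  al <- .align_to_mean(traj, mask)
  dev2 <- matrix(0, nrow = n_frames(traj), ncol = length(mask))
  for (f in seq_len(n_frames(traj))) {
    d <- matrix(al$coords[f, mask, ], ncol = 3) - al$mean[mask, , drop = FALSE]
    dev2[f, ] <- rowSums(d^2)
  }
  atom_msf <- colMeans(dev2)
  resid <- traj$atoms$resid[mask]
  res_ids <- sort(unique(resid))
  tibble::tibble(resid = res_ids,
                 rmsf = as.numeric(sqrt(tapply(atom_msf, resid, mean))[
                   as.character(res_ids)]))
}

#' Dynamic cross-correlation matrix of residue motions
#'
#' On mean-superposed frames, each residue is represented by the unweighted
#' centroid of its masked atoms (set `selection = "calpha"` for the
#' C-alpha-only convention). The entry for residues i, j is the normalised
#' covariance of their displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, in `[-1, 1]` with a
#' unit diagonal. A residue with zero variance gets zero off-diagonal
#' entries and is recorded in the `flagged_residues` attribute.
#'
#' @inheritParams rmsd_series
#' @return A symmetric `dccm_matrix` (residue x residue) with residue numbers
#'   as dimnames.
#' @export
dccm <- function(traj, selection = "all", residues = NULL) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames", call. = FALSE)
  mask <- select_atoms(traj, selection, residues)
  al <- .align_to_mean(traj, mask)
  resid <- traj$atoms$resid[mask]
  res_ids <- sort(unique(resid))
  nf <- n_frames(traj)
  nr <- length(res_ids)
  # residue centroids per frame, displacements from the mean centroid
  disp <- array(0, c(nf, nr, 3))
  for (f in seq_len(nf)) {
    m <- matrix(al$coords[f, mask, ], ncol = 3)
    for (k in 1:3) {
      disp[f, , k] <- tapply(m[, k], resid, mean)[as.character(res_ids)]
    }
  }
  mean_c <- apply(disp, c(2, 3), mean)
  for (k in 1:3) disp[, , k] <- sweep(disp[, , k, drop = TRUE], 2, mean_c[, k])
  # <dr_i . dr_j> = sum over axes of per-axis cross products
  cov3 <- matrix(0, nr, nr)
  for (k in 1:3) cov3 <- cov3 + crossprod(disp[, , k]) / nf
  v <- diag(cov3)
  zero <- v <= .Machine$double.eps * max(v, 1)
  denom <- sqrt(outer(pmax(v, .Machine$double.xmin),
                      pmax(v, .Machine$double.xmin)))
  C <- cov3 / denom
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(res_ids, res_ids)
  if (any(zero)) {
    warning(sprintf("%d residue(s) with zero variance zeroed in DCCM",
                    sum(zero)), call. = FALSE)
  }
  structure(C, class = c("dccm_matrix", "matrix", "array"),
            flagged_residues = res_ids[zero])
}

#' @rdname dccm
#' @param x,object A `dccm_matrix`.
#' @param ... Unused.
#' @method tidy dccm_matrix
#' @export
tidy.dccm_matrix <- function(x, ...) {
  ids <- as.integer(rownames(x))
  tibble::tibble(
    resid_i = rep(ids, times = length(ids)),
    resid_j = rep(ids, each = length(ids)),
    correlation = as.vector(unclass(x))
  )
}

#' @rdname dccm
#' @method autoplot dccm_matrix
#' @export
autoplot.dccm_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy.dccm_matrix(object),
                  ggplot2::aes(.data$resid_i, .data$resid_j,
                               fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#c51b7d", mid = "white",
                                  high = "#00a0a0", limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue", fill = "C(i,j)")
}

#' Principal component analysis of trajectory coordinates
#'
#' Eigendecomposition of the `3N x 3N` covariance of mean-superposed masked
#' coordinates. Rank deficiency (fewer frames than coordinates) is handled
#' naturally: trailing eigenvalues are zero.
#'
#' @inheritParams rmsd_series
#' @return An object of class `trajectory_pca` with `projections` (centred
#'   frame scores, frames x components), `variance_fraction` (eigenvalue
#'   shares, non-increasing, summing to 1) and `eigenvalues`.
#' @export
pca_trajectory <- function(traj, selection = "all", residues = NULL) {
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames", call. = FALSE)
  mask <- select_atoms(traj, selection, residues)
  al <- .align_to_mean(traj, mask)
  nf <- n_frames(traj)
  X <- matrix(al$coords[, mask, ], nrow = nf)  # frames x 3N (atom-major ok)
  Xc <- sweep(X, 2, colMeans(X))
  cv <- crossprod(Xc) / (nf - 1)
  if (max(abs(cv)) == 0) stop("all-zero covariance: constant trajectory",
                              call. = FALSE)
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  proj <- Xc %*% e$vectors
  structure(
    list(projections = proj,
         variance_fraction = lam / sum(lam),
         eigenvalues = lam,
         dt = traj$dt),
    class = "trajectory_pca"
  )
}

#' @export
print.trajectory_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<trajectory_pca> %d frames, %d modes; PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%%)\n",
              nrow(x$projections), length(vf), 100 * vf[1], 100 * vf[2],
              100 * (vf[1] + vf[2])))
  invisible(x)
}

#' @rdname pca_trajectory
#' @param x,object A `trajectory_pca`.
#' @param n_components Components to keep in the tidy output.
#' @param ... Unused.
#' @method tidy trajectory_pca
#' @export
tidy.trajectory_pca <- function(x, n_components = 2, ...) {
  k <- min(n_components, ncol(x$projections))
  out <- tibble::as_tibble(x$projections[, seq_len(k), drop = FALSE],
                           .name_repair = ~ paste0("PC", seq_len(k)))
  out$frame <- seq_len(nrow(out)) - 1L
  out$time <- out$frame * x$dt
  dplyr::relocate(out, "frame", "time")
}

#' @rdname pca_trajectory
#' @method glance trajectory_pca
#' @export
glance.trajectory_pca <- function(x, ...) {
  vf <- x$variance_fraction
  tibble::tibble(n_frames = nrow(x$projections), n_modes = length(vf),
                 pc1_fraction = vf[1], pc2_fraction = vf[2],
                 pc12_fraction = vf[1] + vf[2])
}

#' @rdname pca_trajectory
#' @method autoplot trajectory_pca
#' @export
autoplot.trajectory_pca <- function(object, ...) {
  ggplot2::ggplot(tidy.trajectory_pca(object),
                  ggplot2::aes(.data$PC1, .data$PC2, colour = .data$time)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "time (ns)") +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' Trajectory statistics bundle
#'
#' Convenience wrapper computing the standard post-simulation statistics in
#' one pass: RMSD series, per-residue RMSF, DCCM and PCA.
#'
#' @inheritParams rmsd_series
#' @return A list with elements `rmsd`, `rmsf`, `dccm`, `pca`.
#' @export
trajectory_stats <- function(traj, selection = "all", residues = NULL) {
  list(rmsd = rmsd_series(traj, selection, residues),
       rmsf = rmsf_per_residue(traj, selection, residues),
       dccm = dccm(traj, selection, residues),
       pca = pca_trajectory(traj, selection, residues))
}
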
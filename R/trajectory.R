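#' Molecular-dynamics trajectory container
#'
#' Ordered frames of labelled 3-D coordinates with a fixed time step. Every
#' frame carries the same atoms in the same order.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, positions in
#'   Angstrom; or a list of `n_atoms x 3` frame matrices.
#' @param atoms Data frame describing the atoms, with columns `name` (PDB
#'   atom name, e.g. `"CA"`), `resid` (1-based residue number) and optionally
#'   `element` (inferred from the first letter of `name` when absent).
#' @param dt Time between consecutive frames, in ns (> 0).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms, dt = 1) {
  if (is.list(coords) && !is.array(coords)) {
    n_frames <- length(coords)
    n_atoms <- nrow(coords[[1]])
    arr <- array(NA_real_, c(n_frames, n_atoms, 3))
    for (f in seq_len(n_frames)) {
      m <- as.matrix(coords[[f]])
      if (!identical(dim(m), c(n_atoms, 3L)))
        stop("all frames must be n_atoms x 3 with identical atom count",
             call. = FALSE)
      arr[f, , ] <- m
    }
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] >= 1, dt > 0)
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("name", "resid") %in% names(atoms)),
            nrow(atoms) == dim(coords)[2])
  if (!"element" %in% names(atoms)) {
    atoms$element <- substr(gsub("[^A-Za-z].*$", "", atoms$name), 1, 1)
  }
  structure(list(coords = coords, atoms = atoms, dt = dt),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms (%d residues), dt = %g ns\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$resid)), x$dt))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

# one frame as an n_atoms x 3 matrix
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Select atoms of a trajectory by declarative mask
#'
#' @param traj An [md_trajectory()].
#' @param selection One of `"all"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (element != H) or `"calpha"`.
#' @param residues Optional vector of 1-based residue numbers to intersect
#'   with the name mask.
#' @return Integer atom indices into the trajectory's atom table.
#' @export
select_atoms <- function(traj, selection = c("all", "backbone", "heavy",
                                             "calpha"),
                         residues = NULL) {
  selection <- match.arg(selection)
  at <- traj$atoms
  keep <- switch(selection,
    all = rep(TRUE, nrow(at)),
    backbone = at$name %in% BACKBONE_NAMES,
    heavy = toupper(at$element) != "H",
    calpha = at$name == "CA"
  )
  if (!is.null(residues)) keep <- keep & at$resid %in% residues
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection matches no atom", call. = FALSE)
  idx
}

#' Keep only the final fraction of a trajectory
#'
#' Returns the last `ceiling(fraction * n_frames)` frames — the converged
#' tail used for energy averaging and free-energy landscapes (by default the
#' last 20% of the run).
#'
#' @param traj An [md_trajectory()].
#' @param fraction Fraction of frames to keep, in (0, 1].
#' @return An `md_trajectory` holding the trailing window.
#' @export
convergence_window <- function(traj, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  nf <- n_frames(traj)
  keep <- ceiling(fraction * nf)
  md_trajectory(traj$coords[seq.int(nf - keep + 1L, nf), , , drop = FALSE],
                traj$atoms, traj$dt)
}

#' Read a trajectory from a plain whitespace coordinate table
#'
#' The file holds `n_frames` consecutive blocks of `n_atoms` rows with three
#' numeric columns (x, y, z in Angstrom); blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @param n_atoms Atoms per frame.
#' @param atoms Optional atom table (see [md_trajectory()]); defaults to one
#'   CA pseudo-atom per row index.
#' @param dt Frame spacing in ns.
#' @return An [md_trajectory()].
#' @export
read_coord_table <- function(path, n_atoms, atoms = NULL, dt = 1) {
  vals <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(vals) %% (3 * n_atoms) != 0) {
    stop("coordinate count is not a multiple of 3 * n_atoms", call. = FALSE)
  }
  nf <- length(vals) %/% (3 * n_atoms)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  arr <- array(NA_real_, c(nf, n_atoms, 3))
  for (f in seq_len(nf)) {
    arr[f, , ] <- m[seq.int((f - 1) * n_atoms + 1, f * n_atoms), ]
  }
  if (is.null(atoms)) {
    atoms <- tibble::tibble(name = "CA", resid = seq_len(n_atoms),
                            element = "C")
  }
  md_trajectory(arr, atoms, dt)
}

#' @rdname read_coord_table
#' @param traj An [md_trajectory()] to write.
#' @export
write_coord_table <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d frames x %d atoms, dt = %.17g ns",
                     n_frames(traj), n_atoms(traj), traj$dt), con)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses ATOM/HETATM records grouped by MODEL/ENDMDL via
#' [bio3d::read.pdb()]; each model becomes one frame.
#'
#' @param path PDB file path.
#' @param dt Frame spacing in ns.
#' @return An [md_trajectory()].
#' @export
read_multimodel_pdb <- function(path, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB trajectories requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  na <- ncol(xyz) / 3
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  atoms <- tibble::tibble(
    name = pdb$atom$elety,
    resid = as.integer(pdb$atom$resno),
    element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                     substr(pdb$atom$elety, 1, 1), pdb$atom$elesy)
  )
  md_trajectory(arr, atoms, dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits fixed-width ATOM records inside MODEL/ENDMDL blocks (coordinates at
#' the format's native 0.001-Angstrom precision).
#'
#' @param traj An [md_trajectory()].
#' @param path Output path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  sprintf("%-4s", at$name))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), name4, at$resid, m[, 1], m[, 2], m[, 3], 1, 0,
      toupper(at$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
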
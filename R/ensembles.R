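# Trajectory data model, superposition, Cartesian PCA, projection, RMSF.

#' Construct a bead ensemble
#'
#' The universal carrier for target and coarse-grained ensembles: a stack of
#' frames of bead coordinates with optional per-frame statistical weights.
#'
#' @param coords an F x B x 3 array, or a list of F matrices of dimension
#'   B x 3, coordinates in nm.
#' @param bead_ids optional character vector of B bead labels.
#' @param frame_weights optional non-negative per-frame weights (default
#'   uniform); they are carried as statistical weights through PCA, projection
#'   and RMSF so that reweighted ensembles can be analysed without resampling.
#' @param box optional length-3 box vector in nm.
#' @return an object of class `BeadEnsemble`.
#' @export
bead_ensemble <- function(coords, bead_ids = NULL, frame_weights = NULL,
                          box = NULL) {
  if (is.list(coords)) {
    .chk(length(coords) >= 1, "empty coordinate list")
    B <- nrow(coords[[1]])
    .chk(all(vapply(coords, function(m) identical(dim(m), c(B, 3L)) ||
                      identical(dim(m), c(as.integer(B), 3L)), logical(1))),
         "all frames must share the same B x 3 shape")
    arr <- array(0, dim = c(length(coords), B, 3))
    for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
    coords <- arr
  }
  .chk(is.array(coords) && length(dim(coords)) == 3 && dim(coords)[3] == 3,
       "coords must be an F x B x 3 array")
  F <- dim(coords)[1]; B <- dim(coords)[2]
  .chk(B >= 2, "an ensemble needs at least 2 beads")
  .chk(all(is.finite(coords)), "non-finite coordinates")
  if (is.null(bead_ids)) bead_ids <- paste0("B", seq_len(B))
  .chk(length(bead_ids) == B, "bead_ids length must equal bead count")
  if (is.null(frame_weights)) frame_weights <- rep(1, F)
  .chk(length(frame_weights) == F, "frame_weights length must equal frame count")
  .chk(all(frame_weights >= 0) && sum(frame_weights) > 0,
       "frame_weights must be non-negative with positive sum")
  structure(list(coords = coords, bead_ids = as.character(bead_ids),
                 frame_weights = as.numeric(frame_weights), box = box),
            class = "BeadEnsemble")
}

#' @export
print.BeadEnsemble <- function(x, ...) {
  cat(sprintf("BeadEnsemble: %d frames x %d beads (nm)\n",
              n_frames(x), n_beads(x)))
  invisible(x)
}

#' Number of frames / beads in an ensemble
#' @param ensemble a `BeadEnsemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_beads <- function(ensemble) dim(ensemble$coords)[2]

# F x 3B matrix of flattened frames, bead-major (x1 y1 z1 x2 y2 z2 ...)
flatten_frames <- function(ensemble) {
  d <- dim(ensemble$coords)
  out <- matrix(aperm(ensemble$coords, c(3, 2, 1)), nrow = d[1],
                ncol = 3 * d[2], byrow = TRUE)
  out
}

unflatten_frame <- function(v) {
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Load a bead ensemble from a coordinate file
#'
#' Reads multi-model PDB (via \pkg{bio3d}, coordinates converted from Angstrom
#' to nm) or single/multi-frame GRO (already in nm).
#'
#' @param trajectory_path path to a .pdb or .gro file.
#' @param topology_path optional; unused for PDB/GRO but kept for interface
#'   symmetry with topology-carrying trajectory formats.
#' @param bead_selection `NULL` for all beads, an integer vector of 0-based
#'   bead indices, a `list(from, to)` 0-based half-open index range, or a
#'   character vector of bead (atom) names.
#' @return a `BeadEnsemble` with uniform frame weights, frames in file order.
#' @export
load_ensemble <- function(trajectory_path, topology_path = NULL,
                          bead_selection = NULL) {
  .chk(file.exists(trajectory_path), "file not found: ", trajectory_path)
  ext <- tolower(tools::file_ext(trajectory_path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(trajectory_path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    F <- nrow(xyz); B <- ncol(xyz) / 3
    coords <- array(0, dim = c(F, B, 3))
    for (f in seq_len(F)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3,
                                                  byrow = TRUE) / 10
    ids <- pdb$atom$elety
  } else if (ext == "gro") {
    g <- read_gro(trajectory_path)
    coords <- g$coords
    ids <- g$bead_ids
  } else {
    stop("unsupported trajectory format: .", ext,
         " (supported: .pdb, .gro)", call. = FALSE)
  }
  sel <- resolve_selection(bead_selection, ids)
  .chk(length(sel) >= 2, "bead selection matches fewer than 2 beads")
  bead_ensemble(coords[, sel, , drop = FALSE], bead_ids = ids[sel])
}

resolve_selection <- function(bead_selection, ids) {
  B <- length(ids)
  if (is.null(bead_selection)) return(seq_len(B))
  if (is.list(bead_selection)) {
    from <- bead_selection$from; to <- bead_selection$to
    .chk(!is.null(from) && !is.null(to), "index range needs $from and $to")
    .chk(from >= 0 && to <= B && from < to,
         "0-based half-open range [from, to) out of bounds")
    return(seq.int(from + 1, to))
  }
  if (is.character(bead_selection)) {
    sel <- which(ids %in% bead_selection)
    .chk(length(sel) > 0, "bead selection matches 0 beads")
    return(sel)
  }
  idx <- as.integer(bead_selection)
  .chk(all(idx >= 0 & idx < B), "0-based bead indices out of bounds")
  idx + 1L
}

#' Read / write multi-frame GRO files
#'
#' GROMACS .gro fixed-width format, coordinates in nm at 0.001 nm printed
#' precision.  Multi-frame files are concatenated frame blocks.
#'
#' @param path file path.
#' @return for `read_gro`, a list with `coords` (F x B x 3 array), `bead_ids`
#'   and `box`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  .chk(length(lines) >= 3, "truncated GRO file")
  frames <- list(); ids <- NULL; box <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    .chk(!is.na(natoms) && natoms > 0, "bad atom count in GRO at line ", i + 1)
    .chk(i + 1 + natoms + 1 <= length(lines), "truncated GRO frame")
    atom_lines <- lines[(i + 2):(i + 1 + natoms)]
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    .chk(all(is.finite(c(x, y, z))), "malformed coordinates in GRO frame")
    if (is.null(ids)) ids <- trimws(substr(atom_lines, 11, 15))
    frames[[length(frames) + 1]] <- cbind(x, y, z)
    box <- as.numeric(strsplit(trimws(lines[i + 1 + natoms + 1]),
                               "\\s+")[[1]])[1:3]
    i <- i + natoms + 3
  }
  arr <- array(0, dim = c(length(frames), natoms, 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  list(coords = arr, bead_ids = ids, box = box)
}

#' @rdname read_gro
#' @param ensemble a `BeadEnsemble` to write.
#' @param title title string placed on each frame's first line.
#' @export
write_gro <- function(ensemble, path, title = "goperturb frame") {
  B <- n_beads(ensemble)
  box <- if (is.null(ensemble$box)) c(0, 0, 0) else ensemble$box
  con <- file(path, "w")
  on.exit(close(con))
  nm <- substr(ensemble$bead_ids, 1, 5)
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(c(sprintf("%s t=%d", title, f),
                 sprintf("%5d", B)), con)
    xyz <- ensemble$coords[f, , , drop = TRUE]
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(B), "BEAD", nm, seq_len(B),
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

# Kabsch rigid-body fit: rotation + translation minimizing RMSD of P onto Q
# (both B x 3, mass-unweighted).  Returns the transformed P.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P0 %*% t(R), 2, cq, FUN = "+")
}

#' Superpose every frame onto a reference structure
#'
#' Mass-unweighted rigid-body least-squares fit (rotation + translation, no
#' scaling) of each frame onto the reference over all beads.
#'
#' @param ensemble a `BeadEnsemble`.
#' @param reference_structure B x 3 matrix in nm (e.g. a subspace mean
#'   structure).
#' @return the superposed `BeadEnsemble`; if the reference is degenerate (all
#'   beads coincident or collinear, making the rotation ill-determined) the fit
#'   is still returned with attribute `degenerate_reference = TRUE` and a
#'   warning.
#' @export
superpose <- function(ensemble, reference_structure) {
  ref <- as.matrix(reference_structure)
  .chk(nrow(ref) == n_beads(ensemble),
       "reference bead count does not match ensemble")
  ref0 <- sweep(ref, 2, colMeans(ref))
  degenerate <- qr(ref0)$rank < 2
  if (degenerate) warning("degenerate reference (rank < 2); fit returned anyway")
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    out$coords[f, , ] <- kabsch_fit(ensemble$coords[f, , , drop = TRUE], ref)
  }
  attr(out, "degenerate_reference") <- degenerate
  out
}

# per-frame distance between beads i and j (1-based), robust to F = 1
pair_dists <- function(ensemble, i, j) {
  F <- n_frames(ensemble)
  d <- matrix(ensemble$coords[, i, , drop = FALSE] -
                ensemble$coords[, j, , drop = FALSE], nrow = F)
  sqrt(rowSums(d^2))
}

# per-frame RMSD to a reference structure (nm)
rmsd_to <- function(ensemble, reference_structure) {
  ref <- as.matrix(reference_structure)
  vapply(seq_len(n_frames(ensemble)), function(f) {
    d <- ensemble$coords[f, , , drop = TRUE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

#' Cartesian principal component analysis of an ensemble
#'
#' Eigendecomposition of the (weighted, population-form) covariance of the
#' flattened 3B coordinates of a superposed ensemble.  The returned subspace is
#' the "essential subspace": the mean structure plus the leading orthonormal
#' eigenvectors and their variances.
#'
#' @param ensemble a superposed `BeadEnsemble`.
#' @param n_components number of leading components to retain (>= 1,
#'   < number of frames).
#' @return an `EssentialSubspace`: `mean_structure` (B x 3 nm),
#'   `eigenvectors` (3B x n, orthonormal columns), `eigenvalues` (nm^2,
#'   descending), `total_variance` (sum over all 3B eigenvalues), `n_beads`,
#'   and an `id` string used to tag projections.
#' @export
compute_pca <- function(ensemble, n_components) {
  F <- n_frames(ensemble); B <- n_beads(ensemble)
  .chk(n_components >= 1, "n_components must be >= 1")
  .chk(F > n_components, "need more frames than components")
  X <- flatten_frames(ensemble)
  w <- ensemble$frame_weights / sum(ensemble$frame_weights)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc * w, Xc)           # population-form weighted covariance
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  n <- as.integer(n_components)
  structure(list(
    mean_structure = unflatten_frame(mu),
    eigenvectors = eig$vectors[, seq_len(n), drop = FALSE],
    eigenvalues = vals[seq_len(n)],
    total_variance = sum(vals),
    n_beads = B,
    id = sprintf("pca-%dx%d-%.10g", B, n, sum(vals))
  ), class = "EssentialSubspace")
}

#' @export
print.EssentialSubspace <- function(x, ...) {
  cat(sprintf("EssentialSubspace: %d beads, %d components, %.1f%% of variance\n",
              x$n_beads, length(x$eigenvalues),
              100 * variance_fraction(x, length(x$eigenvalues))))
  invisible(x)
}

#' Fraction of total variance captured by the first k components
#'
#' @param subspace an `EssentialSubspace`.
#' @param k number of leading components.
#' @return value in \[0, 1\].
#' @export
variance_fraction <- function(subspace, k) {
  .chk(k >= 1 && k <= length(subspace$eigenvalues), "k out of range")
  if (subspace$total_variance <= 0) return(0)
  min(1, sum(subspace$eigenvalues[seq_len(k)]) / subspace$total_variance)
}

#' Project an ensemble onto an essential subspace
#'
#' Applies the eigenvector transpose to each centred, flattened frame.  By
#' default each frame is first rigid-body fitted onto the subspace mean
#' structure, matching how coarse ensembles are always superposed to the
#' target mean before projection.
#'
#' @param ensemble a `BeadEnsemble` with bead count matching the subspace.
#' @param subspace an `EssentialSubspace`.
#' @param superpose_first fit frames to `subspace$mean_structure` before
#'   projecting (default `TRUE`).
#' @return a `ProjectedEnsemble`: `points` (F x n, nm), `frame_weights`,
#'   `subspace_ref`.
#' @export
project <- function(ensemble, subspace, superpose_first = TRUE) {
  .chk(n_beads(ensemble) == subspace$n_beads, "bead count mismatch")
  if (superpose_first) ensemble <- superpose(ensemble, subspace$mean_structure)
  X <- flatten_frames(ensemble)
  mu <- as.vector(t(subspace$mean_structure))
  pts <- sweep(X, 2, mu) %*% subspace$eigenvectors
  structure(list(points = pts,
                 frame_weights = ensemble$frame_weights,
                 subspace_ref = subspace$id),
            class = "ProjectedEnsemble")
}

#' Reconstruct a frame from subspace coordinates
#'
#' Inverse of [project()] restricted to the stored components: mean structure
#' plus the linear combination of eigenvectors.
#'
#' @param subspace an `EssentialSubspace`.
#' @param point length-n coordinate vector in the subspace.
#' @return a B x 3 coordinate matrix in nm.
#' @export
reconstruct_frame <- function(subspace, point) {
  .chk(length(point) == ncol(subspace$eigenvectors), "dimension mismatch")
  v <- as.vector(t(subspace$mean_structure)) +
    as.vector(subspace$eigenvectors %*% point)
  unflatten_frame(v)
}

#' Per-bead root-mean-square fluctuation profile
#'
#' Weighted RMSF about the weighted mean position, per bead, in nm.  The
#' ensemble should be superposed first; rigid-body motion left in the frames
#' inflates the profile.
#'
#' @param ensemble a superposed `BeadEnsemble`.
#' @return numeric vector of length B (nm).
#' @export
rmsf <- function(ensemble) {
  F <- n_frames(ensemble)
  if (F < 2) {
    warning("single-frame ensemble: RMSF is identically zero")
    return(rep(0, n_beads(ensemble)))
  }
  w <- ensemble$frame_weights / sum(ensemble$frame_weights)
  X <- flatten_frames(ensemble)
  mu <- colSums(X * w)
  dev2 <- sweep(X, 2, mu)^2
  msd_flat <- colSums(dev2 * w)                # per Cartesian component
  per_bead <- rowSums(matrix(msd_flat, ncol = 3, byrow = TRUE))
  sqrt(per_bead)
}

#' Average unsigned error between two RMSF profiles
#'
#' @param profile_a,profile_b equal-length numeric profiles in nm.
#' @return mean absolute difference (nm).
#' @export
rmsf_aue <- function(profile_a, profile_b) {
  .chk(length(profile_a) == length(profile_b), "profile length mismatch")
  mean(abs(profile_a - profile_b))
}
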
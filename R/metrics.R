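# Ensemble-similarity metrics: RMSIP, covariance overlap, (sliced) Wasserstein.

#' Pair of essential subspaces for comparison
#'
#' @param subspace_a,subspace_b `EssentialSubspace` objects, or lists with
#'   `eigenvectors` and `eigenvalues`, sharing the ambient dimension 3B and
#'   the number of components n.
#' @return a `SubspacePair`.
#' @export
subspace_pair <- function(subspace_a, subspace_b) {
  Va <- subspace_a$eigenvectors; Vb <- subspace_b$eigenvectors
  .chk(nrow(Va) == nrow(Vb), "ambient dimension mismatch")
  .chk(ncol(Va) == ncol(Vb), "component count mismatch")
  .chk(all(subspace_a$eigenvalues >= 0) && all(subspace_b$eigenvalues >= 0),
       "negative eigenvalues")
  structure(list(eigenvectors_a = Va, eigenvectors_b = Vb,
                 eigenvalues_a = subspace_a$eigenvalues,
                 eigenvalues_b = subspace_b$eigenvalues),
            class = "SubspacePair")
}

check_orthonormal <- function(V, tol = 1e-6) {
  G <- crossprod(V)
  .chk(max(abs(G - diag(ncol(V)))) < tol,
       "eigenvector columns are not orthonormal within tolerance")
}

#' Root-mean-square inner product between two subspaces
#'
#' RMSIP = sqrt( (1/n) sum_{p,q} (v_p' w_q)^2 ), a geometric similarity in
#' \[0, 1\]: 1 for identical spans, 0 for mutually orthogonal ones.  Invariant
#' under orthonormal re-basis within each span.
#'
#' @param pair a `SubspacePair`.
#' @return value in \[0, 1\].
#' @export
rmsip <- function(pair) {
  check_orthonormal(pair$eigenvectors_a)
  check_orthonormal(pair$eigenvectors_b)
  n <- ncol(pair$eigenvectors_a)
  S <- crossprod(pair$eigenvectors_a, pair$eigenvectors_b)
  min(1, sqrt(sum(S^2) / n))
}

#' Covariance overlap between two subspaces
#'
#' CO = sum_{p,q} (mu_p nu_q / (mu nu)) (v_p' w_q)^2 with
#' mu = sqrt(sum mu_p^2), nu = sqrt(sum nu_q^2): an eigenvalue-weighted
#' subspace similarity that emphasizes overlap along high-variance directions.
#' It is exactly 1 for identical subspaces with proportional eigenvalue
#' spectra and 0 for mutually orthogonal ones.  The value is clamped to
#' \[0, 1\]; the unclamped number is kept in attribute `"raw"`.
#'
#' @param pair a `SubspacePair` with at least one positive eigenvalue per side.
#' @return value in \[0, 1\].
#' @export
covariance_overlap <- function(pair) {
  mu <- pair$eigenvalues_a; nu <- pair$eigenvalues_b
  .chk(any(mu > 0) && any(nu > 0), "all-zero eigenvalues on one side")
  check_orthonormal(pair$eigenvectors_a)
  check_orthonormal(pair$eigenvectors_b)
  S2 <- crossprod(pair$eigenvectors_a, pair$eigenvectors_b)^2
  raw <- sum(outer(mu, nu) * S2) / (sqrt(sum(mu^2)) * sqrt(sum(nu^2)))
  out <- min(1, max(0, raw))
  attr(out, "raw") <- raw
  out
}

#' One-dimensional weighted Wasserstein distance
#'
#' Order-gamma Wasserstein distance between two weighted empirical 1-D
#' distributions, computed exactly via merged-quantile integration of
#' |F^{-1}(t) - G^{-1}(t)|^gamma over t in (0, 1) (exact for step CDFs; no
#' resampling).
#'
#' @param samples_a,samples_b numeric sample vectors.
#' @param weights_a,weights_b non-negative weights (default uniform);
#'   normalized internally.
#' @param gamma transport order, >= 1 (default 3).
#' @return non-negative distance on the samples' scale.
#' @export
wasserstein_1d <- function(samples_a, samples_b, weights_a = NULL,
                           weights_b = NULL, gamma = 3) {
  .chk(gamma >= 1, "gamma must be >= 1")
  .chk(length(samples_a) > 0 && length(samples_b) > 0, "empty sample set")
  if (is.null(weights_a)) weights_a <- rep(1, length(samples_a))
  if (is.null(weights_b)) weights_b <- rep(1, length(samples_b))
  .chk(all(weights_a >= 0) && all(weights_b >= 0), "negative weights")
  .chk(sum(weights_a) > 0 && sum(weights_b) > 0, "zero total weight")
  oa <- order(samples_a); ob <- order(samples_b)
  va <- samples_a[oa]; wa <- weights_a[oa] / sum(weights_a)
  vb <- samples_b[ob]; wb <- weights_b[ob] / sum(weights_b)
  pa <- cumsum(wa); pb <- cumsum(wb)
  ps <- sort(unique(c(pa, pb)))
  widths <- diff(c(0, ps))
  mids <- ps - widths / 2
  # index of the first atom whose cumulative weight reaches the quantile level
  ia <- findInterval(mids, pa) + 1L
  ib <- findInterval(mids, pb) + 1L
  ia <- pmin(ia, length(va)); ib <- pmin(ib, length(vb))
  (sum(widths * abs(va[ia] - vb[ib])^gamma))^(1 / gamma)
}

#' Random slice directions on the unit sphere
#'
#' Quasi-uniform sphere sampling via normalized Gaussian draws under a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param n_slices number of directions S.
#' @param dim ambient dimension n.
#' @param seed integer seed (mandatory for reproducibility).
#' @return a `SliceSet` with an S x n matrix of unit `directions`.
#' @export
slice_set <- function(n_slices, dim, seed) {
  .chk(n_slices >= 1, "n_slices must be >= 1")
  D <- with_seed(seed, matrix(rnorm(n_slices * dim), n_slices, dim))
  D <- D / sqrt(rowSums(D^2))
  structure(list(directions = D, seed = as.integer(seed)),
            class = "SliceSet")
}

#' Sliced Wasserstein distance between projected ensembles
#'
#' SWD_gamma = ( mean over random unit directions theta of
#' WD_gamma(f_theta, g_theta)^gamma )^{1/gamma}, where f_theta, g_theta are the
#' two weighted point clouds projected onto theta.  A tractable surrogate for
#' the full d-dimensional Wasserstein distance; frame weights are respected.
#'
#' @param proj_a,proj_b `ProjectedEnsemble` objects or plain F x n matrices
#'   with matching column count.
#' @param gamma transport order (default 3, the standard choice for essential
#'   subspace comparisons here).
#' @param n_slices number of random directions (default 1000).
#' @param seed integer seed for the slice directions.
#' @param weights_a,weights_b optional weights overriding those carried by the
#'   projections.
#' @return non-negative distance in nm (for nm-scale projections).
#' @export
sliced_wasserstein <- function(proj_a, proj_b, gamma = 3, n_slices = 1000,
                               seed = 1L, weights_a = NULL, weights_b = NULL) {
  Xa <- if (inherits(proj_a, "ProjectedEnsemble")) proj_a$points else as.matrix(proj_a)
  Xb <- if (inherits(proj_b, "ProjectedEnsemble")) proj_b$points else as.matrix(proj_b)
  .chk(ncol(Xa) == ncol(Xb), "projection dimension mismatch")
  if (is.null(weights_a))
    weights_a <- if (inherits(proj_a, "ProjectedEnsemble"))
      proj_a$frame_weights else rep(1, nrow(Xa))
  if (is.null(weights_b))
    weights_b <- if (inherits(proj_b, "ProjectedEnsemble"))
      proj_b$frame_weights else rep(1, nrow(Xb))
  d <- ncol(Xa)
  if (d == 1) {
    return(wasserstein_1d(Xa[, 1], Xb[, 1], weights_a, weights_b, gamma))
  }
  S <- slice_set(n_slices, d, seed)
  Pa <- Xa %*% t(S$directions)
  Pb <- Xb %*% t(S$directions)
  wd_g <- vapply(seq_len(n_slices), function(s) {
    wasserstein_1d(Pa[, s], Pb[, s], weights_a, weights_b, gamma)^gamma
  }, numeric(1))
  mean(wd_g)^(1 / gamma)
}

#' Split-half self-distance of an ensemble (sampling noise floor)
#'
#' SWD between the odd and even frames of one projected ensemble; the scale of
#' SWD values that pure sampling noise produces, reported alongside
#' optimization SWDs.
#'
#' @param proj a `ProjectedEnsemble`.
#' @inheritParams sliced_wasserstein
#' @return non-negative SWD.
#' @export
swd_noise_floor <- function(proj, gamma = 3, n_slices = 1000, seed = 1L) {
  F <- nrow(proj$points)
  .chk(F >= 4, "need at least 4 frames for a split-half estimate")
  odd <- seq(1, F, by = 2); even <- seq(2, F, by = 2)
  sliced_wasserstein(proj$points[odd, , drop = FALSE],
                     proj$points[even, , drop = FALSE],
                     gamma = gamma, n_slices = n_slices, seed = seed,
                     weights_a = proj$frame_weights[odd],
                     weights_b = proj$frame_weights[even])
}
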
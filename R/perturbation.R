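# Per-frame contact-energy evaluation, cumulant statistics, and the
# second-order analytic estimator of the perturbed configurational
# distribution.
#
# Convention used throughout the package: a perturbation vector lambda scales
# contact strengths as strength * (1 + lambda_k), so the perturbed potential
# is V_lambda = V + lambda' L where L holds the per-contact energies.  The
# induced change of the Boltzmann distribution is
#   ln(rho_lambda / rho) = -lambda' L - psi(lambda),
#   psi(lambda) = ln < exp(-lambda' L) >  ~=  -lambda' <L> + 1/2 lambda' C lambda
# to second order in the cumulant expansion.  Under this convention
# lambda_k > 0 strengthens contact k both in the reweighting estimate and in
# the updated network, so estimator and updater always move the ensemble the
# same way.

#' Per-frame, per-contact energy matrix
#'
#' Evaluates every network contact in every frame and converts to thermal
#' units (kT at `temperature_K`, with k_B = 0.00831446 kJ/mol/K).
#'
#' @param ensemble a `BeadEnsemble`.
#' @param network an `InteractionNetwork` with indices valid for the ensemble.
#' @param temperature_K temperature in kelvin (default 300).
#' @return a `TermMatrix`: `values` (F x M, in kT), `temperature_K`,
#'   `kBT_kJmol`.
#' @export
evaluate_terms <- function(ensemble, network, temperature_K = 300) {
  .chk(max(network$contacts$j) < n_beads(ensemble),
       "network indices exceed ensemble bead count")
  kT <- kBT(temperature_K)
  F <- n_frames(ensemble); M <- n_contacts(network)
  vals <- matrix(0, F, M)
  for (k in seq_len(M)) {
    d <- pair_dists(ensemble, network$contacts$i[k] + 1L,
                    network$contacts$j[k] + 1L)
    if (network$kind == "go_lj" && any(d <= 0))
      stop(sprintf("overlapping beads (contact %d, frame %d): LJ energy not finite",
                   k, which(d <= 0)[1]), call. = FALSE)
    vals[, k] <- contact_energy(network$kind, network$contacts$strength[k],
                                network$contacts$geometry[k], d) / kT
  }
  .chk(all(is.finite(vals)), "non-finite contact energies")
  structure(list(values = vals, temperature_K = temperature_K,
                 kBT_kJmol = kT),
            class = "TermMatrix")
}

#' Cumulant basis of a term matrix
#'
#' Weighted mean vector and (population-form, denominator sum-of-weights)
#' covariance of the per-frame energy rows, the symmetric eigendecomposition
#' C = U Omega U', and the centred eigenprojections B = (L - <L>) U per frame.
#' Negative eigenvalues from numerical round-off are clamped at zero.
#'
#' @param term_matrix a `TermMatrix` (or plain F x M matrix).
#' @param frame_weights optional non-negative weights (default uniform).
#' @param diagonal_loading optional non-negative ridge added to the covariance
#'   diagonal (default 0; M is normally far smaller than F so no shrinkage is
#'   needed).
#' @return a `PerturbationBasis`: `mean` (M), `covariance` (M x M),
#'   `eigenvectors` (M x M, orthonormal), `eigenvalues` (M, >= 0, descending),
#'   `centered_eigenprojections` (F x M), `n_frames`, `frame_weights`.
#' @export
build_basis <- function(term_matrix, frame_weights = NULL,
                        diagonal_loading = 0) {
  L <- if (inherits(term_matrix, "TermMatrix")) term_matrix$values
  else as.matrix(term_matrix)
  F <- nrow(L); M <- ncol(L)
  .chk(F >= 2, "need at least 2 frames")
  if (is.null(frame_weights)) frame_weights <- rep(1, F)
  .chk(length(frame_weights) == F && all(frame_weights >= 0) &&
         sum(frame_weights) > 0, "bad frame weights")
  w <- frame_weights / sum(frame_weights)
  mu <- colSums(L * w)
  Lc <- sweep(L, 2, mu)
  C <- crossprod(Lc * w, Lc)
  C <- (C + t(C)) / 2
  if (diagonal_loading > 0) C <- C + diag(diagonal_loading, M)
  eig <- eigen(C, symmetric = TRUE)
  structure(list(mean = mu, covariance = C,
                 eigenvectors = eig$vectors,
                 eigenvalues = pmax(eig$values, 0),
                 centered_eigenprojections = Lc %*% eig$vectors,
                 n_frames = F,
                 frame_weights = frame_weights),
            class = "PerturbationBasis")
}

check_trust_region <- function(lambda, bound = 0.3) {
  if (max(abs(lambda)) > bound)
    warning(sprintf("lambda outside trust region (max |lambda| = %.3g > %.3g); estimate may be inaccurate",
                    max(abs(lambda)), bound))
  invisible(lambda)
}

#' Per-frame log density ratio under a strength perturbation
#'
#' Second-order estimate of ln(rho_lambda / rho) per frame for the
#' strength-scaling convention (1 + lambda):
#' `-lambda' (L_f - <L>) - 1/2 lambda' C lambda`, evaluated in the covariance
#' eigenbasis as `sum_k (-B_fk xi_k - 1/2 omega_k^2 xi_k^2)` with
#' xi = U' lambda (the two forms are algebraically identical).
#'
#' @param basis a `PerturbationBasis`.
#' @param lambda length-M perturbation vector.
#' @param trust_bound infinity-norm bound beyond which a warning is emitted
#'   (evaluation proceeds regardless); default 0.3.
#' @return length-F vector of per-frame log weights (up to the common
#'   normalizer).
#' @export
log_density_ratio <- function(basis, lambda, trust_bound = 0.3) {
  .chk(length(lambda) == length(basis$mean), "lambda dimension mismatch")
  check_trust_region(lambda, trust_bound)
  xi <- as.vector(crossprod(basis$eigenvectors, lambda))
  as.vector(-basis$centered_eigenprojections %*% xi) -
    0.5 * sum(basis$eigenvalues * xi^2)
}

#' Second-order cumulant expansion of the log normalizer
#'
#' psi(lambda) = ln < exp(-lambda' L) > approximated as
#' `-lambda' <L> + 1/2 lambda' C lambda`; the error is third order in lambda
#' (the neglected third cumulant).
#'
#' @inheritParams log_density_ratio
#' @return a scalar.
#' @export
psi_second_order <- function(basis, lambda) {
  .chk(length(lambda) == length(basis$mean), "lambda dimension mismatch")
  -sum(lambda * basis$mean) +
    0.5 * as.numeric(crossprod(lambda, basis$covariance %*% lambda))
}

#' Kish effective sample size of a weight vector
#'
#' ESS = (sum w)^2 / sum w^2; equals F for uniform weights and degrades toward
#' 1 as the weights concentrate.
#'
#' @param weights non-negative weights.
#' @return effective number of frames.
#' @export
effective_sample_size <- function(weights) {
  sum(weights)^2 / sum(weights^2)
}

#' Reweight an ensemble or projection toward a perturbed potential
#'
#' Multiplies the existing frame weights by exp([log_density_ratio()]) and
#' renormalizes to sum 1, so the reweighted frames represent the Boltzmann
#' ensemble of the perturbed network without new sampling.  The Kish effective
#' sample size is attached as attribute `"ess"`; a warning fires when
#' ESS / F drops below `ess_floor`.
#'
#' @param x a `BeadEnsemble` or `ProjectedEnsemble` whose frame count matches
#'   the basis.
#' @param basis a `PerturbationBasis` built from the same ensemble.
#' @param lambda length-M perturbation vector.
#' @param ess_floor relative ESS warning threshold (default 0.05).
#' @param trust_bound see [log_density_ratio()].
#' @return `x` with updated `frame_weights` (summing to 1).
#' @export
reweight_frames <- function(x, basis, lambda, ess_floor = 0.05,
                            trust_bound = 0.3) {
  F <- basis$n_frames
  old_w <- x$frame_weights
  .chk(length(old_w) == F, "frame count does not match basis")
  lr <- log_density_ratio(basis, lambda, trust_bound)
  lw <- log(old_w / sum(old_w)) + lr
  lw <- lw - max(lw)                       # underflow-safe normalization
  w <- exp(lw)
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("all frame weights underflowed; reduce the trust region",
         call. = FALSE)
  w <- w / s
  ess <- effective_sample_size(w)
  if (ess / F < ess_floor)
    warning(sprintf("effective sample size collapsed (ESS/F = %.3f < %.2f)",
                    ess / F, ess_floor))
  x$frame_weights <- w
  attr(x, "ess") <- ess
  x
}

#' Persist / restore a perturbation basis
#'
#' Versioned RDS container with shape metadata, for reusing an expensive basis
#' across sessions.
#'
#' @param basis a `PerturbationBasis`.
#' @param path file path.
#' @return `save_basis` the path invisibly; `load_basis` the basis.
#' @export
save_basis <- function(basis, path) {
  saveRDS(list(schema = "goperturb/basis", version = 1L,
               shape = c(F = basis$n_frames, M = length(basis$mean)),
               basis = unclass(basis)), path)
  invisible(path)
}

#' @rdname save_basis
#' @export
load_basis <- function(path) {
  obj <- readRDS(path)
  .chk(identical(obj$schema, "goperturb/basis"), "not a basis container")
  .chk(obj$version == 1L, "unsupported basis schema version")
  structure(obj$basis, class = "PerturbationBasis")
}
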
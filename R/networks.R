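# Interaction-network data model, potential kernels, construction, refitting,
# GROMACS-dialect .itp I/O, and network-comparison statistics.

#' Construct an interaction network
#'
#' A homogeneous list of pairwise contacts over B beads.  Each contact couples
#' beads i < j (0-based) with either a Lennard-Jones Go term (strength epsilon
#' in kJ/mol, geometry sigma in nm) or a harmonic elastic-network spring
#' (strength kappa in kJ/mol/nm^2, geometry r0 in nm).
#'
#' @param i,j integer vectors of 0-based bead indices (i < j enforced by
#'   swapping).
#' @param kind `"go_lj"` or `"enm_harmonic"` (one kind per network).
#' @param strength positive per-contact strengths.
#' @param geometry positive per-contact geometry parameters.
#' @param n_beads total bead count B.
#' @return an `InteractionNetwork` with a `contacts` data frame
#'   (`i`, `j`, `strength`, `geometry`), `kind` and `n_beads`.
#' @export
interaction_network <- function(i, j, kind, strength, geometry, n_beads) {
  kind <- match.arg(kind, c("go_lj", "enm_harmonic"))
  i <- as.integer(i); j <- as.integer(j)
  .chk(length(i) == length(j), "i/j length mismatch")
  .chk(length(i) >= 1, "a network needs at least one contact")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  .chk(all(i != j), "self-contacts not allowed")
  .chk(all(i >= 0) && all(j < n_beads), "bead indices out of range")
  .chk(!anyDuplicated(paste(i, j)), "duplicate contact pairs")
  strength <- rep_len(as.numeric(strength), length(i))
  geometry <- rep_len(as.numeric(geometry), length(i))
  .chk(all(strength > 0), "strengths must be positive")
  .chk(all(geometry > 0), "geometry parameters must be positive")
  structure(list(contacts = data.frame(i = i, j = j, strength = strength,
                                       geometry = geometry),
                 kind = kind, n_beads = as.integer(n_beads)),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d %s contacts over %d beads\n",
              nrow(x$contacts), x$kind, x$n_beads))
  invisible(x)
}

#' Number of contacts in a network
#' @param network an `InteractionNetwork`.
#' @return integer count M.
#' @export
n_contacts <- function(network) nrow(network$contacts)

#' Lennard-Jones pair energy
#'
#' V(r) = 4 epsilon \[ (sigma/r)^12 - (sigma/r)^6 \]: zero crossing at
#' r = sigma, unique minimum of depth -epsilon at r_min = 2^(1/6) sigma.
#'
#' @param epsilon well depth in kJ/mol (> 0).
#' @param sigma zero-crossing distance in nm (> 0).
#' @param r separation(s) in nm (> 0).
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
lj_energy <- function(epsilon, sigma, r) {
  .chk(all(epsilon > 0) && all(sigma > 0), "epsilon and sigma must be positive")
  .chk(all(r > 0), "r must be positive")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Harmonic elastic-network pair energy
#'
#' V(r) = 1/2 kappa (r - r0)^2.
#'
#' @param kappa spring constant in kJ/mol/nm^2 (> 0).
#' @param r0 equilibrium distance in nm (> 0).
#' @param r separation(s) in nm (>= 0).
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
enm_energy <- function(kappa, r0, r) {
  .chk(all(kappa > 0) && all(r0 > 0), "kappa and r0 must be positive")
  .chk(all(r >= 0), "r must be non-negative")
  0.5 * kappa * (r - r0)^2
}

# energy of one contact row at distance r, respecting the network kind
contact_energy <- function(kind, strength, geometry, r) {
  if (kind == "go_lj") lj_energy(strength, geometry, r)
  else enm_energy(strength, geometry, r)
}

#' Build a uniform-strength network from a single structure
#'
#' One contact per bead pair with sequence separation |i - j| >= `min_seq_sep`
#' whose distance in the reference frame lies within \[cutoff_lo, cutoff_hi\].
#' Go networks place the LJ minimum at the observed distance
#' (sigma = r / 2^(1/6)); elastic networks set r0 = r.  Standard defaults for
#' backbone-bead models: Go epsilon = 9.4 kJ/mol with cutoffs \[0.3, 1.1\] nm,
#' elastic kappa = 500 kJ/mol/nm^2 with cutoffs \[0, 0.9\] nm.
#'
#' @param structure B x 3 bead coordinates in nm.
#' @param kind `"go_lj"` or `"enm_harmonic"`.
#' @param cutoff_lo,cutoff_hi distance window in nm (lo < hi); defaults depend
#'   on `kind`.
#' @param strength uniform strength; default 9.4 kJ/mol (Go) or
#'   500 kJ/mol/nm^2 (elastic).
#' @param min_seq_sep minimum |i - j|; default 3 for Go (excluding bonded
#'   neighbours), 1 for elastic networks.
#' @return an `InteractionNetwork`; error if no pair qualifies.
#' @export
build_uniform_network <- function(structure, kind = c("go_lj", "enm_harmonic"),
                                  cutoff_lo = NULL, cutoff_hi = NULL,
                                  strength = NULL, min_seq_sep = NULL) {
  kind <- match.arg(kind)
  structure <- as.matrix(structure)
  B <- nrow(structure)
  if (is.null(cutoff_lo)) cutoff_lo <- if (kind == "go_lj") 0.3 else 0
  if (is.null(cutoff_hi)) cutoff_hi <- if (kind == "go_lj") 1.1 else 0.9
  if (is.null(strength)) strength <- if (kind == "go_lj") 9.4 else 500
  if (is.null(min_seq_sep)) min_seq_sep <- if (kind == "go_lj") 3 else 1
  .chk(cutoff_lo < cutoff_hi, "cutoff_lo must be < cutoff_hi")
  pairs <- which(upper.tri(matrix(0, B, B)), arr.ind = TRUE)
  ii <- pairs[, 1]; jj <- pairs[, 2]
  keep <- (jj - ii) >= min_seq_sep
  ii <- ii[keep]; jj <- jj[keep]
  d <- sqrt(rowSums((structure[ii, , drop = FALSE] -
                       structure[jj, , drop = FALSE])^2))
  keep <- d >= cutoff_lo & d <= cutoff_hi
  .chk(any(keep), "no bead pair falls inside the cutoff window (empty network)")
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  geometry <- if (kind == "go_lj") d / 2^(1 / 6) else d
  interaction_network(ii - 1L, jj - 1L, kind, strength, geometry, B)
}

#' Refit contact equilibrium distances from an ensemble
#'
#' For every contact, the mean pair distance over frames (weighted by the
#' ensemble frame weights) becomes the energy minimum: sigma = rbar / 2^(1/6)
#' for Go contacts, r0 = rbar for elastic springs.  Strengths are untouched.
#' Idempotent when re-applied with the same ensemble.
#'
#' @param network an `InteractionNetwork`.
#' @param ensemble a `BeadEnsemble` covering all network bead indices.
#' @return the refitted `InteractionNetwork`.
#' @export
set_equilibrium_from_ensemble <- function(network, ensemble) {
  .chk(max(network$contacts$j) < n_beads(ensemble),
       "ensemble bead count too small for network indices")
  w <- ensemble$frame_weights / sum(ensemble$frame_weights)
  rbar <- vapply(seq_len(n_contacts(network)), function(k) {
    sum(w * pair_dists(ensemble, network$contacts$i[k] + 1L,
                       network$contacts$j[k] + 1L))
  }, numeric(1))
  network$contacts$geometry <- if (network$kind == "go_lj")
    rbar / 2^(1 / 6) else rbar
  network
}

#' Scale contact strengths by a perturbation vector
#'
#' Contact k's strength becomes strength_k (1 + lambda_k): lambda_k > 0
#' strengthens the interaction, lambda_k < 0 weakens it.  Results are clamped
#' from below at `strength_floor` to keep bonds physical (with a warning when
#' clamping fires, including the lambda <= -1 case).  Contact order, pairing
#' and geometry are unchanged.
#'
#' @param network an `InteractionNetwork`.
#' @param lambda_vector length-M perturbation vector.
#' @param strength_floor positive lower bound; default 0.5 kJ/mol for Go
#'   networks, 10 kJ/mol/nm^2 for elastic networks.
#' @return the perturbed `InteractionNetwork`.
#' @export
apply_perturbation <- function(network, lambda_vector, strength_floor = NULL) {
  .chk(length(lambda_vector) == n_contacts(network),
       "lambda length must equal contact count")
  .chk(all(is.finite(lambda_vector)), "non-finite lambda")
  if (is.null(strength_floor))
    strength_floor <- if (network$kind == "go_lj") 0.5 else 10
  .chk(strength_floor > 0, "strength_floor must be positive")
  s <- network$contacts$strength * (1 + lambda_vector)
  n_clamped <- sum(s < strength_floor)
  if (n_clamped > 0) {
    warning(sprintf("%d contact strength(s) clamped at floor %g",
                    n_clamped, strength_floor))
    s <- pmax(s, strength_floor)
  }
  network$contacts$strength <- s
  network
}

#' Pearson correlation of two networks' strength vectors
#'
#' Requires identical contact pair lists (same i, j in the same order).
#'
#' @param net_a,net_b `InteractionNetwork`s over the same topology.
#' @return correlation in \[-1, 1\]; error when either side has zero variance
#'   (e.g. a uniform network) or the pair lists differ.
#' @export
network_pearson <- function(net_a, net_b) {
  .chk(identical(net_a$contacts$i, net_b$contacts$i) &&
         identical(net_a$contacts$j, net_b$contacts$j),
       "contact pair lists differ")
  sa <- net_a$contacts$strength; sb <- net_b$contacts$strength
  .chk(stats::sd(sa) > 0 && stats::sd(sb) > 0,
       "zero strength variance (Pearson undefined, e.g. uniform network)")
  stats::cor(sa, sb)
}

# weighted graph Laplacian L = D - A with A_ij = strength of contact (i, j)
network_laplacian <- function(network, normalize = FALSE) {
  B <- network$n_beads
  A <- matrix(0, B, B)
  s <- network$contacts$strength
  if (normalize) s <- s / mean(s)
  idx <- cbind(network$contacts$i + 1L, network$contacts$j + 1L)
  A[idx] <- s
  A[idx[, c(2, 1), drop = FALSE]] <- s
  diag(rowSums(A)) - A
}

#' L2 distance between Laplacian eigenvalue spectra of two networks
#'
#' Builds the weighted graph Laplacian of each network (weights = raw
#' strengths, or strengths divided by their joint mean when
#' `normalize = TRUE`), takes the ascending eigenvalue spectrum of each by a
#' dense symmetric eigensolve, and returns the Euclidean norm of the
#' difference.  A pseudometric on networks with equal bead count.
#'
#' @param net_a,net_b `InteractionNetwork`s with equal `n_beads`.
#' @param normalize divide all strengths by the joint mean strength of the two
#'   networks before building the Laplacians (default `FALSE`).
#' @return non-negative spectral distance.
#' @export
laplacian_spectrum_distance <- function(net_a, net_b, normalize = FALSE) {
  .chk(net_a$n_beads == net_b$n_beads, "bead count mismatch")
  .chk(n_contacts(net_a) >= 1 && n_contacts(net_b) >= 1, "empty network")
  if (normalize) {
    joint <- mean(c(net_a$contacts$strength, net_b$contacts$strength))
    net_a$contacts$strength <- net_a$contacts$strength / joint
    net_b$contacts$strength <- net_b$contacts$strength / joint
  }
  ev_a <- sort(eigen(network_laplacian(net_a), symmetric = TRUE,
                     only.values = TRUE)$values)
  ev_b <- sort(eigen(network_laplacian(net_b), symmetric = TRUE,
                     only.values = TRUE)$values)
  sqrt(sum((ev_a - ev_b)^2))
}

#' Dump / load a network as a plain TSV table
#'
#' Columns: i, j (0-based), kind, strength, geometry.
#'
#' @param network an `InteractionNetwork`.
#' @param path file path.
#' @return `write_network_tsv` returns the path invisibly; `read_network_tsv`
#'   returns the `InteractionNetwork`.
#' @export
write_network_tsv <- function(network, path) {
  df <- network$contacts
  df$kind <- network$kind
  df$n_beads <- network$n_beads
  utils::write.table(df[, c("i", "j", "kind", "strength", "geometry",
                            "n_beads")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  interaction_network(df$i, df$j, df$kind[1], df$strength, df$geometry,
                      df$n_beads[1])
}
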
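# Shared in-code fixtures for the test suite.  Everything is generated
# programmatically under fixed seeds; nothing is read from disk except files
# the tests themselves write to tempdir().

# small deterministic ensemble: F frames of B beads jittered around a base
# structure (not superposed)
tiny_ensemble <- function(F = 6, B = 5, sd = 0.05, seed = 1) {
  base <- matrix(seq_len(B * 3) / 10, ncol = 3)
  coords <- with_seed(seed, {
    arr <- array(0, dim = c(F, B, 3))
    for (f in seq_len(F)) arr[f, , ] <- base + matrix(rnorm(B * 3, sd = sd),
                                                      ncol = 3)
    arr
  })
  bead_ensemble(coords)
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function(seed = 1) {
  with_seed(seed, {
    qr_d <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

# orthonormal basis of dimension d x n from a seeded Gaussian matrix
random_orthonormal <- function(d, n, seed = 1) {
  with_seed(seed, qr.Q(qr(matrix(rnorm(d * n), d, n))))
}

# small Go network on a fixed 3-bead-plus chain for networks tests
toy_network <- function(strengths = c(10, 12, 8), B = 6) {
  interaction_network(i = c(0, 1, 2), j = c(3, 4, 5), kind = "go_lj",
                      strength = strengths, geometry = c(0.5, 0.45, 0.55),
                      n_beads = B)
}

# handcrafted Go-dialect .itp fixture written to a temp file; returns the path
write_go_itp_fixture <- function(path = tempfile(fileext = ".itp")) {
  writeLines(c(
    "; synthetic Go-style topology fragment (martinize2 dialect)",
    "[ atomtypes ]",
    ";name  mass charge ptype c6 c12",
    " mol_go_1   0.0 0.000 A 0.0 0.0",
    " mol_go_4   0.0 0.000 A 0.0 0.0",
    " mol_go_7   0.0 0.000 A 0.0 0.0",
    " mol_go_9   0.0 0.000 A 0.0 0.0",
    "",
    "[ nonbond_params ]",
    "; i  j  funct  sigma  epsilon",
    " mol_go_1  mol_go_4  1  0.47014900  9.40000000",
    " mol_go_1  mol_go_7  1  0.52000000 12.50000000",
    " mol_go_4  mol_go_9  1  0.61250000  7.25000000",
    " mol_go_7  mol_go_9  1  0.44544000 15.00000000",
    "",
    "[ exclusions ]",
    " 1 4",
    " 1 7"), path)
  path
}

# handcrafted elastic-network .itp fixture ([ bonds ], funct 1, kappa 500)
write_enm_itp_fixture <- function(path = tempfile(fileext = ".itp")) {
  writeLines(c(
    "; synthetic elastic network fragment",
    "[ bonds ]",
    "; i  j  funct  r0  k",
    "  1   4  1  0.50000  500.0",
    "  2   5  1  0.45000  500.0",
    "  3   6  1  0.55000  500.0"), path)
  path
}

# brute-force order-gamma Wasserstein for equal-weight sets of equal size n
# (<= 8): exact optimum over all assignment permutations
wasserstein_bruteforce <- function(a, b, gamma) {
  n <- length(a)
  stopifnot(length(b) == n, n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) out <- c(out, lapply(perms(v[-k]),
                                                 function(p) c(v[k], p)))
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- mean(abs(a - b[p])^gamma)
    if (cost < best) best <- cost
  }
  best^(1 / gamma)
}
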
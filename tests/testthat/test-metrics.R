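# RMSIP, covariance overlap, 1-D Wasserstein, sliced Wasserstein.

test_that("rmsip is 1 on identical, 0 on orthogonal, basis-invariant in span", {
  Va <- random_orthonormal(12, 3, seed = 1)
  expect_equal(rmsip(subspace_pair(list(eigenvectors = Va, eigenvalues = 1:3),
                                   list(eigenvectors = Va, eigenvalues = 1:3))),
               1, tolerance = 1e-10)

  Q <- random_orthonormal(12, 6, seed = 2)
  pa <- list(eigenvectors = Q[, 1:3], eigenvalues = c(3, 2, 1))
  pb <- list(eigenvectors = Q[, 4:6], eigenvalues = c(3, 2, 1))
  expect_equal(rmsip(subspace_pair(pa, pb)), 0, tolerance = 1e-10)

  # in-span rotation of the basis leaves RMSIP at 1; matches brute-force sum
  Rot <- random_orthonormal(3, 3, seed = 3)
  pb2 <- list(eigenvectors = Va %*% Rot, eigenvalues = c(1, 1, 1))
  pr <- subspace_pair(pa_id <- list(eigenvectors = Va, eigenvalues = 1:3), pb2)
  brute <- sqrt(sum(crossprod(Va, Va %*% Rot)^2) / 3)
  expect_equal(rmsip(pr), brute, tolerance = 1e-12)
  expect_equal(rmsip(pr), 1, tolerance = 1e-10)

  # symmetry
  expect_equal(rmsip(subspace_pair(pa, pb2)), rmsip(subspace_pair(pb2, pa)),
               tolerance = 1e-12)
  # non-orthonormal input rejected
  bad <- list(eigenvectors = Va * 2, eigenvalues = 1:3)
  expect_error(rmsip(subspace_pair(bad, pa)), "orthonormal")
})

test_that("covariance overlap matches a brute-force evaluation of its formula", {
  Va <- random_orthonormal(10, 1, seed = 4)
  pa <- list(eigenvectors = Va, eigenvalues = 2.3)
  expect_equal(as.numeric(covariance_overlap(subspace_pair(pa, pa))), 1,
               tolerance = 1e-12)
  # identical subspaces with proportional spectra are a perfect match for any n
  Vn <- random_orthonormal(15, 4, seed = 44)
  pn <- list(eigenvectors = Vn, eigenvalues = c(5, 3, 2, 1))
  expect_equal(as.numeric(covariance_overlap(subspace_pair(pn, pn))), 1,
               tolerance = 1e-12)

  Q <- random_orthonormal(12, 6, seed = 5)
  ort_a <- list(eigenvectors = Q[, 1:3], eigenvalues = c(3, 2, 1))
  ort_b <- list(eigenvectors = Q[, 4:6], eigenvalues = c(5, 1, 0.5))
  expect_equal(as.numeric(covariance_overlap(subspace_pair(ort_a, ort_b))), 0,
               tolerance = 1e-12)

  # random 5-dimensional cases against a straight-line reimplementation
  for (seed in 1:5) {
    n <- 5
    Va <- random_orthonormal(20, n, seed = 100 + seed)
    Vb <- random_orthonormal(20, n, seed = 200 + seed)
    mu <- with_seed(300 + seed, sort(runif(n, 0.1, 4), decreasing = TRUE))
    nu <- with_seed(400 + seed, sort(runif(n, 0.1, 4), decreasing = TRUE))
    brute <- 0
    for (p in 1:n) for (q in 1:n)
      brute <- brute + (mu[p] * nu[q]) /
        (sqrt(sum(mu^2)) * sqrt(sum(nu^2))) * sum(Va[, p] * Vb[, q])^2
    got <- covariance_overlap(subspace_pair(
      list(eigenvectors = Va, eigenvalues = mu),
      list(eigenvectors = Vb, eigenvalues = nu)))
    expect_equal(attr(got, "raw"), brute, tolerance = 1e-10)
  }
  expect_error(covariance_overlap(subspace_pair(
    list(eigenvectors = Va, eigenvalues = rep(0, 5)),
    list(eigenvectors = Vb, eigenvalues = nu))), "all-zero")
})

test_that("wasserstein_1d has exact trivial cases and matches the brute-force oracle", {
  x <- c(0.3, -1, 2, 0.5)
  expect_equal(wasserstein_1d(x, x, gamma = 1), 0)
  expect_equal(wasserstein_1d(x, x, gamma = 3), 0)
  for (g in c(1, 2, 3))
    expect_equal(wasserstein_1d(0.4, -1.1, gamma = g), 1.5, tolerance = 1e-12)

  # equal-size unweighted, gamma = 1: mean |sorted a - sorted b|
  a <- with_seed(6, rnorm(7)); b <- with_seed(7, rnorm(7))
  expect_equal(wasserstein_1d(a, b, gamma = 1), mean(abs(sort(a) - sort(b))),
               tolerance = 1e-12)

  # brute-force assignment oracle on <= 8 points, several gammas and sizes
  for (seed in 1:6) {
    n <- with_seed(seed, sample(2:8, 1))
    a <- with_seed(10 + seed, rnorm(n))
    b <- with_seed(20 + seed, rnorm(n))
    g <- c(1, 2, 3)[1 + seed %% 3]
    expect_equal(wasserstein_1d(a, b, gamma = g),
                 wasserstein_bruteforce(a, b, g), tolerance = 1e-8)
  }
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
  expect_error(wasserstein_1d(1, 1, weights_a = 0, weights_b = 1), "zero total")
})

test_that("weighted wasserstein_1d equals the unweighted form on replicated atoms", {
  # weight 2 on an atom is the same as listing it twice
  a <- c(0, 1, 3); wa <- c(2, 1, 1)
  b <- c(0.5, 2)
  expect_equal(wasserstein_1d(a, b, weights_a = wa, gamma = 2),
               wasserstein_1d(c(0, 0, 1, 3), b, gamma = 2), tolerance = 1e-12)
})

test_that("sliced_wasserstein: degeneracies, translation closed form, symmetry", {
  X <- with_seed(8, matrix(rnorm(200 * 3), 200, 3))
  expect_equal(sliced_wasserstein(X, X, n_slices = 50, seed = 1), 0)

  # d = 1 equals wasserstein_1d exactly
  a <- matrix(with_seed(9, rnorm(40)), ncol = 1)
  b <- matrix(with_seed(10, rnorm(40)), ncol = 1)
  expect_equal(sliced_wasserstein(a, b, gamma = 3, n_slices = 7, seed = 2),
               wasserstein_1d(a[, 1], b[, 1], gamma = 3), tolerance = 1e-12)

  # translated cloud, gamma = 2, d = 3: SWD = |Delta| / sqrt(3)
  delta <- c(0.4, -0.2, 0.3)
  Y <- sweep(X, 2, delta, "+")
  swd <- sliced_wasserstein(X, Y, gamma = 2, n_slices = 10000, seed = 3)
  expect_equal(swd, sqrt(sum(delta^2)) / sqrt(3), tolerance = 0.02)

  # symmetry and rotation invariance (statistically, same slices)
  expect_equal(sliced_wasserstein(X, Y, gamma = 3, n_slices = 500, seed = 4),
               sliced_wasserstein(Y, X, gamma = 3, n_slices = 500, seed = 4),
               tolerance = 1e-12)
  R <- random_rotation(11)
  swd_rot <- sliced_wasserstein(X %*% t(R), Y %*% t(R), gamma = 2,
                                n_slices = 10000, seed = 5)
  expect_equal(swd_rot, sqrt(sum(delta^2)) / sqrt(3), tolerance = 0.02)
  expect_error(sliced_wasserstein(X, a), "dimension mismatch")
})

test_that("sliced_wasserstein satisfies the triangle inequality on random triples", {
  for (seed in 1:4) {
    pts <- with_seed(seed, list(matrix(rnorm(60), 30, 2),
                                matrix(rnorm(60, 1), 30, 2),
                                matrix(rnorm(60, -0.5, 2), 30, 2)))
    d <- function(i, j) sliced_wasserstein(pts[[i]], pts[[j]], gamma = 2,
                                           n_slices = 400, seed = 99)
    dab <- d(1, 2); dbc <- d(2, 3); dac <- d(1, 3)
    expect_lte(dac, dab + dbc + 1e-9)
    expect_lte(dab, dac + dbc + 1e-9)
  }
})

test_that("slice directions are unit vectors and seed-reproducible", {
  S <- slice_set(100, 4, seed = 42)
  expect_equal(sqrt(rowSums(S$directions^2)), rep(1, 100), tolerance = 1e-10)
  expect_identical(S$directions, slice_set(100, 4, seed = 42)$directions)
})
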
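# Term-matrix evaluation, cumulant basis, analytic reweighting estimator.

test_that("evaluate_terms converts contact energies to kT and matches a naive loop", {
  # single contact at its LJ minimum with epsilon = kT -> entry -1
  kT <- kBT(300)
  net <- interaction_network(0, 1, "go_lj", kT, 0.5, n_beads = 2)
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, 1] <- 2^(1 / 6) * 0.5
  tm <- evaluate_terms(bead_ensemble(coords), net, 300)
  expect_equal(tm$values[1, 1], -1, tolerance = 1e-12)
  expect_equal(tm$kBT_kJmol, 0.00831446 * 300)

  # elastic contact at r0 in every frame -> zero column
  enet <- interaction_network(0, 1, "enm_harmonic", 500, 0.5, n_beads = 2)
  coords2 <- array(0, c(3, 2, 3)); coords2[, 2, 1] <- 0.5
  expect_equal(evaluate_terms(bead_ensemble(coords2), enet)$values,
               matrix(0, 3, 1))

  # random 10-frame 5-contact case vs per-pair double loop
  ens <- tiny_ensemble(F = 10, B = 6, sd = 0.02, seed = 31)
  net5 <- interaction_network(c(0, 0, 1, 2, 3), c(2, 4, 3, 5, 5), "go_lj",
                              strength = c(5, 8, 11, 3, 7),
                              geometry = c(0.3, 0.5, 0.4, 0.45, 0.6),
                              n_beads = 6)
  tm5 <- evaluate_terms(ens, net5, 300)
  for (f in 1:10) for (k in 1:5) {
    i <- net5$contacts$i[k] + 1; j <- net5$contacts$j[k] + 1
    r <- sqrt(sum((ens$coords[f, i, ] - ens$coords[f, j, ])^2))
    expect_equal(tm5$values[f, k],
                 lj_energy(net5$contacts$strength[k],
                           net5$contacts$geometry[k], r) / kT,
                 tolerance = 1e-12)
  }

  # overlapping beads reported with indices
  bad <- ens; bad$coords[3, 3, ] <- bad$coords[3, 1, ]
  netbad <- interaction_network(0, 2, "go_lj", 5, 0.4, n_beads = 6)
  expect_error(evaluate_terms(bad, netbad), "contact 1, frame 3")
})

test_that("build_basis reproduces covariance structure", {
  # constant columns -> zero covariance and eigenvalues
  Lc <- matrix(rep(c(1.5, -2), each = 10), 10, 2)
  b0 <- build_basis(Lc)
  expect_equal(b0$covariance, matrix(0, 2, 2))
  expect_equal(b0$eigenvalues, c(0, 0))

  # eigendecomposition identity U Omega U' = C
  L <- with_seed(41, matrix(rnorm(400), 100, 4))
  b <- build_basis(L)
  expect_equal(b$eigenvectors %*% diag(b$eigenvalues) %*% t(b$eigenvectors),
               b$covariance, tolerance = 1e-10)
  # per-component mean of the centred eigenprojections is 0
  expect_lt(max(abs(colMeans(b$centered_eigenprojections))), 1e-8)

  # sampled 2-contact case with covariance [[2,1],[1,2]] -> eigenvalues (3,1)
  A <- chol(matrix(c(2, 1, 1, 2), 2, 2))
  Ls <- with_seed(42, matrix(rnorm(2 * 50000), 50000, 2) %*% A)
  bs <- build_basis(Ls)
  expect_equal(bs$eigenvalues, c(3, 1), tolerance = 0.03)
  expect_error(build_basis(L[1, , drop = FALSE]), "at least 2")
})

test_that("direct and eigenbasis forms of the log density ratio agree to 1e-10", {
  for (seed in 1:5) {
    L <- with_seed(seed, matrix(rnorm(50 * 6, sd = 2), 50, 6))
    w <- with_seed(seed + 50, runif(50))
    b <- build_basis(L, w)
    lam <- with_seed(seed + 100, runif(6, -0.3, 0.3))
    eig_form <- log_density_ratio(b, lam)
    direct <- as.vector(-(sweep(L, 2, b$mean) %*% lam)) -
      0.5 * as.numeric(crossprod(lam, b$covariance %*% lam))
    expect_equal(eig_form, direct, tolerance = 1e-10)
  }
  # lambda = 0 -> all zeros; M = 1 scalar algebra
  L1 <- with_seed(7, matrix(rexp(200), 200, 1))
  b1 <- build_basis(L1)
  expect_equal(log_density_ratio(b1, 0), rep(0, 200))
  lam <- 0.15
  expect_equal(log_density_ratio(b1, lam),
               -lam * (L1[, 1] - mean(L1)) -
                 0.5 * lam^2 * mean((L1 - mean(L1))^2),
               tolerance = 1e-10)
  expect_warning(log_density_ratio(b1, 5), "trust region")
})

test_that("exp of the log ratio weight-averages to 1 with third-order error", {
  L <- with_seed(8, matrix(rexp(2000) - 0.3, 2000, 1))   # skewed: kappa3 != 0
  b <- build_basis(L)
  err <- function(lam) abs(mean(exp(log_density_ratio(b, lam))) - 1)
  lam0 <- 0.2
  ratio <- err(lam0) / err(lam0 / 2)
  expect_gt(ratio, 5)
  expect_lt(ratio, 11)
})

test_that("psi_second_order matches cumulants and shows third-order error decay", {
  L <- with_seed(9, matrix(rexp(3000), 3000, 1))
  b <- build_basis(L)
  expect_equal(psi_second_order(b, 0), 0)
  lam <- 0.25
  expect_equal(psi_second_order(b, lam),
               -lam * mean(L) + 0.5 * lam^2 * mean((L - mean(L))^2),
               tolerance = 1e-12)
  # against direct exponential averaging on the same empirical sample
  psi_exact <- function(l) log(mean(exp(-l * L[, 1])))
  err <- function(l) abs(psi_second_order(b, l) - psi_exact(l))
  ratio <- err(lam) / err(lam / 2)
  expect_gt(ratio, 6)
  expect_lt(ratio, 10)
})

test_that("reweighting conserves probability and matches the harmonic closed form", {
  ens <- tiny_ensemble(F = 20, B = 5, seed = 51)
  L <- with_seed(52, matrix(rnorm(20 * 3), 20, 3))
  b <- build_basis(L)
  rw0 <- reweight_frames(ens, b, rep(0, 3))
  expect_equal(rw0$frame_weights, rep(1 / 20, 20))
  rw <- reweight_frames(ens, b, c(0.1, -0.05, 0.2))
  expect_true(all(rw$frame_weights >= 0))
  expect_equal(sum(rw$frame_weights), 1, tolerance = 1e-12)
  expect_equal(attr(rw0, "ess"), 20)

  # 1-D harmonic oracle: V = k x^2 / 2, strength scaling (1 + lambda)
  # multiplies k, so the perturbed variance is sigma^2 / (1 + lambda)
  kT <- kBT(300); k_spring <- 250
  sigma2 <- kT / k_spring
  F <- 1e5
  x <- with_seed(53, rnorm(F, sd = sqrt(sigma2)))
  Lh <- matrix(0.5 * k_spring * x^2 / kT, ncol = 1)
  bh <- build_basis(Lh)
  lam <- 0.2
  carrier <- bead_ensemble(array(0, c(F, 2, 3)))
  rwh <- reweight_frames(carrier, bh, lam)
  v_rw <- sum(rwh$frame_weights * x^2) - sum(rwh$frame_weights * x)^2
  expect_equal(v_rw, sigma2 / (1 + lam), tolerance = 0.02)

  # weighted mean of an observable is unchanged at lambda = 0
  obs <- with_seed(54, rnorm(20))
  expect_equal(sum(rw0$frame_weights * obs), mean(obs), tolerance = 1e-12)
})

test_that("ESS collapse triggers the diagnostic warning", {
  L <- with_seed(55, matrix(rnorm(100, sd = 40), 100, 1))
  b <- build_basis(L)
  ens <- bead_ensemble(array(0, c(100, 2, 3)))
  expect_warning(rw <- reweight_frames(ens, b, 0.29), "effective sample size")
  expect_lt(attr(rw, "ess") / 100, 0.05)
  expect_equal(sum(rw$frame_weights), 1, tolerance = 1e-12)
})

test_that("basis containers round-trip through save/load", {
  L <- with_seed(61, matrix(rnorm(60), 20, 3))
  b <- build_basis(L)
  path <- tempfile(fileext = ".rds")
  save_basis(b, path)
  b2 <- load_basis(path)
  expect_equal(b2$mean, b$mean)
  expect_equal(b2$covariance, b$covariance)
  expect_equal(b2$centered_eigenprojections, b$centered_eigenprojections)
  expect_s3_class(b2, "PerturbationBasis")
})

test_that("estimator and network update move the ensemble the same way", {
  # strengthening one contact (lambda_k > 0) must lower its mean energy both
  # under analytic reweighting and after re-simulating the perturbed network
  model <- make_toy_protein(12, 1)
  cfg <- sampler_config(n_steps = 4e5, burn_in = 4e4, thinning = 200, seed = 3)
  ens <- sample_mc(model, cfg)
  tm <- evaluate_terms(ens, model$network)
  b <- build_basis(tm)
  M <- n_contacts(model$network)
  k <- which.max(apply(tm$values, 2, stats::sd))   # a contact that fluctuates
  lam <- rep(0, M); lam[k] <- 0.3
  rw <- reweight_frames(bead_ensemble(ens$coords), b, lam)
  e_rw <- sum(rw$frame_weights * tm$values[, k])
  e_0 <- mean(tm$values[, k])

  net2 <- apply_perturbation(model$network, lam)
  cfg2 <- sampler_config(n_steps = 4e5, burn_in = 4e4, thinning = 200, seed = 4)
  ens2 <- sample_mc(model, cfg2, network = net2)
  # energies of the *original-strength* contact, for comparability
  e_sim <- mean(evaluate_terms(ens2, model$network)$values[, k])
  expect_lt(e_rw, e_0)        # reweighting predicts deeper binding
  expect_lt(e_sim, e_0)       # resimulation agrees in direction
})
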
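# Essential-subspace density estimation, the density-mismatch objective,
# particle swarm minimization, and the iterate-sample-reweight controller.

#' Regular grid specification over projected ensembles
#'
#' A per-dimension regular binning covering the union support of the supplied
#' point sets, padded by a fraction of the range on each side.
#'
#' @param points_list list of F x n point matrices (or `ProjectedEnsemble`s)
#'   whose union support the grid must cover.
#' @param bins bins per dimension (default 30).
#' @param pad fractional padding of the union range (default 0.05).
#' @return a `GridSpec`: `dim`, `bins`, `edges` (list of length-`bins`+1
#'   numeric vectors).
#' @export
grid_spec <- function(points_list, bins = 30, pad = 0.05) {
  pts <- lapply(points_list, function(p)
    if (inherits(p, "ProjectedEnsemble")) p$points else as.matrix(p))
  d <- ncol(pts[[1]])
  .chk(all(vapply(pts, ncol, integer(1)) == d), "dimension mismatch")
  all_pts <- do.call(rbind, pts)
  edges <- lapply(seq_len(d), function(a) {
    lo <- min(all_pts[, a]); hi <- max(all_pts[, a])
    span <- max(hi - lo, 1e-12)
    seq(lo - pad * span, hi + pad * span, length.out = bins + 1)
  })
  structure(list(dim = d, bins = as.integer(bins), edges = edges),
            class = "GridSpec")
}

# per-point linear cell index on a grid (1-based)
grid_cells <- function(points, grid) {
  d <- grid$dim; nb <- grid$bins
  idx <- vapply(seq_len(d), function(a)
    findInterval(points[, a], grid$edges[[a]], all.inside = TRUE),
    integer(nrow(points)))
  idx <- matrix(idx, ncol = d)
  cell <- idx[, 1]
  if (d > 1) for (a in 2:d) cell <- cell + (idx[, a] - 1L) * nb^(a - 1L)
  as.integer(cell)
}

# column-normalized discrete Gaussian smoothing kernel (nb x nb, sigma bins);
# R reference for the compiled separable convolution, kept for cross-checks
smoothing_kernel <- function(nb, sigma = 1, truncate = 4) {
  K <- outer(seq_len(nb), seq_len(nb), function(i, j) {
    dd <- abs(i - j)
    ifelse(dd <= truncate * sigma, exp(-dd^2 / (2 * sigma^2)), 0)
  })
  sweep(K, 2, colSums(K), "/")
}

# apply the separable kernel along every axis of a d-dimensional probability
# array stored as a plain vector of length nb^d
smooth_density_vec <- function(v, nb, d, K) {
  if (d == 1) return(as.vector(K %*% v))
  arr <- array(v, dim = rep(nb, d))
  for (a in seq_len(d)) {
    perm <- c(a, setdiff(seq_len(d), a))
    ap <- aperm(arr, perm)
    m <- K %*% matrix(ap, nrow = nb)
    ap <- array(m, dim = rep(nb, d))
    arr <- aperm(ap, order(perm))
  }
  as.vector(arr)
}

# core density pipeline: accumulate weights per cell, smooth, record occupancy,
# floor and renormalize
density_pipeline <- function(cell_idx, weights, grid, floor_p = 1e-4,
                             sigma_bins = 1) {
  nb <- grid$bins; d <- grid$dim
  w <- weights / sum(weights)
  h <- floor(4 * sigma_bins)
  kvals <- exp(-(0:h)^2 / (2 * sigma_bins^2))
  prob <- .density_grid_cpp(cell_idx, w, nb, d, kvals)
  occupied <- prob > floor_p
  prob <- pmax(prob, floor_p)
  prob <- prob / sum(prob)
  structure(list(dim = d, edges = grid$edges, prob = prob,
                 floor = floor_p, occupied = occupied, bins = nb),
            class = "DensityGrid")
}

#' Weighted, smoothed histogram density on a regular grid
#'
#' Weighted histogram of the projected frames on `grid`, smoothed with a small
#' Gaussian kernel (1 bin sigma by default), floored at `floor_p` and
#' renormalized to sum 1.  Cells whose pre-floor probability exceeds the floor
#' are flagged in the `occupied` mask used for admissibility decisions in the
#' objective.
#'
#' @param projected_ensemble a `ProjectedEnsemble` (or F x n matrix).
#' @param grid a `GridSpec` whose dimension matches the projection.
#' @param floor_p smallest admissible probability (default 1e-4).  The floor
#'   doubles as the occupancy threshold: with a 30^3 grid and a few thousand
#'   frames, a much smaller floor admits cells whose estimated mass is pure
#'   smoothing-kernel tail, and the log-density mismatch over those
#'   negligible-mass cells then dominates the objective; 1e-4 (about a tenth
#'   of a uniform cell's probability) keeps only cells with real support.
#' @param sigma_bins Gaussian kernel width in bins (default 1).
#' @param weights optional weights overriding the carried frame weights.
#' @return a `DensityGrid`.
#' @export
estimate_density <- function(projected_ensemble, grid, floor_p = 1e-4,
                             sigma_bins = 1, weights = NULL) {
  pts <- if (inherits(projected_ensemble, "ProjectedEnsemble"))
    projected_ensemble$points else as.matrix(projected_ensemble)
  .chk(nrow(pts) >= 1, "empty ensemble")
  .chk(ncol(pts) == grid$dim, "projection dimension does not match grid")
  if (is.null(weights))
    weights <- if (inherits(projected_ensemble, "ProjectedEnsemble"))
      projected_ensemble$frame_weights else rep(1, nrow(pts))
  density_pipeline(grid_cells(pts, grid), weights, grid, floor_p, sigma_bins)
}

#' Build a fast evaluator of the density-mismatch objective
#'
#' Precomputes everything that does not depend on lambda (cell assignment of
#' the coarse frames, the target and unperturbed coarse densities, and the
#' admissible-cell mask), returning a closure suitable for many PSO
#' evaluations.  The objective is
#' `chi(lambda) = sum_cells | ln(rho_T/rho_CG) - ln(rho_CG^lambda/rho_CG) |`
#' restricted to cells where both the target and the unperturbed coarse
#' density are occupied; `rho_CG^lambda` is the density of the coarse frames
#' reweighted with the analytic per-frame log ratio.  Cells the coarse
#' ensemble never visited are excluded (reweighting cannot populate unsampled
#' regions); the excluded fraction of target-occupied cells is reported as
#' attribute `"exclusion_fraction"` of the returned function.
#'
#' @param basis a `PerturbationBasis` built from the coarse ensemble.
#' @param projected_cg the coarse `ProjectedEnsemble` (same frames as the
#'   basis).
#' @param target_density a `DensityGrid` of the target on `grid`.
#' @param grid the shared `GridSpec`.
#' @param floor_p,sigma_bins density-estimation parameters (must match those
#'   used for `target_density`).
#' @return `function(lambda) -> chi`, with attribute `"exclusion_fraction"`.
#' @export
chi_evaluator <- function(basis, projected_cg, target_density, grid,
                          floor_p = 1e-4, sigma_bins = 1) {
  pts <- projected_cg$points
  .chk(nrow(pts) == basis$n_frames, "frame count mismatch with basis")
  cells <- grid_cells(pts, grid)
  w0 <- projected_cg$frame_weights / sum(projected_cg$frame_weights)
  cg0 <- density_pipeline(cells, w0, grid, floor_p, sigma_bins)
  admissible <- target_density$occupied & cg0$occupied
  if (!any(admissible))
    stop("disjoint supports: no grid cell is occupied by both ensembles; ",
         "widen the sampling or coarsen the grid", call. = FALSE)
  adm <- which(admissible)
  log_t <- log(target_density$prob[adm])
  log_cg0 <- log(cg0$prob[adm])
  excl <- sum(target_density$occupied & !cg0$occupied) /
    max(1, sum(target_density$occupied))
  h <- floor(4 * sigma_bins)
  kvals <- exp(-(0:h)^2 / (2 * sigma_bins^2))
  logw0 <- log(w0)
  fn <- function(lambda) {
    .chi_eval_cpp(lambda, basis$eigenvectors, basis$eigenvalues,
                  basis$centered_eigenprojections, logw0, cells,
                  grid$bins, grid$dim, kvals, floor_p, adm, log_t, log_cg0)
  }
  attr(fn, "exclusion_fraction") <- excl
  fn
}

#' Density-mismatch objective for one perturbation vector
#'
#' One-shot wrapper around [chi_evaluator()]; see there for the definition.
#'
#' @inheritParams chi_evaluator
#' @param lambda length-M perturbation vector.
#' @return non-negative chi value.
#' @export
objective_chi <- function(lambda, basis, projected_cg, target_density, grid,
                          floor_p = 1e-4, sigma_bins = 1) {
  chi_evaluator(basis, projected_cg, target_density, grid,
                floor_p, sigma_bins)(lambda)
}

#' Particle swarm optimizer configuration
#'
#' Constriction-style defaults: inertia 0.729 with cognitive and social
#' coefficients 1.494, swarm of 40 particles, up to 200 iterations per outer
#' step, search box \[-`lambda_bound`, `lambda_bound`\]^M (the trust region of
#' the perturbation estimate).  `patience`/`rel_tol` stop the swarm early once
#' the global best stops improving.
#'
#' @param swarm_size number of particles (>= 2).
#' @param inertia,cognitive,social PSO coefficients (>= 0).
#' @param max_iters maximum PSO iterations.
#' @param lambda_bound half-width of the search box.
#' @param seed mandatory integer seed.
#' @param patience PSO iterations without relative improvement `rel_tol`
#'   before stopping early.
#' @param rel_tol relative improvement threshold for `patience`.
#' @return a `PSOConfig` list.
#' @export
pso_config <- function(swarm_size = 40, inertia = 0.729, cognitive = 1.494,
                       social = 1.494, max_iters = 200, lambda_bound = 0.3,
                       seed = 1L, patience = 50, rel_tol = 1e-4) {
  .chk(swarm_size >= 2, "swarm_size must be >= 2")
  .chk(inertia >= 0 && cognitive >= 0 && social >= 0,
       "coefficients must be non-negative")
  .chk(!is.null(seed), "seed is mandatory")
  structure(list(swarm_size = as.integer(swarm_size), inertia = inertia,
                 cognitive = cognitive, social = social,
                 max_iters = as.integer(max_iters),
                 lambda_bound = lambda_bound, seed = as.integer(seed),
                 patience = as.integer(patience), rel_tol = rel_tol),
            class = "PSOConfig")
}

#' Global-best particle swarm minimization in a box
#'
#' Standard global-best PSO over \[-b, b\]^M with velocity clamping at half
#' the box width and position clamping at the box; fully reproducible from
#' `config$seed`.
#'
#' @param objective_callable `function(lambda) -> scalar`.
#' @param m_dims dimension M of the search space.
#' @param config a [pso_config()].
#' @return list with `lambda` (best-ever position), `value` (its objective),
#'   and `trace` (global-best value after each iteration, non-increasing).
#' @export
pso_minimize <- function(objective_callable, m_dims, config = pso_config()) {
  .chk(m_dims >= 1, "m_dims must be >= 1")
  b <- config$lambda_bound
  vmax <- b                                # half of the 2b box width
  S <- config$swarm_size
  with_seed(config$seed, {
    X <- matrix(runif(S * m_dims, -b, b), S, m_dims)
    V <- matrix(runif(S * m_dims, -vmax, vmax), S, m_dims)
    fX <- apply(X, 1, objective_callable)
    if (!any(is.finite(fX)))
      stop("objective not finite at any initial particle", call. = FALSE)
    P <- X; fP <- fX
    g <- which.min(fP)
    gbest <- X[g, ]; fgbest <- fP[g]
    trace <- numeric(0)
    since_improve <- 0L
    for (it in seq_len(config$max_iters)) {
      r1 <- matrix(runif(S * m_dims), S, m_dims)
      r2 <- matrix(runif(S * m_dims), S, m_dims)
      V <- config$inertia * V +
        config$cognitive * r1 * (P - X) +
        config$social * r2 * matrix(gbest, S, m_dims, byrow = TRUE) -
        config$social * r2 * X
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, -b), b)
      fX <- apply(X, 1, objective_callable)
      upd <- which(fX < fP)
      if (length(upd)) { P[upd, ] <- X[upd, ]; fP[upd] <- fX[upd] }
      g <- which.min(fP)
      if (fP[g] < fgbest) {
        improved <- (fgbest - fP[g]) > config$rel_tol * max(abs(fgbest), 1e-12)
        fgbest <- fP[g]; gbest <- P[g, ]
        since_improve <- if (improved) 0L else since_improve + 1L
      } else since_improve <- since_improve + 1L
      trace <- c(trace, fgbest)
      if (since_improve >= config$patience) break
    }
    list(lambda = gbest, value = fgbest, trace = trace)
  })
}

#' Full iterate-sample-reweight optimization of a contact network
#'
#' The outer loop of the method: (1) build the essential subspace of the
#' target ensemble once and keep it fixed; then repeatedly (2) sample a coarse
#' ensemble under the current network, build the perturbation basis from it
#' and PSO-minimize the density-mismatch objective, (3) apply the optimal
#' perturbation to the network, and (4) record similarity metrics.  The
#' perturbation is applied cumulatively: each iteration perturbs the current
#' network and the next basis is rebuilt from the newly sampled ensemble.
#' Before application each PSO solution is pruned to a minimal update
#' (components are zeroed, smallest first, whenever that preserves 99% of the
#' achieved objective improvement), so contacts are only touched when they
#' demonstrably move the landscape.  The network of the iteration with the
#' smallest recorded sliced Wasserstein distance is returned (not the last
#' one).
#'
#' @param target_ensemble the reference `BeadEnsemble`.
#' @param initial_network starting `InteractionNetwork`.
#' @param sampler `function(network, seed) -> BeadEnsemble`: draws an
#'   equilibrium ensemble of the model carrying `network` (see
#'   [make_mc_sampler()] for the built-in toy sampler and
#'   [external_sampler()] for the file-handoff contract).
#' @param opt_config list of options: `n_pcs` (subspace dimension, default 3,
#'   refused above 5 because higher-dimensional densities are too
#'   undersampled to optimize against), `max_iterations` (default 30),
#'   `patience` (5), `rel_tol` (0.02) on the SWD for early stopping, `seed`
#'   (root seed, default 1), `pso` (a [pso_config()]; its seed is re-derived
#'   from the root seed), `grid_bins` (30), `grid_pad` (0.05), `floor_p`
#'   (1e-8), `sigma_bins` (1), `gamma` (3), `n_slices` (1000),
#'   `temperature_K` (300), `strength_floor` (kind-dependent default).
#' @return list with `best_network`, `trace` (an `OptimizationTrace`),
#'   `subspace`, `noise_floor` and `best_iteration` (0-based, matching the
#'   trace's iteration numbering).
#' @export
run_optimization <- function(target_ensemble, initial_network, sampler,
                             opt_config = list()) {
  oc <- utils::modifyList(list(n_pcs = 3, max_iterations = 30, patience = 5,
                        rel_tol = 0.02, seed = 1L, pso = pso_config(),
                        grid_bins = 30, grid_pad = 0.05, floor_p = 1e-4,
                        sigma_bins = 1, gamma = 3, n_slices = 1000,
                        temperature_K = 300, strength_floor = NULL),
                   opt_config)
  if (oc$n_pcs > 5)
    stop("n_pcs > 5 refused: densities in more than five essential ",
         "dimensions are too undersampled for a meaningful objective",
         call. = FALSE)
  .chk(oc$n_pcs >= 1, "n_pcs must be >= 1")

  n_it <- oc$max_iterations
  seeds <- derive_seeds(oc$seed, 1 + 2 * n_it)
  slice_seed <- seeds[1]
  sampler_seeds <- seeds[1 + seq_len(n_it)]
  pso_seeds <- seeds[1 + n_it + seq_len(n_it)]

  # Step 1: fixed reference subspace from the target ensemble
  tgt <- superpose(target_ensemble,
                   target_ensemble$coords[1, , , drop = TRUE])
  mean1 <- apply(tgt$coords, c(2, 3), mean)
  tgt <- superpose(tgt, mean1)
  subspace <- compute_pca(tgt, oc$n_pcs)
  proj_t <- project(tgt, subspace)
  noise_floor <- swd_noise_floor(proj_t, gamma = oc$gamma,
                                 n_slices = oc$n_slices, seed = slice_seed)
  target_rmsf <- rmsf(tgt)

  network <- initial_network
  records <- list(); networks <- list(); lambdas <- list()
  swds <- numeric(0)
  for (it in seq_len(n_it)) {
    ens <- sampler(network, sampler_seeds[it])
    ens_fit <- superpose(ens, subspace$mean_structure)
    proj_cg <- project(ens_fit, subspace, superpose_first = FALSE)
    swd <- sliced_wasserstein(proj_t, proj_cg, gamma = oc$gamma,
                              n_slices = oc$n_slices, seed = slice_seed)
    cg_sub <- compute_pca(ens_fit, oc$n_pcs)
    pr <- subspace_pair(subspace, cg_sub)
    terms <- evaluate_terms(ens, network, oc$temperature_K)
    basis <- build_basis(terms, ens$frame_weights)
    grid <- grid_spec(list(proj_t, proj_cg), bins = oc$grid_bins,
                      pad = oc$grid_pad)
    tgt_dens <- estimate_density(proj_t, grid, oc$floor_p, oc$sigma_bins)
    chifn <- chi_evaluator(basis, proj_cg, tgt_dens, grid,
                           oc$floor_p, oc$sigma_bins)
    chi0 <- chifn(rep(0, n_contacts(network)))
    pcfg <- oc$pso; pcfg$seed <- pso_seeds[it]
    opt <- pso_minimize(chifn, n_contacts(network), pcfg)
    # minimal-update policy: the quadratic estimate is only trusted for small
    # perturbations, and along objective-flat directions PSO drifts to the
    # trust-region edge on noise alone, which compounds across iterations
    # into a multiplicative random walk of the strengths.  Greedily zero
    # every component whose removal keeps at least 99% of the achieved chi
    # improvement (smallest first), so only contacts that demonstrably move
    # the landscape are updated.
    budget <- opt$value + 0.01 * max(chi0 - opt$value, 0)
    lam <- opt$lambda
    cur <- opt$value
    for (k in order(abs(lam))) {
      trial <- lam; trial[k] <- 0
      v <- chifn(trial)
      if (v <= budget) { lam <- trial; cur <- v }
    }
    n_kept <- sum(lam != 0)
    opt$lambda <- lam
    opt$value <- cur
    rw <- suppressWarnings(reweight_frames(proj_cg, basis, opt$lambda,
                                           trust_bound = Inf))
    records[[it]] <- data.frame(
      iteration = it - 1L, swd = swd, chi0 = chi0, chi = opt$value,
      rmsip = rmsip(pr), co = as.numeric(covariance_overlap(pr)),
      rmsf_aue = rmsf_aue(target_rmsf, rmsf(ens_fit)),
      lambda_nonzero = n_kept,
      ess = attr(rw, "ess"), ess_frac = attr(rw, "ess") / n_frames(ens),
      exclusion_fraction = attr(chifn, "exclusion_fraction"),
      sampler_seed = sampler_seeds[it], pso_seed = pso_seeds[it])
    networks[[it]] <- network
    lambdas[[it]] <- opt$lambda
    swds <- c(swds, swd)
    if (it < n_it && length(swds) > oc$patience) {
      recent <- min(tail(swds, oc$patience))
      prior <- min(head(swds, length(swds) - oc$patience))
      if (recent > prior * (1 - oc$rel_tol)) break
    }
    if (it < n_it)
      network <- suppressWarnings(
        apply_perturbation(network, opt$lambda, oc$strength_floor))
  }
  rec <- do.call(rbind, records)
  best <- which.min(rec$swd)
  trace <- structure(list(records = rec, networks = networks,
                          lambdas = lambdas, best_iteration = best - 1L,
                          noise_floor = noise_floor,
                          slice_seed = slice_seed),
                     class = "OptimizationTrace")
  list(best_network = networks[[best]], trace = trace, subspace = subspace,
       noise_floor = noise_floor, best_iteration = best - 1L)
}

#' @export
print.OptimizationTrace <- function(x, ...) {
  r <- x$records
  cat(sprintf("OptimizationTrace: %d iterations; SWD %.4g -> best %.4g (iteration %d); noise floor %.4g\n",
              nrow(r), r$swd[1], min(r$swd), x$best_iteration, x$noise_floor))
  invisible(x)
}

#' File-handoff sampler for an external simulation engine
#'
#' Implements the controller side of the external-sampler contract: for every
#' requested ensemble the current network is written to a working directory as
#' a TSV (plus a rewritten .itp when the network originated from one) together
#' with a JSON job manifest (seed, temperature, file names); `submit_fn` is
#' then called with the manifest path and must return the path of a trajectory
#' file (.gro or .pdb) sampled under that network, which is loaded and
#' returned.  No engine is invoked by the package itself.
#'
#' @param workdir directory for the handoff files (created if missing).
#' @param submit_fn `function(manifest_path) -> trajectory_path`.
#' @param itp_document optional [read_itp()] document for .itp emission.
#' @param temperature_K recorded in the manifest (default 300).
#' @return a sampler `function(network, seed) -> BeadEnsemble`.
#' @export
external_sampler <- function(workdir, submit_fn, itp_document = NULL,
                             temperature_K = 300) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  counter <- 0L
  function(network, seed) {
    counter <<- counter + 1L
    net_path <- file.path(workdir, sprintf("network_%03d.tsv", counter))
    write_network_tsv(network, net_path)
    files <- list(network_tsv = net_path)
    if (!is.null(itp_document)) {
      itp_path <- file.path(workdir, sprintf("network_%03d.itp", counter))
      write_itp(itp_document, network, itp_path)
      files$network_itp <- itp_path
    }
    manifest <- file.path(workdir, sprintf("job_%03d.json", counter))
    jsonlite::write_json(list(job = counter, seed = seed,
                              temperature_K = temperature_K, files = files),
                         manifest, auto_unbox = TRUE)
    traj <- submit_fn(manifest)
    .chk(is.character(traj) && file.exists(traj),
         "external sampler did not return an existing trajectory path")
    load_ensemble(traj)
  }
}
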
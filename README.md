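# goperturb

Refines the per-contact strengths of structure-based interaction networks —
Go-type Lennard-Jones contacts or harmonic elastic-network springs attached
to a coarse-grained protein backbone model — so that the coarse model's
free-energy landscape in a fixed essential subspace matches a reference
("target") ensemble.  Intended for practitioners of Go/elastic-network
Martini modelling who have an atomistic (or other trusted) ensemble already
mapped to backbone-bead resolution and want the coarse model to populate the
same collective-motion landscape, not just hold the fold together.

## Method in brief

With the coarse potential $V(q) = \sum_i L_i(q)$ and the per-frame energies
of the $M$ network contacts $L = [L_1,\dots,L_M]^\top$ (in $k_BT$), a
perturbation $\lambda$ scales strengths as
$\varepsilon_k \to (1+\lambda_k)\varepsilon_k$, i.e.
$V_\lambda = V + \lambda^\top L$.  A second-order cumulant expansion of
$\psi(\lambda) = \ln\langle e^{-\lambda^\top L}\rangle$ gives the analytic
per-frame reweighting

$$\ln\frac{\rho_\lambda}{\rho} \approx
  -\lambda^\top (L - \langle L\rangle) - \tfrac12 \lambda^\top C \lambda,$$

so the effect of *any* candidate $\lambda$ on the sampled distribution can be
predicted without new simulation.  Candidate perturbations are scored by the
density-mismatch objective on a grid over the essential subspace
(the top principal components of the target's Cartesian covariance),

$$\chi(\lambda) = \sum_q \left|\ln\tfrac{\rho_T(q)}{\rho_{CG}(q)}
 - \ln\tfrac{\rho^\lambda_{CG}(q)}{\rho_{CG}(q)}\right| ,$$

minimized by global-best particle swarm optimization inside the trust region
$\|\lambda\|_\infty \le 0.3$.  The outer loop alternates sampling under the
current network, PSO over the analytic estimate, and a cumulative network
update, and returns the network of the best-scoring iteration.  Agreement is
tracked with the root-mean-square inner product (RMSIP), an
eigenvalue-weighted covariance overlap (CO), the sliced Wasserstein distance
(SWD, order 3) and per-bead RMSF error.  A self-contained Metropolis Monte
Carlo sampler over bead-chain toy models exercises the whole loop with an
exactly known Boltzmann target; the `vignettes/network-optimization.Rmd`
vignette documents every model assumption and numerical choice.

## Worked example

Ground-truth recovery on the built-in 20-bead fixture: a heterogeneous Go
network (strengths log-uniform in 4–20 kJ/mol) defines the target ensemble;
optimization starts from a uniform network at the ground-truth mean.

```r
library(goperturb)

fx  <- make_recovery_fixture(seed = 1)
res <- run_optimization(fx$target, fx$initial_network,
                        make_mc_sampler(fx$model),
                        opt_config = list(seed = 42, max_iterations = 30,
                                          patience = 30))
res$trace
#> OptimizationTrace: 30 iterations; SWD 2.391 -> best 0.0788 (iteration 9); noise floor 0.1684
rec <- res$trace$records
round(rec[c(1, res$best_iteration + 1),
          c("iteration", "swd", "rmsip", "co", "rmsf_aue")], 4)
#>    iteration    swd  rmsip     co rmsf_aue
#> 1          0 2.3910 0.8915 0.9902   0.1892
#> 10         9 0.0788 0.9915 0.9977   0.0049
```

Reading: the uniform network's ensemble sits 2.39 nm (in sliced-Wasserstein
distance over the first 3 PCs) from the target — about 14x the target's own
split-half sampling floor of 0.17 nm.  Nine iterations later the refined
network reproduces the target landscape to 0.079 nm, *below* the sampling
floor, while the per-bead fluctuation error (never an explicit target) falls
from 0.19 to 0.005 nm and the subspace-agreement scores rise toward 1.  The
same run from the command line:

```sh
Rscript inst/cli/goperturb toy-demo --seed 42 --out demo_out
Rscript inst/cli/goperturb metrics --traj-a target.gro --traj-b model.gro --n-pcs 3 --seed 1
```

Real networks enter either as plain TSV tables (`read_network_tsv()`) or as
martinize2-style GROMACS `.itp` fragments (`read_itp()` / `write_itp()`,
byte-preserving for unmodified content); `external_sampler()` documents the
file-handoff contract for driving a real simulation engine instead of the
built-in sampler.

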
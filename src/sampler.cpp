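// Metropolis Monte Carlo sampler for bead-chain toy models.
//
// Move mixture: single-bead Gaussian displacements plus chain pivot moves
// (rotate the chain on one side of a randomly chosen pivot bead by a random
// angle about a random axis through the pivot).  Both proposals are
// symmetric, so acceptance min(1, e^{-dV/kT}) leaves the Boltzmann
// distribution invariant; pivots are essential for decorrelating the soft
// collective (hinge/bending) modes that single-bead moves only diffuse
// through slowly.  The potential is a sum of pairwise terms (harmonic
// backbone bonds plus a Go LJ or elastic harmonic contact network); dV is
// computed from the terms whose endpoints straddle the move.  Uses R's RNG,
// so runs are reproducible via set.seed()/with_seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double term_energy(int kind, double a, double g, double r) {
  if (kind == 0) {                 // Lennard-Jones: a = epsilon, g = sigma
    double sr = g / r;
    double sr6 = sr * sr * sr;
    sr6 = sr6 * sr6;
    return 4.0 * a * (sr6 * sr6 - sr6);
  }
  if (kind == 2) {                 // soft-sphere repulsion: 4 a (g/r)^12
    double sr = g / r;
    double sr6 = sr * sr * sr;
    sr6 = sr6 * sr6;
    return 4.0 * a * sr6 * sr6;
  }
  double d = r - g;                // harmonic: a = kappa, g = r0
  return 0.5 * a * d * d;
}

static inline double pair_dist(const std::vector<double>& x, int i, int j) {
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export(name = ".mc_sample_cpp")]]
List mc_sample_cpp(NumericMatrix coords0, IntegerVector term_i,
                   IntegerVector term_j, IntegerVector term_kind,
                   NumericVector term_a, NumericVector term_g,
                   double kT, int n_steps, int burn_in, int thinning,
                   double step_size, bool tune, double pivot_prob,
                   double rot_step) {
  const int B = coords0.nrow();
  const int T = term_i.size();
  std::vector<double> x(3 * B), xtrial(3 * B);
  for (int b = 0; b < B; ++b)
    for (int d = 0; d < 3; ++d) x[3 * b + d] = coords0(b, d);

  std::vector<std::vector<int> > nbr(B);
  for (int t = 0; t < T; ++t) {
    nbr[term_i[t]].push_back(t);
    nbr[term_j[t]].push_back(t);
  }

  double energy = 0.0;
  for (int t = 0; t < T; ++t)
    energy += term_energy(term_kind[t], term_a[t], term_g[t],
                          pair_dist(x, term_i[t], term_j[t]));
  if (!R_finite(energy))
    stop("non-finite energy at the starting structure");

  const int n_frames = (n_steps > burn_in) ? (n_steps - burn_in) / thinning : 0;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * B * 3);
  NumericVector frame_energy(n_frames);
  int frame = 0;

  RNGScope scope;
  long acc_bead = 0, prop_bead = 0, acc_piv = 0, prop_piv = 0;
  int winb_acc = 0, winb_n = 0;
  const int tune_window = 1000;
  double step = step_size, rstep = rot_step;
  std::vector<char> rot(B);

  for (int s = 1; s <= n_steps; ++s) {
    bool pivot = (B >= 3) && (pivot_prob > 0.0) && (unif_rand() < pivot_prob);
    double dV;
    if (!pivot) {
      int b = (int)std::floor(unif_rand() * B);
      if (b == B) b = B - 1;
      double old_xyz[3] = { x[3 * b], x[3 * b + 1], x[3 * b + 2] };
      double e_old = 0.0;
      for (size_t q = 0; q < nbr[b].size(); ++q) {
        int t = nbr[b][q];
        e_old += term_energy(term_kind[t], term_a[t], term_g[t],
                             pair_dist(x, term_i[t], term_j[t]));
      }
      for (int d = 0; d < 3; ++d) x[3 * b + d] += step * norm_rand();
      double e_new = 0.0;
      for (size_t q = 0; q < nbr[b].size(); ++q) {
        int t = nbr[b][q];
        e_new += term_energy(term_kind[t], term_a[t], term_g[t],
                             pair_dist(x, term_i[t], term_j[t]));
      }
      dV = e_new - e_old;
      bool accept = R_finite(dV) &&
        (dV <= 0.0 || unif_rand() < std::exp(-dV / kT));
      ++prop_bead; ++winb_n;
      if (accept) { energy += dV; ++acc_bead; ++winb_acc; }
      else for (int d = 0; d < 3; ++d) x[3 * b + d] = old_xyz[d];
    } else {
      int k = 1 + (int)std::floor(unif_rand() * (B - 2));
      if (k > B - 2) k = B - 2;
      bool tail = unif_rand() < 0.5;
      for (int b = 0; b < B; ++b)
        rot[b] = tail ? (b > k) : (b < k);
      // random axis (isotropic) and Gaussian angle: symmetric proposal
      double ax, ay, az, n2;
      do {
        ax = norm_rand(); ay = norm_rand(); az = norm_rand();
        n2 = ax * ax + ay * ay + az * az;
      } while (n2 < 1e-12);
      double inv = 1.0 / std::sqrt(n2);
      ax *= inv; ay *= inv; az *= inv;
      double th = rstep * norm_rand();
      double ct = std::cos(th), st = std::sin(th);
      const double px = x[3 * k], py = x[3 * k + 1], pz = x[3 * k + 2];
      std::copy(x.begin(), x.end(), xtrial.begin());
      for (int b = 0; b < B; ++b) {
        if (!rot[b]) continue;
        double vx = x[3 * b] - px, vy = x[3 * b + 1] - py,
               vz = x[3 * b + 2] - pz;
        double dot = ax * vx + ay * vy + az * vz;
        double cx = ay * vz - az * vy, cy = az * vx - ax * vz,
               cz = ax * vy - ay * vx;
        xtrial[3 * b]     = px + vx * ct + cx * st + ax * dot * (1 - ct);
        xtrial[3 * b + 1] = py + vy * ct + cy * st + ay * dot * (1 - ct);
        xtrial[3 * b + 2] = pz + vz * ct + cz * st + az * dot * (1 - ct);
      }
      dV = 0.0;
      for (int t = 0; t < T; ++t) {
        if (rot[term_i[t]] == rot[term_j[t]]) continue;  // distance preserved
        dV += term_energy(term_kind[t], term_a[t], term_g[t],
                          pair_dist(xtrial, term_i[t], term_j[t])) -
              term_energy(term_kind[t], term_a[t], term_g[t],
                          pair_dist(x, term_i[t], term_j[t]));
      }
      bool accept = R_finite(dV) &&
        (dV <= 0.0 || unif_rand() < std::exp(-dV / kT));
      ++prop_piv;
      if (accept) { energy += dV; ++acc_piv; x.swap(xtrial); }
      (void)0;
    }
    // step-size auto-tuning toward 30-50% acceptance, burn-in only
    if (tune && s <= burn_in) {
      if (winb_n >= tune_window) {
        double rate = (double)winb_acc / winb_n;
        if (rate < 0.30) step *= 0.9;
        else if (rate > 0.50) step *= 1.1;
        winb_acc = 0; winb_n = 0;
      }
      // rot_step is deliberately NOT tuned: in compact folds large pivots
      // have low acceptance yet decorrelate the collective modes far better
      // than the small rotations an acceptance-targeted tuner converges to.
    }
    if (s > burn_in && (s - burn_in) % thinning == 0 && frame < n_frames) {
      for (int b2 = 0; b2 < B; ++b2)
        for (int d = 0; d < 3; ++d)
          frames[frame + n_frames * (b2 + (R_xlen_t)B * d)] = x[3 * b2 + d];
      frame_energy[frame] = energy;
      ++frame;
    }
  }

  frames.attr("dim") = IntegerVector::create(n_frames, B, 3);
  return List::create(_["frames"] = frames,
                      _["frame_energy"] = frame_energy,
                      _["acceptance_rate"] =
                        (double)(acc_bead + acc_piv) /
                        std::max(1L, prop_bead + prop_piv),
                      _["acceptance_rate_bead"] =
                        prop_bead ? (double)acc_bead / prop_bead : NA_REAL,
                      _["acceptance_rate_pivot"] =
                        prop_piv ? (double)acc_piv / prop_piv : NA_REAL,
                      _["step_size"] = step,
                      _["rot_step"] = rstep);
}
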
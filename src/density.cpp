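// Hot paths of the density estimator and the density-mismatch objective:
// weighted accumulation onto a regular d-dimensional grid followed by
// separable truncated-Gaussian smoothing, and the full per-lambda objective
// evaluation used inside particle swarm optimization.
//
// Each smoothing pass distributes mass from source cell j to targets i with
// kernel k(|i-j|) normalized over the targets available inside the grid, so
// total mass is conserved exactly (matching the column-normalized kernel
// matrix of the R reference implementation).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void smooth_separable(std::vector<double>& v, std::vector<double>& out,
                             int nb, int d, const NumericVector& kvals) {
  const int h = kvals.size() - 1;
  R_xlen_t ncell = v.size();
  std::vector<double> norm(nb);
  for (int j = 0; j < nb; ++j) {
    double s = 0.0;
    for (int i = std::max(0, j - h); i <= std::min(nb - 1, j + h); ++i)
      s += kvals[std::abs(i - j)];
    norm[j] = s;
  }
  R_xlen_t pre = 1;
  for (int axis = 0; axis < d; ++axis) {
    R_xlen_t post = ncell / (pre * nb);
    std::fill(out.begin(), out.end(), 0.0);
    for (R_xlen_t q = 0; q < post; ++q) {
      const R_xlen_t base_q = q * nb * pre;
      for (int j = 0; j < nb; ++j) {
        const R_xlen_t row_j = base_q + (R_xlen_t)j * pre;
        const int lo = std::max(0, j - h), hi = std::min(nb - 1, j + h);
        for (R_xlen_t p = 0; p < pre; ++p) {
          const double vj = v[row_j + p];
          if (vj == 0.0) continue;
          const double scaled = vj / norm[j];
          for (int i = lo; i <= hi; ++i)
            out[base_q + (R_xlen_t)i * pre + p] += scaled * kvals[std::abs(i - j)];
        }
      }
    }
    v.swap(out);
    pre *= nb;
  }
}

// [[Rcpp::export(name = ".density_grid_cpp")]]
NumericVector density_grid_cpp(IntegerVector cells, NumericVector w,
                               int nb, int d, NumericVector kvals) {
  R_xlen_t ncell = 1;
  for (int a = 0; a < d; ++a) ncell *= nb;
  std::vector<double> v(ncell, 0.0), scratch(ncell, 0.0);
  for (R_xlen_t f = 0; f < cells.size(); ++f) v[cells[f] - 1] += w[f];
  smooth_separable(v, scratch, nb, d, kvals);
  double total = 0.0;
  for (R_xlen_t c = 0; c < ncell; ++c) total += v[c];
  NumericVector res(ncell);
  for (R_xlen_t c = 0; c < ncell; ++c) res[c] = v[c] / total;
  return res;
}

// Full objective chi(lambda): reweight frames with the analytic second-order
// log density ratio (in the covariance eigenbasis), re-histogram, smooth,
// floor + renormalize, and sum |(log_t - log_cg0) - (log_dl - log_cg0)| over
// the admissible cells.
// [[Rcpp::export(name = ".chi_eval_cpp")]]
double chi_eval_cpp(NumericVector lambda, NumericMatrix U, NumericVector omega,
                    NumericMatrix Bproj, NumericVector logw0,
                    IntegerVector cells, int nb, int d, NumericVector kvals,
                    double floor_p, IntegerVector adm, NumericVector log_t,
                    NumericVector log_cg0) {
  const int M = U.nrow();
  const R_xlen_t F = Bproj.nrow();
  std::vector<double> xi(M, 0.0);
  for (int k = 0; k < M; ++k) {
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += U(m, k) * lambda[m];
    xi[k] = s;
  }
  double quad = 0.0;
  for (int k = 0; k < M; ++k) quad += omega[k] * xi[k] * xi[k];
  std::vector<double> lw(F);
  double lwmax = R_NegInf;
  for (R_xlen_t f = 0; f < F; ++f) {
    double s = 0.0;
    for (int k = 0; k < M; ++k) s += Bproj(f, k) * xi[k];
    lw[f] = logw0[f] - s - 0.5 * quad;
    if (lw[f] > lwmax) lwmax = lw[f];
  }
  R_xlen_t ncell = 1;
  for (int a = 0; a < d; ++a) ncell *= nb;
  std::vector<double> v(ncell, 0.0), scratch(ncell, 0.0);
  double wsum = 0.0;
  for (R_xlen_t f = 0; f < F; ++f) {
    double w = std::exp(lw[f] - lwmax);
    v[cells[f] - 1] += w;
    wsum += w;
  }
  if (wsum <= 0.0 || !R_finite(wsum))
    stop("all frame weights underflowed in the objective");
  for (R_xlen_t c = 0; c < ncell; ++c) v[c] /= wsum;
  smooth_separable(v, scratch, nb, d, kvals);
  double total = 0.0;
  for (R_xlen_t c = 0; c < ncell; ++c) {
    v[c] = std::max(v[c], floor_p);
    total += v[c];
  }
  double chi = 0.0;
  for (R_xlen_t a = 0; a < adm.size(); ++a) {
    const double log_dl = std::log(v[adm[a] - 1] / total);
    chi += std::fabs((log_t[a] - log_cg0[a]) - (log_dl - log_cg0[a]));
  }
  return chi;
}
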
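#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Euler-Maruyama integration of a network of stochastic phase oscillators
//   dphi_i = [omega_i + sum_j Gamma_ij(phi_i - phi_j)] h + sqrt(2 D_i h) z
// Spikes are emitted at the linearly interpolated times where phi_i crosses
// successive multiples of 2*pi (first upward crossing only, so backward
// diffusion across an already-crossed level never retracts a spike).
// Uses R's RNG (norm_rand), so results are reproducible under set.seed().
//
// Edges are flattened: edge e couples sender edge_from[e] onto receiver
// edge_to[e] (0-based) with edge_M[e] harmonics whose coefficients sit at
// edge_a[edge_off[e] .. edge_off[e] + M - 1] (same for edge_b).
// [[Rcpp::export]]
List simulate_phases_cpp(NumericVector omega,
                         NumericVector D,
                         IntegerVector edge_to,
                         IntegerVector edge_from,
                         IntegerVector edge_M,
                         IntegerVector edge_off,
                         NumericVector edge_a,
                         NumericVector edge_b,
                         NumericVector phi0,
                         double duration,
                         double h,
                         int thin) {
  const int n = omega.size();
  const int n_edges = edge_to.size();
  const long n_steps = (long)std::ceil(duration / h - 1e-9);
  const double two_pi = 2.0 * M_PI;

  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> drift(n);
  std::vector<double> noise_sd(n);
  std::vector<double> next_cross(n);
  std::vector<long> neg_steps(n, 0);
  std::vector<std::vector<double> > spikes(n);
  for (int i = 0; i < n; ++i) {
    noise_sd[i] = std::sqrt(2.0 * D[i] * h);
    next_cross[i] = two_pi * std::floor(phi[i] / two_pi + 1.0);
  }

  const bool keep_paths = thin > 0;
  long n_keep = keep_paths ? (n_steps / thin + 1) : 0;
  NumericMatrix paths(keep_paths ? n_keep : 1, keep_paths ? n : 1);
  NumericVector path_times(keep_paths ? n_keep : 1);
  long kept = 0;
  if (keep_paths) {
    for (int i = 0; i < n; ++i) paths(0, i) = phi[i];
    path_times[0] = 0.0;
    kept = 1;
  }

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * h;
    for (int i = 0; i < n; ++i) drift[i] = omega[i];
    for (int e = 0; e < n_edges; ++e) {
      const double d = phi[edge_to[e]] - phi[edge_from[e]];
      const int off = edge_off[e];
      double g = 0.0;
      for (int m = 1; m <= edge_M[e]; ++m) {
        g += edge_a[off + m - 1] * std::cos(m * d) +
             edge_b[off + m - 1] * std::sin(m * d);
      }
      drift[edge_to[e]] += g;
    }
    for (int i = 0; i < n; ++i) {
      if (drift[i] <= 0.0) ++neg_steps[i];
      double dphi = drift[i] * h;
      if (noise_sd[i] > 0.0) dphi += noise_sd[i] * norm_rand();
      const double phi_new = phi[i] + dphi;
      while (phi_new >= next_cross[i]) {
        const double frac = (next_cross[i] - phi[i]) / (phi_new - phi[i]);
        spikes[i].push_back(t + frac * h);
        next_cross[i] += two_pi;
      }
      phi[i] = phi_new;
    }
    if (keep_paths && ((step + 1) % thin == 0)) {
      if (kept < n_keep) {
        for (int i = 0; i < n; ++i) paths(kept, i) = phi[i];
        path_times[kept] = (step + 1) * h;
        ++kept;
      }
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  NumericVector negfrac(n);
  for (int i = 0; i < n; ++i) negfrac[i] = (double)neg_steps[i] / (double)n_steps;
  List out = List::create(_["spikes"] = spk,
                          _["phi_end"] = NumericVector(phi.begin(), phi.end()),
                          _["neg_drift_fraction"] = negfrac,
                          _["t_end"] = (double)n_steps * h);
  if (keep_paths) {
    out["paths"] = paths;
    out["path_times"] = path_times;
  }
  return out;
}
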
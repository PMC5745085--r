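#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact (direct-method) stochastic simulation of one realization of either
// dimerization network at integer molecule counts.
//
// Reactions (propensities in events/s; omega_na = Omega * N_A in 1/M):
//   production:     0 -> N        a = lambda_N(t) * omega_na
//   degradation:    N -> 0        a = beta_N * nN
//   degradation:    V -> 0        a = beta_V * nV          (primed only)
//   dimerization:   N + V -> D    a = (lambda_D/omega_na) * nN * nV (primed)
//   dimerization:   N -> D        a = (lambda_D/omega_na) * nN*(nN-1)
//                                 (cold-start; consumes ONE monomer so the
//                                 mean field reproduces dN/dt = -lambda_D N^2,
//                                 dD/dt = +lambda_D N^2 exactly)
//
// The production propensity is piecewise constant in time, so simulation is
// split at the window boundaries t_on/t_off; within each segment all
// propensities are time-homogeneous and the plain direct method is exact.
// Uses R's RNG stream: reproducible via set.seed() on the R side.

// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(bool primed, double lambda_on, double beta_N,
                          double beta_V, double lambda_D, double omega_na,
                          int n_V0, double t_on, double t_off,
                          NumericVector record_times) {
  const int nt = record_times.size();
  IntegerMatrix out(nt, 3);
  const double t_end = record_times[nt - 1];

  long long nN = 0, nV = primed ? (long long)n_V0 : 0, nD = 0;
  int rec = 0;
  double t = 0.0;
  const double c_dim = lambda_D / omega_na;

  std::vector<double> cuts;
  cuts.push_back(0.0);
  if (t_on > 0.0 && t_on < t_end) cuts.push_back(t_on);
  if (t_off > 0.0 && t_off < t_end) cuts.push_back(t_off);
  cuts.push_back(t_end);

  for (size_t k = 0; k + 1 < cuts.size(); ++k) {
    const double seg_end = cuts[k + 1];
    const double mid = 0.5 * (cuts[k] + seg_end);
    const double a_prod =
        (mid > t_on && mid < t_off) ? lambda_on * omega_na : 0.0;

    for (;;) {
      const double a_degN = beta_N * (double)nN;
      const double a_degV = primed ? beta_V * (double)nV : 0.0;
      double a_dim = primed ? c_dim * (double)nN * (double)nV
                            : c_dim * (double)nN * ((double)nN - 1.0);
      if (a_dim < 0.0) a_dim = 0.0;
      const double a0 = a_prod + a_degN + a_degV + a_dim;

      double t_next;
      if (a0 <= 0.0) {
        t_next = seg_end;  // nothing can fire: jump to the window boundary
      } else {
        t_next = t + R::exp_rand() / a0;
      }

      if (t_next >= seg_end) {
        while (rec < nt && record_times[rec] <= seg_end) {
          out(rec, 0) = (int)nN; out(rec, 1) = (int)nV; out(rec, 2) = (int)nD;
          ++rec;
        }
        t = seg_end;
        break;
      }

      while (rec < nt && record_times[rec] < t_next) {
        out(rec, 0) = (int)nN; out(rec, 1) = (int)nV; out(rec, 2) = (int)nD;
        ++rec;
      }
      t = t_next;

      const double u = unif_rand() * a0;
      if (u < a_prod) {
        ++nN;
      } else if (u < a_prod + a_degN) {
        --nN;
      } else if (u < a_prod + a_degN + a_degV) {
        --nV;
      } else if (primed) {
        --nN; --nV; ++nD;
      } else {
        --nN; ++nD;
      }
    }
  }
  return out;
}
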
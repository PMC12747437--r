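#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stochastic descent over the corrections of one locus along one dimension.
//
// o_alpha: observed coordinates of the focal locus (NA = missing spot).
// o_beta:  N x B matrix of observed partner coordinates (usable pairs only).
// mu, sg:  goal-variance mean and uncertainty per partner (nm^2).
// prop_sd: initial proposal STD in nm; annealed by `anneal` per sweep.
//
// Traces are visited in a random order each sweep; each proposal perturbs a
// single correction and is accepted only if the summed log-density of the
// adjusted-vs-observed displacement variances improves (greedy descent; ties
// keep the incumbent). Displacement variances are updated incrementally in
// O(B) per proposal; running sums are refreshed once per sweep to keep
// floating-point drift out of the likelihood trace. Uses R's RNG stream so
// set.seed() governs reproducibility.
// [[Rcpp::export]]
List optimize_locus_cpp(NumericVector o_alpha, NumericMatrix o_beta,
                        NumericVector mu, NumericVector sg,
                        double prop_sd, int sweeps, double anneal,
                        double tol) {
  const int N = o_alpha.size();
  const int B = o_beta.ncol();
  if (mu.size() != B || sg.size() != B) stop("mu/sg length mismatch");

  std::vector< std::vector<int> > betas_of(N);
  std::vector< std::vector<int> > traces_of(B);
  std::vector<double> sum(B, 0.0), ssq(B, 0.0);
  std::vector<int> n(B, 0);
  std::vector<double> C(N, 0.0);

  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < N; ++i) {
      if (ISNAN(o_alpha[i]) || ISNAN(o_beta(i, b))) continue;
      double d = o_alpha[i] - o_beta(i, b);
      sum[b] += d; ssq[b] += d * d; n[b]++;
      betas_of[i].push_back(b);
      traces_of[b].push_back(i);
    }
  }
  double n_data = 0.0;
  for (int b = 0; b < B; ++b) {
    if (n[b] < 2) stop("partner with fewer than 2 co-localized traces");
    n_data += n[b];
  }

  const double LOG_SQRT_2PI = 0.9189385332046727;
  std::vector<double> cur_ld(B);

  auto var_of = [&](int b) {
    return (ssq[b] - sum[b] * sum[b] / n[b]) / (n[b] - 1);
  };
  auto logdens = [&](double v, int b) {
    double z = (v - mu[b]) / sg[b];
    return -0.5 * z * z - std::log(sg[b]) - LOG_SQRT_2PI;
  };
  auto refresh = [&]() {
    double ll = 0.0;
    for (int b = 0; b < B; ++b) {
      double s1 = 0.0, s2 = 0.0;
      for (size_t q = 0; q < traces_of[b].size(); ++q) {
        int i = traces_of[b][q];
        double d = o_alpha[i] + C[i] - o_beta(i, b);
        s1 += d; s2 += d * d;
      }
      sum[b] = s1; ssq[b] = s2;
      cur_ld[b] = logdens(var_of(b), b);
      ll += cur_ld[b];
    }
    return ll;
  };

  double logL = refresh();
  std::vector<double> ll_trace;
  ll_trace.reserve(sweeps + 1);
  ll_trace.push_back(logL);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  double scale = prop_sd;
  int sweeps_run = 0;
  int quiet = 0;        // consecutive sweeps below tol
  bool converged = false;
  long accepted = 0;
  std::vector<double> new_ld, dsum, dssq;

  for (int s = 0; s < sweeps; ++s) {
    for (int i = N - 1; i > 0; --i) {           // Fisher-Yates off R's RNG
      int j = (int) std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ll0 = logL;
    for (int k = 0; k < N; ++k) {
      int i = order[k];
      if (ISNAN(o_alpha[i])) continue;          // never impute missing spots
      const std::vector<int>& bs = betas_of[i];
      if (bs.empty()) continue;
      double delta = norm_rand() * scale;
      double dll = 0.0;
      size_t m = bs.size();
      new_ld.assign(m, 0.0);
      dsum.assign(m, 0.0);
      dssq.assign(m, 0.0);
      for (size_t q = 0; q < m; ++q) {
        int b = bs[q];
        double d = o_alpha[i] + C[i] - o_beta(i, b);
        double s1 = sum[b] + delta;
        double s2 = ssq[b] + 2.0 * d * delta + delta * delta;
        double v = (s2 - s1 * s1 / n[b]) / (n[b] - 1);
        double ld = logdens(v, b);
        dll += ld - cur_ld[b];
        new_ld[q] = ld; dsum[q] = s1; dssq[q] = s2;
      }
      if (dll > 0.0) {
        C[i] += delta;
        for (size_t q = 0; q < m; ++q) {
          int b = bs[q];
          sum[b] = dsum[q]; ssq[b] = dssq[q]; cur_ld[b] = new_ld[q];
        }
        logL += dll;
        ++accepted;
      }
    }
    logL = refresh();
    ll_trace.push_back(logL);
    sweeps_run = s + 1;
    scale *= anneal;
    // a single all-reject sweep is not convergence (likely early on when
    // the proposal scale is still coarse); require three quiet sweeps
    if (logL - ll0 >= 0.0 && (logL - ll0) / n_data < tol) ++quiet;
    else quiet = 0;
    if (quiet >= 3) {
      converged = true;
      break;
    }
  }

  return List::create(_["C"] = NumericVector(C.begin(), C.end()),
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["sweeps"] = sweeps_run,
                      _["accepted"] = (double) accepted,
                      _["converged"] = converged);
}

// Count, per k-tuple of loci, the traces with all members localized and the
// traces where additionally every pairwise distance is <= thresh.
// pos is the N x L x D coordinate array (column-major), tuples is T x K
// (1-based locus indices).
// [[Rcpp::export]]
IntegerMatrix multiway_counts_cpp(NumericVector pos, IntegerVector dims,
                                  IntegerMatrix tuples, double thresh) {
  const int N = dims[0], L = dims[1], D = dims[2];
  const int T = tuples.nrow(), K = tuples.ncol();
  const double t2 = thresh * thresh;
  IntegerMatrix out(T, 2);
  for (int t = 0; t < T; ++t) {
    int n_complete = 0, n_contact = 0;
    for (int i = 0; i < N; ++i) {
      bool ok = true;
      for (int k = 0; k < K; ++k) {
        int l = tuples(t, k) - 1;
        if (ISNAN(pos[i + (R_xlen_t) N * l])) { ok = false; break; }
      }
      if (!ok) continue;
      ++n_complete;
      bool contact = true;
      for (int a = 0; a < K && contact; ++a) {
        int la = tuples(t, a) - 1;
        for (int b = a + 1; b < K && contact; ++b) {
          int lb = tuples(t, b) - 1;
          double s = 0.0;
          for (int d = 0; d < D; ++d) {
            double diff = pos[i + (R_xlen_t) N * (la + (R_xlen_t) L * d)]
                        - pos[i + (R_xlen_t) N * (lb + (R_xlen_t) L * d)];
            s += diff * diff;
          }
          if (s > t2) contact = false;
        }
      }
      if (contact) ++n_contact;
    }
    out(t, 0) = n_complete;
    out(t, 1) = n_contact;
  }
  return out;
}
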
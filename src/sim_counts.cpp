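#include <Rcpp.h>
using namespace Rcpp;

// Tally present/absent responses of the optimal search observer over a block
// of trials. z holds standard-normal draws (trials x locations); measurements
// are s_D + sigma_D * z at distractor locations and s_T + sigma_T * z at the
// target location of present trials (target_col is 1-based, 0 for absent).
// The local LLR is quadratic in the measurement; pooling is an overflow-safe
// log-mean-exp; ties at the threshold count as "absent".
// [[Rcpp::export]]
IntegerVector sim_counts_cpp(NumericMatrix z, LogicalVector present,
                             IntegerVector target_col,
                             double s_t, double s_d,
                             double sig_t, double sig_d, double threshold) {
  const int n_trials = z.nrow(), n_loc = z.ncol();
  const double log_ratio = std::log(sig_d * sig_d / (sig_t * sig_t));
  const double inv2t = 0.5 / (sig_t * sig_t), inv2d = 0.5 / (sig_d * sig_d);
  const double log_n = std::log(static_cast<double>(n_loc));
  int hits = 0, misses = 0, fas = 0, crs = 0;
  std::vector<double> d(n_loc);

  for (int i = 0; i < n_trials; ++i) {
    double dmax = R_NegInf;
    for (int j = 0; j < n_loc; ++j) {
      double x;
      if (present[i] && target_col[i] == j + 1)
        x = s_t + sig_t * z(i, j);
      else
        x = s_d + sig_d * z(i, j);
      double dt = x - s_t, dd = x - s_d;
      double dij = 0.5 * log_ratio - dt * dt * inv2t + dd * dd * inv2d;
      d[j] = dij;
      if (dij > dmax) dmax = dij;
    }
    double s = 0.0;
    for (int j = 0; j < n_loc; ++j) s += std::exp(d[j] - dmax);
    double dv = dmax + std::log(s) - log_n;
    bool resp_present = dv > threshold;
    if (present[i]) { if (resp_present) ++hits; else ++misses; }
    else            { if (resp_present) ++fas;  else ++crs;    }
  }
  return IntegerVector::create(hits, misses, fas, crs);
}
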
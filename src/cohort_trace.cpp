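#include <Rcpp.h>
using namespace Rcpp;

// Propagate a cohort distribution through per-age transition matrices.
// tmats: S x S x Y array (column-major), slice y used for cycles in year y.
// Returns the (cycles+1) x S occupancy trace including the initial row.
// [[Rcpp::export]]
NumericMatrix cohort_trace_cpp(NumericVector tmats, int n_states, int n_years,
                               NumericVector init, int cycles,
                               int days_per_year) {
  const int S = n_states;
  if ((int)init.size() != S) stop("init length must equal n_states");
  if ((R_xlen_t)S * S * n_years != tmats.size())
    stop("transition array has wrong size");
  NumericMatrix out(cycles + 1, S);
  std::vector<double> v(init.begin(), init.end());
  std::vector<double> w(S);
  for (int s = 0; s < S; ++s) out(0, s) = v[s];
  for (int t = 0; t < cycles; ++t) {
    int y = t / days_per_year;
    if (y >= n_years) y = n_years - 1;
    const double* M = &tmats[(R_xlen_t)y * S * S];
    for (int j = 0; j < S; ++j) {
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += v[i] * M[i + j * S];
      if (acc < 0.0) {
        if (acc < -1e-12) stop("negative occupancy produced at cycle %d", t + 1);
        acc = 0.0;
      }
      w[j] = acc;
    }
    for (int s = 0; s < S; ++s) {
      v[s] = w[s];
      out(t + 1, s) = v[s];
    }
  }
  return out;
}
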
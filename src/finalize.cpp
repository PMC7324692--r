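#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assemble the final HU array from per-slice noiseless templates:
// adds Gaussian noise (R's RNG, so set.seed() governs it), rounds to
// integer HU and clamps to [-1024, 4000] in a single pass. The output
// vector is laid out as dim = c(n_slices, nr, nc).
// [[Rcpp::export(rng = true)]]
NumericVector finalize_volume(List templates, IntegerVector slice_map,
                              double sigma, int nr, int nc) {
  const int ns = slice_map.size();
  const R_xlen_t n = (R_xlen_t)ns * nr * nc;
  NumericVector out(no_init(n));

  std::vector<const double *> tpl(templates.size());
  for (int k = 0; k < templates.size(); ++k) {
    NumericMatrix m = templates[k];
    if (m.nrow() != nr || m.ncol() != nc) stop("template dimension mismatch");
    tpl[k] = REAL((SEXP)m);
  }
  for (int i = 0; i < ns; ++i) {
    int k = slice_map[i] - 1;
    if (k < 0 || k >= (int)tpl.size()) stop("slice_map out of range");
  }

  double *o = REAL((SEXP)out);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const R_xlen_t off = (R_xlen_t)ns * (r + (R_xlen_t)nr * c);
      const R_xlen_t t_off = r + (R_xlen_t)nr * c;
      for (int i = 0; i < ns; ++i) {
        double v = tpl[slice_map[i] - 1][t_off];
        if (sigma > 0) v += norm_rand() * sigma;
        v = std::nearbyint(v);
        if (v < -1024.0) v = -1024.0;
        else if (v > 4000.0) v = 4000.0;
        o[off + i] = v;
      }
    }
  }
  return out;
}
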
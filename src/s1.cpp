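#include <Rcpp.h>
using namespace Rcpp;

// Event-driven S1 accumulation over 32 feature maps (16 kernels x 2
// polarities). Events must be time-sorted (integer microseconds). Each event
// adds every kernel, centered at its address and clipped at the borders, to
// the map of matching (scale, orientation, polarity). Before the time
// advances past an event, all cells are decayed linearly toward zero at
// `leak` response-units per second; magnitudes never cross zero. The
// whole-stack sweep at each timestamp advance is exactly equivalent to
// per-cell lazy decay for this linear rule.
//
// Returned vector has layout [y + H*(x + W*m)], m = 0..31 with maps 0..15
// for ON events and 16..31 for OFF, kernel order within a polarity matching
// the order of `kernels`.
// [[Rcpp::export]]
NumericVector s1_accumulate_cpp(IntegerVector t, IntegerVector x,
                                IntegerVector y, IntegerVector p,
                                int width, int height, List kernels,
                                double leak) {
  const int n_kern = kernels.size();
  const int n_maps = 2 * n_kern;
  const R_xlen_t n_cells = (R_xlen_t)width * height * n_maps;
  NumericVector out(n_cells);
  std::vector<NumericMatrix> ks(n_kern);
  for (int k = 0; k < n_kern; ++k) ks[k] = as<NumericMatrix>(kernels[k]);

  const int n_ev = t.size();
  if (n_ev == 0) return out;
  double cur_t = t[0];

  for (int i = 0; i < n_ev; ++i) {
    const double ti = t[i];
    if (ti < cur_t) stop("events must be time-sorted");
    if (ti > cur_t) {
      const double dec = leak * (ti - cur_t) * 1e-6;  // us -> s
      for (R_xlen_t j = 0; j < n_cells; ++j) {
        const double v = out[j];
        if (v > 0.0)      out[j] = (v > dec) ? v - dec : 0.0;
        else if (v < 0.0) out[j] = (v < -dec) ? v + dec : 0.0;
      }
      cur_t = ti;
    }
    const int base = (p[i] == 1) ? 0 : n_kern;
    const int ex = x[i], ey = y[i];
    for (int k = 0; k < n_kern; ++k) {
      const NumericMatrix& km = ks[k];
      const int s = km.nrow();
      const int r = s / 2;
      const R_xlen_t moff = (R_xlen_t)(base + k) * width * height;
      for (int kx = 0; kx < s; ++kx) {
        const int xx = ex + kx - r;
        if (xx < 0 || xx >= width) continue;
        const R_xlen_t coff = moff + (R_xlen_t)xx * height;
        for (int ky = 0; ky < s; ++ky) {
          const int yy = ey + ky - r;
          if (yy < 0 || yy >= height) continue;
          out[coff + yy] += km(ky, kx);
        }
      }
    }
  }
  return out;
}
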
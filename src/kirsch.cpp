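#include <Rcpp.h>
using namespace Rcpp;

// Maximum response over a set of square compass kernels: per pixel, the
// linear correlation with each kernel, taking the largest. Borders use
// replicate padding. img is rows x cols (y down, x right); kernels are odd
// square matrices of equal size. The image is copied once into a padded
// buffer and each kernel is flattened to (offset, weight) taps, so the
// inner loop is a plain fused multiply-add sweep.
// [[Rcpp::export]]
NumericMatrix kirsch_max_response(IntegerMatrix img, List kernels) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nk = kernels.size();
  if (nk == 0) stop("no kernels supplied");
  NumericMatrix k0 = kernels[0];
  const int ks = k0.nrow();
  const int r = (ks - 1) / 2;
  const int pnr = nr + 2 * r, pnc = nc + 2 * r;

  // replicate-padded copy, column-major
  std::vector<double> pad(static_cast<size_t>(pnr) * pnc);
  for (int x = 0; x < pnc; ++x) {
    int xs = x - r;
    if (xs < 0) xs = 0; else if (xs >= nc) xs = nc - 1;
    double* col = &pad[static_cast<size_t>(x) * pnr];
    for (int y = 0; y < pnr; ++y) {
      int ys = y - r;
      if (ys < 0) ys = 0; else if (ys >= nr) ys = nr - 1;
      col[y] = img(ys, xs);
    }
  }

  // flatten kernels to taps relative to the padded pixel position
  std::vector<std::vector<std::pair<int, double> > > taps(nk);
  for (int k = 0; k < nk; ++k) {
    NumericMatrix km = kernels[k];
    if (km.nrow() != ks || km.ncol() != ks) stop("kernel size mismatch");
    for (int dx = -r; dx <= r; ++dx)
      for (int dy = -r; dy <= r; ++dy) {
        double w = km(dy + r, dx + r);
        if (w != 0.0) taps[k].push_back(std::make_pair(dx * pnr + dy, w));
      }
  }

  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      const double* base = &pad[static_cast<size_t>(x + r) * pnr + (y + r)];
      double best = R_NegInf;
      for (int k = 0; k < nk; ++k) {
        double acc = 0.0;
        const std::vector<std::pair<int, double> >& tk = taps[k];
        for (size_t t = 0; t < tk.size(); ++t)
          acc += tk[t].second * base[tk[t].first];
        if (acc > best) best = acc;
      }
      out(y, x) = best;
    }
  }
  return out;
}
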
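#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// NCC of a template against every valid placement in an image.
// Placement (r, c) is the 0-based top-left offset; the returned matrix
// has (nri - nrt + 1) x (nci - nct + 1) entries. Zero-variance patches
// on either side score 0 by convention.
// [[Rcpp::export]]
NumericMatrix ncc_scan_cpp(NumericMatrix img, NumericMatrix tpl) {
  int nri = img.nrow(), nci = img.ncol();
  int nrt = tpl.nrow(), nct = tpl.ncol();
  int nr = nri - nrt + 1, nc = nci - nct + 1;
  if (nr < 1 || nc < 1) stop("template larger than image");
  int npx = nrt * nct;
  double tmean = 0.0;
  for (int j = 0; j < nct; ++j)
    for (int i = 0; i < nrt; ++i) tmean += tpl(i, j);
  tmean /= npx;
  std::vector<double> tz(npx);
  double tss = 0.0;
  for (int j = 0; j < nct; ++j)
    for (int i = 0; i < nrt; ++i) {
      double z = tpl(i, j) - tmean;
      tz[i + j * nrt] = z;
      tss += z * z;
    }
  NumericMatrix out(nr, nc);
  if (tss <= 0.0) return out;  // constant template: all 0
  double tnorm = std::sqrt(tss);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0, s2 = 0.0, cross = 0.0;
      for (int j = 0; j < nct; ++j) {
        const double *col = &img(0, c + j);
        const double *tcol = &tz[j * nrt];
        for (int i = 0; i < nrt; ++i) {
          double p = col[r + i];
          s += p; s2 += p * p; cross += p * tcol[i];
        }
      }
      double pvar = s2 - s * s / npx; // sum of squared deviations
      // tz is zero-mean, so sum (p - pbar) * tz reduces to cross
      if (pvar <= 1e-300) { out(r, c) = 0.0; continue; }
      out(r, c) = cross / (std::sqrt(pvar) * tnorm);
    }
  }
  return out;
}
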
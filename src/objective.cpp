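#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hellinger-flavored SSD between the affine pushforward of a subject
// bivariate histogram and the reference, evaluated on the reference grid.
//
// subj     : subject per-bin probability mass (smoothed, normalized)
// refSqrt  : sqrt of reference per-bin probability mass (smoothed, normalized)
// centersT1/centersFlair : bin centers (uniform spacing assumed)
// par      : c(a11, a12, a21, a22, b1, b2) mapping subject -> reference,
//            offsets in intensity units
//
// The pushforward mass at a reference bin center y is the subject mass
// bilinearly interpolated at x = A^{-1}(y - b), divided by det(A)
// (Jacobian correction for the affine change of variables; bins share one
// geometry so the bin-area factor cancels). Zero outside the subject grid.
// [[Rcpp::export]]
double hn_affine_ssd(NumericMatrix subj, NumericMatrix refSqrt,
                     NumericVector centersT1, NumericVector centersFlair,
                     NumericVector par) {
  const int n1 = subj.nrow(), n2 = subj.ncol();
  const double a11 = par[0], a12 = par[1], a21 = par[2], a22 = par[3];
  const double b1 = par[4], b2 = par[5];
  const double det = a11 * a22 - a12 * a21;
  if (!(det > 1e-8)) return 1e6 + (1e-8 - det); // invertibility penalty
  const double i11 = a22 / det, i12 = -a12 / det;
  const double i21 = -a21 / det, i22 = a11 / det;
  const double lo1 = centersT1[0], w1 = centersT1[1] - centersT1[0];
  const double lo2 = centersFlair[0], w2 = centersFlair[1] - centersFlair[0];
  const double *S = &subj(0, 0);
  const double *R = &refSqrt(0, 0);
  const double *c1 = &centersT1[0];
  const double *c2 = &centersFlair[0];
  double E = 0.0;
  for (int j = 0; j < n2; ++j) {
    const double y2 = c2[j];
    const double *Rj = R + (R_xlen_t)j * n1;
    for (int i = 0; i < n1; ++i) {
      const double y1 = c1[i];
      const double x1 = i11 * (y1 - b1) + i12 * (y2 - b2);
      const double x2 = i21 * (y1 - b1) + i22 * (y2 - b2);
      const double u = (x1 - lo1) / w1;
      const double v = (x2 - lo2) / w2;
      double val = 0.0;
      if (u > -1.0 && u < (double)n1 && v > -1.0 && v < (double)n2) {
        const int u0 = (int)std::floor(u), v0 = (int)std::floor(v);
        const double fu = u - u0, fv = v - v0;
        const bool iu0 = u0 >= 0, iu1 = u0 + 1 < n1;
        const bool iv0 = v0 >= 0, iv1 = v0 + 1 < n2;
        const double s00 = (iu0 && iv0 && u0 < n1)
          ? S[(R_xlen_t)v0 * n1 + u0] : 0.0;
        const double s10 = (iu1 && iv0) ? S[(R_xlen_t)v0 * n1 + u0 + 1] : 0.0;
        const double s01 = (iu0 && iv1 && u0 < n1)
          ? S[(R_xlen_t)(v0 + 1) * n1 + u0] : 0.0;
        const double s11 = (iu1 && iv1)
          ? S[(R_xlen_t)(v0 + 1) * n1 + u0 + 1] : 0.0;
        val = (1 - fu) * (1 - fv) * s00 + fu * (1 - fv) * s10 +
              (1 - fu) * fv * s01 + fu * fv * s11;
      }
      const double t = val > 0.0 ? val / det : 0.0;
      const double d = std::sqrt(t) - Rj[i];
      E += d * d;
    }
  }
  return E;
}
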
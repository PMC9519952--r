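#include <Rcpp.h>
using namespace Rcpp;

// Speckle-reducing anisotropic diffusion (Yu & Acton 2002).
// img: non-negative image scaled to ~[0,1]; q0 decays as q0*exp(-rho*step*it).
// [[Rcpp::export]]
NumericMatrix srad_cpp(NumericMatrix img, int iterations, double step,
                       double q0, double rho) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix A = clone(img);
  NumericMatrix B(nr, nc);
  NumericMatrix C(nr, nc);
  const double eps = 1e-8;

  for (int it = 0; it < iterations; ++it) {
    double q0t = q0 * std::exp(-rho * step * it);
    if (q0t < 1e-4) q0t = 1e-4;
    const double q0t2 = q0t * q0t;

    for (int j = 0; j < nc; ++j) {
      const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
      for (int i = 0; i < nr; ++i) {
        const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
        const double Ic = A(i, j) > eps ? A(i, j) : eps;
        const double dN = A(im, j) - A(i, j), dS = A(ip, j) - A(i, j);
        const double dW = A(i, jm) - A(i, j), dE = A(i, jp) - A(i, j);
        const double g2 = (dN * dN + dS * dS + dW * dW + dE * dE) / (Ic * Ic);
        const double lap = (dN + dS + dW + dE) / Ic;
        double q2 = (0.5 * g2 - 0.0625 * lap * lap) /
                    ((1.0 + 0.25 * lap) * (1.0 + 0.25 * lap));
        if (q2 < 0.0) q2 = 0.0;
        double cij = 1.0 / (1.0 + (q2 - q0t2) / (q0t2 * (1.0 + q0t2)));
        if (cij < 0.0) cij = 0.0;
        if (cij > 1.0) cij = 1.0;
        C(i, j) = cij;
      }
    }
    for (int j = 0; j < nc; ++j) {
      const int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
      for (int i = 0; i < nr; ++i) {
        const int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
        const double Ic = A(i, j);
        const double div = C(ip, j) * (A(ip, j) - Ic) + C(i, j) * (A(im, j) - Ic) +
                           C(i, jp) * (A(i, jp) - Ic) + C(i, j) * (A(i, jm) - Ic);
        B(i, j) = Ic + (step / 4.0) * div;
      }
    }
    std::swap(A, B);
  }
  return A;
}
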
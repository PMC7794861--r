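// Per-SNP univariable logistic regression scan.
//
// For each column g of the genotype matrix, fits logit P(y=1) = a + b g by
// Newton-Raphson and returns the slope, its standard error and an iteration
// count. Columns flagged monomorphic (zero variance) are skipped upstream.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".logistic_scan_cpp")]]
NumericMatrix logistic_scan_cpp(NumericMatrix G, NumericVector y,
                                double tol, int max_iter) {
  const int n = G.nrow();
  const int J = G.ncol();
  NumericMatrix out(J, 3); // beta, se, iterations

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  const double a0 = std::log(ybar / (1.0 - ybar));

  for (int j = 0; j < J; ++j) {
    const double *g = &G(0, j);
    // moments for the warm start (linear slope / ybar(1-ybar))
    double sg = 0.0, sg2 = 0.0, sgy = 0.0;
    for (int i = 0; i < n; ++i) {
      sg += g[i];
      sg2 += g[i] * g[i];
      sgy += g[i] * y[i];
    }
    const double gbar = sg / n;
    const double sxx = sg2 - n * gbar * gbar;
    if (sxx <= 0.0) {
      out(j, 0) = NA_REAL; out(j, 1) = NA_REAL; out(j, 2) = 0;
      continue;
    }
    double b = (sgy - n * gbar * ybar) / sxx / (ybar * (1.0 - ybar));
    double a = a0 - b * gbar;

    double Haa = 0.0, Hab = 0.0, Hbb = 0.0, det = 0.0;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      double Ua = 0.0, Ub = 0.0;
      Haa = 0.0; Hab = 0.0; Hbb = 0.0;
      for (int i = 0; i < n; ++i) {
        const double eta = a + b * g[i];
        const double mu = 1.0 / (1.0 + std::exp(-eta));
        const double w = mu * (1.0 - mu);
        const double r = y[i] - mu;
        Ua += r;
        Ub += r * g[i];
        Haa += w;
        Hab += w * g[i];
        Hbb += w * g[i] * g[i];
      }
      det = Haa * Hbb - Hab * Hab;
      if (det <= 0.0 || !std::isfinite(det)) { b = NA_REAL; break; }
      double da = (Hbb * Ua - Hab * Ub) / det;
      double db = (Haa * Ub - Hab * Ua) / det;
      double step = std::max(std::fabs(da), std::fabs(db));
      if (step > 5.0) { da *= 5.0 / step; db *= 5.0 / step; }
      a += da;
      b += db;
      if (step < tol) break;
    }
    out(j, 0) = b;
    out(j, 1) = ISNAN(b) ? NA_REAL : std::sqrt(Haa / det);
    out(j, 2) = it + 1;
  }
  return out;
}
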
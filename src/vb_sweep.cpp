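#include <Rcpp.h>
using namespace Rcpp;

// One coordinate-ascent sweep of the mean-field updates against the
// summary-statistic regression likelihood with a banded LD matrix.
//
// band is (bw+1) x p with band(k, j) = r_{j, j+k} (0-based k; row 0 is the
// unit diagonal). State updated in place:
//   alpha, nu  — mixture weight and conditional slab mean per SNP
//   u          — alpha_j * nu_j / s_j
//   r          — R %*% u, maintained incrementally so the residual term
//                sum_{i != j} r_ij alpha_i nu_i / s_i equals r[j] - u[j]
// order gives the 0-based visiting order. Returns the largest absolute
// change in alpha and in alpha*nu over the sweep.
// [[Rcpp::export]]
List vb_sweep_cpp(NumericVector betahat, NumericVector se,
                  NumericMatrix band, NumericVector pi_j,
                  NumericVector sigma2_j,
                  NumericVector alpha, NumericVector nu,
                  NumericVector u, NumericVector r,
                  IntegerVector order) {
  const int p = betahat.size();
  const int bw = band.nrow() - 1;
  double max_dalpha = 0.0, max_dmu = 0.0;

  for (int k = 0; k < p; ++k) {
    const int j = order[k];
    const double s2 = se[j] * se[j];
    const double sj2 = sigma2_j[j];
    const double a_old = alpha[j];
    const double anu_old = alpha[j] * nu[j];

    if (sj2 <= 0.0) {
      // degenerate slab: the prior is a point mass at zero
      alpha[j] = 0.0;
      nu[j] = 0.0;
    } else {
      const double tau2 = s2 * sj2 / (s2 + sj2);
      const double val = betahat[j] / s2 - (r[j] - u[j]) / se[j];
      const double nuj = tau2 * val;
      const double pj = pi_j[j];
      double lo = log(pj) - log1p(-pj)
        + 0.5 * (log(tau2) - log(sj2))
        + nuj * nuj / (2.0 * tau2);
      if (lo > 700.0) lo = 700.0;
      if (lo < -700.0) lo = -700.0;
      alpha[j] = 1.0 / (1.0 + exp(-lo));
      nu[j] = nuj;
    }

    const double unew = alpha[j] * nu[j] / se[j];
    const double delta = unew - u[j];
    if (delta != 0.0) {
      u[j] = unew;
      r[j] += delta;
      int lo_i = j - bw; if (lo_i < 0) lo_i = 0;
      int hi_i = j + bw; if (hi_i > p - 1) hi_i = p - 1;
      for (int i = lo_i; i < j; ++i) {
        const double rij = band(j - i, i);
        if (rij != 0.0) r[i] += rij * delta;
      }
      for (int i = j + 1; i <= hi_i; ++i) {
        const double rij = band(i - j, j);
        if (rij != 0.0) r[i] += rij * delta;
      }
    }

    const double da = fabs(alpha[j] - a_old);
    const double dm = fabs(alpha[j] * nu[j] - anu_old);
    if (da > max_dalpha) max_dalpha = da;
    if (dm > max_dmu) max_dmu = dm;
  }

  return List::create(_["max_dalpha"] = max_dalpha, _["max_dmu"] = max_dmu);
}
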
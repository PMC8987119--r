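#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihood of the three-state robust-design CJS
// model, vectorized over individuals.  States: available (A), temporarily
// unavailable (U), dead/permanently emigrated (D).  Conditioning on first
// capture: the individual is available with probability one in its release
// primary; within that primary only occasions after the first detection
// contribute Bernoulli terms.
//
// Year indices are 1-based global primary indices.  Occasions are stored in
// one global order (site, year, secondary); u holds the occasion-level
// logit-p offset (delta'W + omega_{s,t}) in that order.  Each individual's
// detections are stored flat over its own site's occasions.
//
// phi(i, t-1): survival over the interval t -> t+1.
// gamma(i, t-1): availability in primary t.
// cmat(i, t-1): individual-level logit-p offset in primary t.
// det_any(i, t-1): 1 if the individual was detected in primary t (for the
//   release primary: detected again after the initial capture).
//
// [[Rcpp::export]]
NumericVector cmr_forward_cpp(IntegerVector first, IntegerVector last,
                              IntegerVector site,
                              NumericMatrix phi, NumericMatrix gamma,
                              NumericMatrix cmat, NumericVector u,
                              IntegerMatrix occ_off, IntegerMatrix occ_len,
                              IntegerVector site_base,
                              IntegerVector y, IntegerVector y_off,
                              IntegerVector first_j,
                              IntegerMatrix det_any) {
  const int n = first.size();
  NumericVector ll(n);

  for (int i = 0; i < n; ++i) {
    const int s = site[i] - 1;
    const int t0 = first[i];
    const int tn = last[i];

    // log emission for the available state in primary t, occasions jstart..
    // (jstart is 0-based within the site-year block)
    auto emisA = [&](int t, int jstart) -> double {
      const int og = occ_off(s, t - 1);
      if (og < 0) return 0.0;
      const int len = occ_len(s, t - 1);
      const int lb = og - site_base[s] + y_off[i];
      double e = 0.0;
      const double c = cmat(i, t - 1);
      for (int j = jstart; j < len; ++j) {
        const double lp = c + u[og + j];
        const double p = 1.0 / (1.0 + std::exp(-lp));
        e += y[lb + j] ? std::log(p) : std::log1p(-p);
      }
      return e;
    };

    double A = std::exp(emisA(t0, first_j[i] + 1));
    double U = 0.0, D = 0.0;

    for (int t = t0 + 1; t <= tn; ++t) {
      const double ps = phi(i, t - 2);   // survival over (t-1) -> t
      const double g = gamma(i, t - 1);  // availability in t
      const double AU = A + U;
      double A2 = AU * ps * g;
      double U2 = AU * ps * (1.0 - g);
      double D2 = D + AU * (1.0 - ps);
      A2 *= std::exp(emisA(t, 0));
      if (det_any(i, t - 1)) {
        A = A2; U = 0.0; D = 0.0;
      } else {
        A = A2; U = U2; D = D2;
      }
    }
    const double tot = A + U + D;
    ll[i] = tot > 0 ? std::log(tot) : R_NegInf;
  }
  return ll;
}
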
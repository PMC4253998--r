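#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs BayesB.
//
// Model: y = X b + Z a + e
//   b        flat prior (X must be full column rank)
//   a_j = 0 with prior probability pi; else a_j | s2_j ~ N(0, s2_j)
//   s2_j ~ scaled-inverse-chi-square(df_alpha, scale_alpha)
//   e ~ N(0, s2e I), s2e ~ scaled-inverse-chi-square(df_e, scale_e)
//
// The inclusion indicator is sampled with the effect integrated out given the
// current locus variance; the effect from its normal conditional; the locus
// variance from its scaled-inverse-chi-square conditional when the marker is
// in the model and from the prior when it is not. The residual vector, the
// genomic-value vector g = Z a and the per-window genomic values are all
// maintained incrementally so each marker update is O(n).
//
// Uses R's RNG throughout: results are reproducible under set.seed().

static inline double rscinvchisq(double df, double scale) {
  // scaled-inverse-chi-square draw: df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

static double colvar(const std::vector<double>& v) {
  const int n = v.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += v[i];
  m /= n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (v[i] - m) * (v[i] - m);
  return ss / (n - 1);
}

// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(NumericVector y,
                 NumericMatrix X,
                 NumericMatrix Z,
                 IntegerVector window,   // 0-based window index per marker
                 int n_windows,
                 double pi,
                 int n_iter,
                 int burn_in,
                 int thin,
                 double df_alpha,
                 double scale_alpha,
                 double df_e,
                 double scale_e,
                 Nullable<double> fixed_sigma2_alpha,
                 Nullable<double> fixed_sigma2_e,
                 bool store_effects) {
  const int n = y.size();
  const int p = X.ncol();
  const int M = Z.ncol();
  const bool fix_sa = fixed_sigma2_alpha.isNotNull();
  const bool fix_se = fixed_sigma2_e.isNotNull();
  const double sa_fix = fix_sa ? as<double>(fixed_sigma2_alpha) : 0.0;

  // precomputed cross-products
  std::vector<double> xtx(p), ztz(M);
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xtx[k] = s;
  }
  for (int j = 0; j < M; ++j) {
    const double* zj = &Z(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    ztz[j] = s;
  }

  // state
  std::vector<double> b(p, 0.0), a(M, 0.0), s2loc(M);
  std::vector<int> delta(M, 0);
  double ybar = mean(y);
  b[0] = ybar; // column 0 is the intercept by construction
  double s2e = fix_se ? as<double>(fixed_sigma2_e) : std::max(1e-10, var(y) / 2.0);
  double prior_mean_sa = fix_sa ? sa_fix
    : (df_alpha > 2.0 ? df_alpha * scale_alpha / (df_alpha - 2.0) : scale_alpha);
  for (int j = 0; j < M; ++j) s2loc[j] = fix_sa ? sa_fix : prior_mean_sa;

  std::vector<double> r(n), g(n, 0.0);
  for (int i = 0; i < n; ++i) r[i] = y[i] - ybar;
  // per-window genomic values (n x W)
  std::vector< std::vector<double> > gw(n_windows, std::vector<double>(n, 0.0));

  const int n_saved = (n_iter - burn_in + thin - 1) / thin;
  NumericVector va_s(n_saved), ve_s(n_saved), h2_s(n_saved), nincl_s(n_saved);
  NumericVector eff_sum(M), incl_sum(M), fix_sum(p), win_sum(n_windows);
  NumericMatrix eff_store;
  if (store_effects) eff_store = NumericMatrix(n_saved, M);

  const double log_prior_odds = (pi > 0.0) ? std::log((1.0 - pi) / pi) : 0.0;
  int save_idx = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, flat prior ---
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, k) * r[i];
      rhs += xtx[k] * b[k];
      double mean_k = rhs / xtx[k];
      double bnew = R::rnorm(mean_k, std::sqrt(s2e / xtx[k]));
      double d = bnew - b[k];
      if (d != 0.0) for (int i = 0; i < n; ++i) r[i] -= X(i, k) * d;
      b[k] = bnew;
    }

    // --- marker effects ---
    int nincl = 0;
    for (int j = 0; j < M; ++j) {
      if (ztz[j] <= 0.0) { a[j] = 0.0; delta[j] = 0; continue; }
      const double* zj = &Z(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += zj[i] * r[i];
      rhs += ztz[j] * a[j]; // r still contains -z_j a_j
      double s2j = fix_sa ? sa_fix : s2loc[j];

      bool include;
      if (pi <= 0.0) {
        include = true;
      } else if (pi >= 1.0) {
        include = false;
      } else {
        double c = ztz[j] * s2j + s2e;
        double logbf = 0.5 * (std::log(s2e / c) + rhs * rhs * s2j / (s2e * c));
        double lo = log_prior_odds + logbf;
        double p1 = 1.0 / (1.0 + std::exp(-lo));
        include = (R::unif_rand() < p1);
      }

      double anew = 0.0;
      if (include) {
        double lhs = ztz[j] + s2e / s2j;
        anew = R::rnorm(rhs / lhs, std::sqrt(s2e / lhs));
        delta[j] = 1;
        ++nincl;
      } else {
        delta[j] = 0;
      }
      double d = anew - a[j];
      if (d != 0.0) {
        const int w = window[j];
        std::vector<double>& gww = gw[w];
        for (int i = 0; i < n; ++i) {
          double zd = zj[i] * d;
          r[i] -= zd;
          g[i] += zd;
          gww[i] += zd;
        }
      }
      a[j] = anew;

      if (!fix_sa) {
        if (delta[j])
          s2loc[j] = rscinvchisq(df_alpha + 1.0,
                                 (df_alpha * scale_alpha + a[j] * a[j]) / (df_alpha + 1.0));
        else
          s2loc[j] = rscinvchisq(df_alpha, scale_alpha);
      }
    }

    // --- residual variance ---
    if (!fix_se) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      s2e = rscinvchisq(df_e + n, (df_e * scale_e + sse) / (df_e + n));
    }

    // --- save ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      double va = colvar(g);
      va_s[save_idx] = va;
      ve_s[save_idx] = s2e;
      h2_s[save_idx] = (va + s2e > 0.0) ? va / (va + s2e) : 0.0;
      nincl_s[save_idx] = nincl;
      for (int w = 0; w < n_windows; ++w) {
        double share = 0.0;
        if (va > 0.0) share = 100.0 * colvar(gw[w]) / va;
        win_sum[w] += share;
      }
      for (int j = 0; j < M; ++j) {
        eff_sum[j] += a[j];
        incl_sum[j] += delta[j];
        if (store_effects) eff_store(save_idx, j) = a[j];
      }
      for (int k = 0; k < p; ++k) fix_sum[k] += b[k];
      ++save_idx;
    }
  }

  List out = List::create(
    _["effect_mean"] = eff_sum / double(n_saved),
    _["sppi"] = incl_sum / double(n_saved),
    _["fixed_mean"] = fix_sum / double(n_saved),
    _["window_share_mean"] = win_sum / double(n_saved),
    _["va_samples"] = va_s,
    _["ve_samples"] = ve_s,
    _["h2_samples"] = h2_s,
    _["n_included"] = nincl_s,
    _["n_saved"] = n_saved);
  if (store_effects) out["effect_samples"] = eff_store;
  return out;
}
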
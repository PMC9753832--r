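// Single-site Gibbs sampler for the four-distribution normal-mixture
// SNP-effect model. Effects within genetic component c follow
//   a_j ~ pi_c1 N(0, s4_c/1000) + pi_c2 N(0, s4_c/100)
//       + pi_c3 N(0, s4_c/10)   + pi_c4 N(0, s4_c),
// with pi_c ~ Dirichlet(alpha) and s4_c, sigma_e^2 scaled inverse-chi^2.
// Uses R's RNG throughout so chains are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  // scaled inverse-chi^2(df, scale) = df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_mix_cpp")]]
List gibbs_mix_cpp(NumericVector y, NumericMatrix X, NumericMatrix Z,
                   IntegerVector comp, NumericVector ratios,
                   NumericVector alpha, NumericMatrix pi_init,
                   NumericVector s4_init, double sigma_e_init,
                   NumericVector s4_prior_scale, double s4_prior_df,
                   double se_prior_scale, double se_prior_df,
                   int chain_length, int burn_in, int thin,
                   bool update_pi, bool update_sigma4, bool update_sigma_e) {
  const int n = y.size(), p = X.ncol(), m = Z.ncol();
  const int ncomp = pi_init.nrow(), K = ratios.size();

  std::vector<double> xx(p), zz(m);
  for (int f = 0; f < p; ++f) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, f) * X(i, f);
    xx[f] = s;
  }
  for (int j = 0; j < m; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zz[j] = s;
  }

  std::vector<double> b(p, 0.0), a(m, 0.0), r(y.begin(), y.end());
  std::vector<int> cls(m, 0);
  NumericMatrix pi(clone(pi_init));
  std::vector<double> s4(s4_init.begin(), s4_init.end());
  double se2 = sigma_e_init;

  // accumulators (post burn-in)
  std::vector<double> a_sum(m, 0.0), b_sum(p, 0.0);
  NumericMatrix cls_sum(m, K), pi_sum(ncomp, K);
  std::vector<double> s4_sum(ncomp, 0.0);
  double se_sum = 0.0;
  int n_kept = 0;
  int n_trace = (chain_length + thin - 1) / thin;
  NumericMatrix trace(n_trace, 1 + ncomp);
  int t_row = 0;

  std::vector<double> logl(K), cum(K);

  for (int it = 0; it < chain_length; ++it) {
    // fixed effects, flat prior
    for (int f = 0; f < p; ++f) {
      double rhs = 0; for (int i = 0; i < n; ++i) rhs += X(i, f) * r[i];
      rhs += xx[f] * b[f];
      double bn = rhs / xx[f] + std::sqrt(se2 / xx[f]) * R::norm_rand();
      double diff = b[f] - bn;
      for (int i = 0; i < n; ++i) r[i] += X(i, f) * diff;
      b[f] = bn;
    }
    // SNP effects: class indicator then effect
    std::vector<int> counts(ncomp * K, 0);
    for (int j = 0; j < m; ++j) {
      const int c = comp[j];
      if (zz[j] < 1e-12) { // monomorphic column: effect stays 0
        double u = R::unif_rand(), acc = 0; int k = K - 1;
        for (int kk = 0; kk < K; ++kk) { acc += pi(c, kk); if (u <= acc) { k = kk; break; } }
        cls[j] = k; counts[c * K + k]++;
        continue;
      }
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * r[i];
      rhs += zz[j] * a[j];
      double maxl = -1e300;
      for (int k = 0; k < K; ++k) {
        double v = ratios[k] * s4[c];
        double C = zz[j] + se2 / v;
        logl[k] = std::log(pi(c, k)) - 0.5 * std::log(v * zz[j] / se2 + 1.0)
                  + 0.5 * rhs * rhs / (se2 * C);
        if (logl[k] > maxl) maxl = logl[k];
      }
      double tot = 0;
      for (int k = 0; k < K; ++k) { cum[k] = std::exp(logl[k] - maxl); tot += cum[k]; }
      double u = R::unif_rand() * tot, acc = 0; int k = K - 1;
      for (int kk = 0; kk < K; ++kk) { acc += cum[kk]; if (u <= acc) { k = kk; break; } }
      cls[j] = k; counts[c * K + k]++;
      double v = ratios[k] * s4[c];
      double C = zz[j] + se2 / v;
      double an = rhs / C + std::sqrt(se2 / C) * R::norm_rand();
      double diff = a[j] - an;
      for (int i = 0; i < n; ++i) r[i] += Z(i, j) * diff;
      a[j] = an;
    }
    // mixture proportions: Dirichlet(alpha + counts)
    if (update_pi) {
      for (int c = 0; c < ncomp; ++c) {
        double tot = 0; std::vector<double> g(K);
        for (int k = 0; k < K; ++k) {
          g[k] = R::rgamma(alpha[k] + counts[c * K + k], 1.0);
          tot += g[k];
        }
        for (int k = 0; k < K; ++k) pi(c, k) = g[k] / tot;
      }
    }
    // largest-class variance per component, pooling classes via fixed ratios
    if (update_sigma4) {
      std::vector<double> ssq(ncomp, 0.0);
      std::vector<int> mc(ncomp, 0);
      for (int j = 0; j < m; ++j) {
        ssq[comp[j]] += a[j] * a[j] / ratios[cls[j]];
        mc[comp[j]]++;
      }
      for (int c = 0; c < ncomp; ++c) {
        double df = s4_prior_df + mc[c];
        double sc = (s4_prior_df * s4_prior_scale[c] + ssq[c]) / df;
        s4[c] = rinvchisq(df, sc);
      }
    }
    // residual variance
    if (update_sigma_e) {
      double rr = 0; for (int i = 0; i < n; ++i) rr += r[i] * r[i];
      double df = se_prior_df + n;
      se2 = rinvchisq(df, (se_prior_df * se_prior_scale + rr) / df);
    }
    if (se2 < 1e-12 || se2 > 1e12 || !R_finite(se2)) {
      stop("Gibbs chain diverged: residual variance left (1e-12, 1e12) at iteration %d", it + 1);
    }
    if (it % thin == 0) {
      trace(t_row, 0) = se2;
      for (int c = 0; c < ncomp; ++c) trace(t_row, 1 + c) = s4[c];
      ++t_row;
    }
    if (it >= burn_in) {
      ++n_kept;
      for (int j = 0; j < m; ++j) { a_sum[j] += a[j]; cls_sum(j, cls[j]) += 1.0; }
      for (int f = 0; f < p; ++f) b_sum[f] += b[f];
      for (int c = 0; c < ncomp; ++c) {
        s4_sum[c] += s4[c];
        for (int k = 0; k < K; ++k) pi_sum(c, k) += pi(c, k);
      }
      se_sum += se2;
    }
  }

  NumericVector effect_mean(m), fixed_mean(p), s4_mean(ncomp);
  for (int j = 0; j < m; ++j) effect_mean[j] = a_sum[j] / n_kept;
  for (int f = 0; f < p; ++f) fixed_mean[f] = b_sum[f] / n_kept;
  for (int c = 0; c < ncomp; ++c) s4_mean[c] = s4_sum[c] / n_kept;
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) cls_sum(j, k) /= n_kept;
  for (int c = 0; c < ncomp; ++c)
    for (int k = 0; k < K; ++k) pi_sum(c, k) /= n_kept;

  return List::create(
    _["effect_mean"] = effect_mean, _["fixed_mean"] = fixed_mean,
    _["pi_mean"] = pi_sum, _["sigma4_mean"] = s4_mean,
    _["sigma_e_mean"] = se_sum / n_kept, _["class_prob"] = cls_sum,
    _["trace"] = trace, _["n_kept"] = n_kept);
}
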
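#include <Rcpp.h>
using namespace Rcpp;

// Draw from a scaled inverse chi-square distribution: df * S / chisq(df).
static inline double rinvchisq(double df, double S) {
  return df * S / R::rchisq(df);
}

// Single-site Gibbs sampler for Bayesian whole-genome regression.
//
// Model: y = W a + X b + e,  e ~ N(0, varE I).
// Fixed effects `a` (columns of W) carry a flat prior.
// Marker effects `b` are grouped (column j belongs to group[j]); each group
// has its own effect-variance parameter. Two priors are supported:
//   BRR    : b_j ~ N(0, varB[g])            (group-common variance)
//   BayesB : b_j = d_j * u_j with P(d_j = 0) = pi, u_j ~ N(0, varL_j),
//            varL_j ~ scaled-inv-chisq(df_b, S_b[g])  (per-locus variance,
//            marginally a scaled-t slab), pi ~ Beta(pi_a, pi_b) optionally
//            updated from the inclusion counts.
// Variance components get scaled-inverse-chi-square updates.
//
// Uses R's RNG (RNGScope via Rcpp attributes) so set.seed() in R makes the
// chain reproducible. Single-threaded by construction.
// [[Rcpp::export(name = ".gibbs_wgr_cpp")]]
List gibbs_wgr_cpp(const NumericVector y,
                   const NumericMatrix W,
                   const NumericMatrix X,
                   const IntegerVector group,
                   const int n_groups,
                   const std::string model,
                   const int n_iter,
                   const int burn_in,
                   const int thin,
                   const double df_b,
                   const NumericVector S_b,
                   const double df_e,
                   const double S_e,
                   const NumericVector varB0,
                   const double varE0,
                   const double pi0,
                   const double pi_a,
                   const double pi_b,
                   const bool update_varB,
                   const bool update_varE,
                   const bool update_pi) {
  const int n = y.size();
  const int p = X.ncol();
  const int k = W.ncol();
  const bool bayesb = (model == "BayesB");
  const double varE_floor = 1e-12;

  // sufficient statistics for columns
  std::vector<double> x2(p), w2(k);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    w2[j] = s;
  }
  std::vector<int> gsize(n_groups, 0);
  for (int j = 0; j < p; ++j) gsize[group[j] - 1]++;

  // state
  std::vector<double> b(p, 0.0), a(k, 0.0), varL(p);
  std::vector<int> d(p, 1);
  std::vector<double> varB(n_groups);
  for (int g = 0; g < n_groups; ++g) varB[g] = varB0[g];
  for (int j = 0; j < p; ++j) varL[j] = varB0[group[j] - 1];
  double varE = std::max(varE0, varE_floor);
  double pi = pi0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  // accumulators
  const int n_samples = (n_iter - burn_in + thin - 1) / thin;
  std::vector<double> b_sum(p, 0.0), b_sumsq(p, 0.0), a_sum(k, 0.0),
      d_sum(p, 0.0);
  NumericVector varE_chain(n_samples), pi_chain(n_samples),
      mu_chain(n_samples);
  NumericMatrix varB_chain(n_samples, n_groups);
  NumericMatrix a_chain(n_samples, k);
  int s_idx = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- fixed effects (flat prior) ---
    for (int j = 0; j < k; ++j) {
      if (w2[j] <= 0.0) continue;
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += W(i, j) * e[i];
      r += w2[j] * a[j];
      double mean = r / w2[j];
      double sd = std::sqrt(varE / w2[j]);
      double anew = R::rnorm(mean, sd);
      double diff = anew - a[j];
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= W(i, j) * diff;
      a[j] = anew;
    }

    // --- marker effects ---
    if (!bayesb) {
      for (int j = 0; j < p; ++j) {
        if (x2[j] <= 0.0) { b[j] = 0.0; continue; }
        double vb = varB[group[j] - 1];
        double r = 0.0;
        for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
        r += x2[j] * b[j];
        double prec = x2[j] / varE + 1.0 / vb;
        double mean = (r / varE) / prec;
        double bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        double diff = bnew - b[j];
        if (diff != 0.0)
          for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
        b[j] = bnew;
      }
      if (update_varB) {
        for (int g = 0; g < n_groups; ++g) {
          double ss = 0.0;
          for (int j = 0; j < p; ++j)
            if (group[j] - 1 == g) ss += b[j] * b[j];
          varB[g] = rinvchisq(df_b + gsize[g],
                              (ss + df_b * S_b[g]) / (df_b + gsize[g]));
        }
      }
    } else {
      for (int j = 0; j < p; ++j) {
        if (x2[j] <= 0.0) { b[j] = 0.0; d[j] = 0; continue; }
        // residual correlation with the locus, excluding its own effect
        double r = 0.0;
        for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
        r += x2[j] * b[j];
        // inclusion indicator, slab effect integrated out given varL_j
        double v0 = x2[j] * varE;
        double v1 = v0 + x2[j] * x2[j] * varL[j];
        double logodds = std::log((1.0 - pi) / std::max(pi, 1e-300)) +
                         0.5 * (std::log(v0) - std::log(v1)) +
                         0.5 * r * r * (1.0 / v0 - 1.0 / v1);
        double pin = 1.0 / (1.0 + std::exp(-logodds));
        int dnew = (R::unif_rand() < pin) ? 1 : 0;
        double bnew = 0.0;
        if (dnew == 1) {
          double prec = x2[j] / varE + 1.0 / varL[j];
          double mean = (r / varE) / prec;
          bnew = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
        double diff = bnew - b[j];
        if (diff != 0.0)
          for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
        b[j] = bnew;
        d[j] = dnew;
      }
      if (update_varB) {
        for (int j = 0; j < p; ++j) {
          double Sg = S_b[group[j] - 1];
          if (d[j] == 1)
            varL[j] = rinvchisq(df_b + 1.0,
                                (b[j] * b[j] + df_b * Sg) / (df_b + 1.0));
          else
            varL[j] = rinvchisq(df_b, Sg);
        }
        // group-level summary kept for diagnostics
        for (int g = 0; g < n_groups; ++g) {
          double s = 0.0;
          int cnt = 0;
          for (int j = 0; j < p; ++j)
            if (group[j] - 1 == g) { s += varL[j]; cnt++; }
          varB[g] = cnt > 0 ? s / cnt : 0.0;
        }
      }
      if (update_pi) {
        int n_in = 0;
        for (int j = 0; j < p; ++j) n_in += d[j];
        pi = R::rbeta(pi_a + (p - n_in), pi_b + n_in);
      }
    }

    // --- residual variance ---
    if (update_varE) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      varE = rinvchisq(df_e + n, (sse + df_e * S_e) / (df_e + n));
      if (varE < varE_floor) varE = varE_floor;
    }

    // --- store ---
    if (iter >= burn_in && ((iter - burn_in) % thin == 0)) {
      for (int j = 0; j < p; ++j) {
        b_sum[j] += b[j];
        b_sumsq[j] += b[j] * b[j];
        d_sum[j] += d[j];
      }
      for (int j = 0; j < k; ++j) {
        a_sum[j] += a[j];
        a_chain(s_idx, j) = a[j];
      }
      varE_chain[s_idx] = varE;
      pi_chain[s_idx] = pi;
      for (int g = 0; g < n_groups; ++g) varB_chain(s_idx, g) = varB[g];
      mu_chain[s_idx] = k > 0 ? a[0] : 0.0;
      s_idx++;
    }
  }

  NumericVector bhat(p), bsd(p), pip(p), ahat(k);
  for (int j = 0; j < p; ++j) {
    double m = b_sum[j] / n_samples;
    bhat[j] = m;
    double v = b_sumsq[j] / n_samples - m * m;
    bsd[j] = v > 0 ? std::sqrt(v) : 0.0;
    pip[j] = d_sum[j] / n_samples;
  }
  for (int j = 0; j < k; ++j) ahat[j] = a_sum[j] / n_samples;

  return List::create(
      _["b"] = bhat, _["b_sd"] = bsd, _["a"] = ahat, _["pip"] = pip,
      _["varE_chain"] = varE_chain, _["varB_chain"] = varB_chain,
      _["pi_chain"] = pi_chain, _["mu_chain"] = mu_chain,
      _["a_chain"] = a_chain, _["n_samples"] = n_samples);
}
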
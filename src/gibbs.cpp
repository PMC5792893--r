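#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inverse-gamma(shape, scale) draw through R's RNG so that set.seed() in R
// gives bit-identical chains.
static inline double rinvgamma(double shape, double scale) {
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

static inline arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

// ---------------------------------------------------------------------------
// Collapsed sampler for the single-random-component linear mixed model
//   y = X b + Z u + e,  u ~ N(0, G va),  e ~ N(0, I ve),  flat prior on b,
// after a one-off spectral reduction done in R:
//   Phi' (W'W) Phi = diag(lambda),  Phi' blockdiag(0, G^-1) Phi = diag(1-lambda),
// with theta = (b, u) = Phi eta.  Integrating eta analytically gives the
// exact marginal posterior of (va, ve):
//   log p(va, ve | y) = -n/2 log ve - q/2 log va - y'y/(2 ve)
//                       - 1/2 sum_j log d_j + 1/2 sum_j (c_j/ve)^2 / d_j
//                       + log IG priors,       d_j = lambda_j/ve + (1-lambda_j)/va.
// The variances are updated on the log scale by coordinate slice sampling on
// this marginal (so their mixing does not depend on the sampled location
// effects), and the location effects are then drawn exactly from their
// diagonal Gaussian conditional.  Repeated eigenvalues are grouped, so one
// marginal evaluation costs O(#distinct eigenvalues).
// ---------------------------------------------------------------------------

struct MarginalPost {
  const arma::vec& lam_u;  // distinct pencil eigenvalues
  const arma::vec& cnt;    // their multiplicities
  const arma::vec& sc;     // sum of c_j^2 within each group
  double yty;
  int n, q, m;
  double a_e, b_e, a_a, b_a;
  bool has_ranef;

  // log posterior at (log va, log ve), including Jacobians
  double operator()(double lva, double lve) const {
    const double va = std::exp(lva), ve = std::exp(lve);
    double slog = 0.0, squad = 0.0;
    for (arma::uword g = 0; g < lam_u.n_elem; ++g) {
      // d = num / (va * ve) with num = lam*va + (1-lam)*ve
      const double num = lam_u[g] * va + (1.0 - lam_u[g]) * ve;
      slog += cnt[g] * std::log(num);
      // (c/ve)^2 / d = c^2 * va / (ve * num)
      squad += sc[g] * va / (ve * num);
    }
    slog -= m * (lva + lve);
    double lp = -0.5 * n * lve - 0.5 * yty / ve - 0.5 * slog + 0.5 * squad;
    lp += -(a_e + 1.0) * lve - b_e / ve + lve;             // IG prior + Jacobian
    if (has_ranef) {
      lp += -0.5 * q * lva - (a_a + 1.0) * lva - b_a / va + lva;
    }
    return lp;
  }
};

// Neal (2003) slice sampler with stepping out and shrinkage, on one
// coordinate of the marginal posterior.
template <class F>
static double slice_update(const F& logf, double x0, double w, int max_steps) {
  const double logy = logf(x0) + std::log(unif_rand());
  double L = x0 - w * unif_rand();
  double R = L + w;
  int j = (int)std::floor(max_steps * unif_rand());
  int k = max_steps - 1 - j;
  while (j-- > 0 && logf(L) > logy) L -= w;
  while (k-- > 0 && logf(R) > logy) R += w;
  for (int it = 0; it < 200; ++it) {
    const double x1 = L + (R - L) * unif_rand();
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List gibbs_spectral_cpp(const arma::vec& lambda, const arma::vec& cvec,
                        const arma::vec& lam_u, const arma::vec& cnt,
                        const arma::vec& sc,
                        double yty, int n_obs, int q_ranef,
                        const arma::mat& phi_fixed,
                        double shape_e0, double scale_e0,
                        double shape_a0, double scale_a0,
                        int n_iter, int burn_in, int thin,
                        double init_ve, double init_va) {
  const int m = lambda.n_elem;
  const int p = phi_fixed.n_rows;
  const bool has_ranef = q_ranef > 0;
  const arma::vec lam  = arma::clamp(lambda, 0.0, arma::datum::inf);
  const arma::vec lam1 = arma::clamp(1.0 - lambda, 0.0, arma::datum::inf);

  const int n_store = (n_iter - burn_in) / thin;
  const int ncol = p + (has_ranef ? 1 : 0) + 1;
  arma::mat out(n_store, ncol);
  arma::vec eta_sum(m, arma::fill::zeros);
  arma::vec eta(m);

  MarginalPost post{lam_u, cnt, sc, yty, n_obs, q_ranef, m,
                    shape_e0, scale_e0, shape_a0, scale_a0, has_ranef};

  // with no random effect the residual marginal is conjugate:
  // ve | y ~ IG(a_e + (n-p)/2, b_e + RSS/2) with RSS = y'y - sum c^2/lambda
  double rss0 = yty;
  if (!has_ranef) {
    for (int j = 0; j < m; ++j) rss0 -= cvec[j] * cvec[j] / lam[j];
    if (rss0 < 0.0) rss0 = 0.0;
  }

  double lva = std::log(init_va), lve = std::log(init_ve);
  int isave = 0;
  for (int it = 1; it <= n_iter; ++it) {
    if (has_ranef) {
      lva = slice_update([&](double x) { return post(x, lve); }, lva, 1.0, 30);
      lve = slice_update([&](double x) { return post(lva, x); }, lve, 1.0, 30);
    } else {
      lve = std::log(rinvgamma(shape_e0 + 0.5 * (n_obs - p), scale_e0 + 0.5 * rss0));
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && isave < n_store) {
      const double va = std::exp(lva), ve = std::exp(lve);
      const double se = 1.0 / ve;
      const double sa = has_ranef ? 1.0 / va : 0.0;
      for (int j = 0; j < m; ++j) {
        const double dj = se * lam[j] + sa * lam1[j];
        eta[j] = (se * cvec[j] + std::sqrt(dj) * norm_rand()) / dj;
      }
      arma::vec b = phi_fixed * eta;
      for (int j = 0; j < p; ++j) out(isave, j) = b[j];
      int k = p;
      if (has_ranef) out(isave, k++) = va;
      out(isave, k) = ve;
      eta_sum += eta;
      ++isave;
    }
  }
  arma::vec eta_mean = eta_sum;
  if (n_store > 0) eta_mean /= n_store;
  return List::create(_["samples"] = out, _["eta_mean"] = eta_mean);
}

// General Gibbs sampler for K >= 1 independent random-effect components:
//   y = X b + sum_k Z_k u_k + e,  u_k ~ N(0, G_k v_k),  e ~ N(0, I ve),
// flat prior on b.  One joint Gaussian draw of theta = (b, u_1, ..., u_K)
// per iteration via a dense Cholesky of the location precision matrix.
//
// M1 = W'W with W = [X Z_1 ... Z_K]; offsets/sizes locate each u_k in theta
// (0-based); ginv_list holds each G_k^{-1} as a dense matrix.
// [[Rcpp::export]]
List gibbs_general_cpp(const arma::vec& y, const arma::mat& W, const arma::mat& M1,
                       const arma::vec& Wty, const List& ginv_list,
                       const arma::ivec& offsets, const arma::ivec& sizes,
                       const arma::vec& shape0, const arma::vec& scale0,
                       double shape_e0, double scale_e0,
                       int n_iter, int burn_in, int thin,
                       const arma::vec& init_v, double init_ve, int p) {
  const int m = W.n_cols;
  const int n = W.n_rows;
  const int K = ginv_list.size();
  std::vector<arma::mat> G(K);
  for (int k = 0; k < K; ++k) G[k] = as<arma::mat>(ginv_list[k]);

  const int n_store = (n_iter - burn_in) / thin;
  arma::mat out(n_store, p + K + 1);
  arma::vec theta_sum(m, arma::fill::zeros);

  arma::vec v = init_v;
  double ve = init_ve;
  int isave = 0;
  for (int it = 1; it <= n_iter; ++it) {
    const double se = 1.0 / ve;
    arma::mat C = se * M1;
    for (int k = 0; k < K; ++k) {
      const int o = offsets[k], s = sizes[k];
      C.submat(o, o, o + s - 1, o + s - 1) += (1.0 / v[k]) * G[k];
    }
    arma::mat U;
    if (!arma::chol(U, C)) {
      C.diag() += 1e-10 * arma::trace(C) / m;
      if (!arma::chol(U, C)) stop("location precision matrix is not positive definite");
    }
    arma::vec tmp = arma::solve(arma::trimatl(U.t()), se * Wty);
    arma::vec theta = arma::solve(arma::trimatu(U), tmp + rnorm_vec(m));

    arma::vec e = y - W * theta;
    double ssr = arma::dot(e, e);
    ve = rinvgamma(shape_e0 + 0.5 * n, scale_e0 + 0.5 * ssr);
    for (int k = 0; k < K; ++k) {
      arma::vec u = theta.subvec(offsets[k], offsets[k] + sizes[k] - 1);
      double ss = arma::as_scalar(u.t() * G[k] * u);
      v[k] = rinvgamma(shape0[k] + 0.5 * sizes[k], scale0[k] + 0.5 * ss);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && isave < n_store) {
      for (int j = 0; j < p; ++j) out(isave, j) = theta[j];
      for (int k = 0; k < K; ++k) out(isave, p + k) = v[k];
      out(isave, p + K) = ve;
      theta_sum += theta;
      ++isave;
    }
  }
  arma::vec theta_mean = theta_sum;
  if (n_store > 0) theta_mean /= n_store;
  return List::create(_["samples"] = out, _["theta_mean"] = theta_mean);
}
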
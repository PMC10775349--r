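// Compiled kernels for the Poisson linear relative-risk likelihood and the
// Metropolis-Hastings sampler of the quasi-2DMC Bayesian model averaging
// estimator.  Everything here consumes grouped data: case counts y_g,
// person-year offsets off_g and group doses d_g, with rates
// mu_g = exp(kappa) * off_g * (1 + alpha d_g + beta d_g^2).
// Log-likelihoods drop terms constant in the parameters (log y_g!).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log-likelihood at explicit (alpha, beta, kappa); -Inf outside the
// relative-risk positivity region.  profile_kappa replaces kappa by its
// closed-form maximiser exp(kappa_hat) = sum(y) / sum(off * RR).
static double ll_rr(const double* y, const double* off, const double* d,
                    int G, double alpha, double beta, double kappa,
                    bool profile_kappa) {
  double rr[64];
  if (G > 64) Rcpp::stop("more than 64 dose groups not supported");
  for (int g = 0; g < G; ++g) {
    double r = 1.0 + alpha * d[g] + beta * d[g] * d[g];
    if (r <= 0.0 || !std::isfinite(r)) return R_NegInf;
    rr[g] = r;
  }
  double ll = 0.0;
  if (profile_kappa) {
    double sy = 0.0, sor = 0.0;
    for (int g = 0; g < G; ++g) { sy += y[g]; sor += off[g] * rr[g]; }
    double lek = std::log(sy / sor);
    for (int g = 0; g < G; ++g)
      ll += y[g] * (lek + std::log(off[g] * rr[g]));
    ll -= sy;
  } else {
    double ek = std::exp(kappa);
    for (int g = 0; g < G; ++g) {
      double mu = ek * off[g] * rr[g];
      ll += y[g] * std::log(mu) - mu;
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_ll_poisson_rr(NumericVector y, NumericVector off,
                         NumericVector dose, double alpha, double beta,
                         double kappa) {
  return ll_rr(y.begin(), off.begin(), dose.begin(), y.size(),
               alpha, beta, kappa, false);
}

// [[Rcpp::export]]
double cpp_ll_profile_kappa(NumericVector y, NumericVector off,
                            NumericVector dose, double alpha, double beta) {
  return ll_rr(y.begin(), off.begin(), dose.begin(), y.size(),
               alpha, beta, 0.0, true);
}

// golden-section maximiser on (lo, hi); tolerance on the argument
template <class F>
static double golden_max(F f, double lo, double hi, double tol) {
  const double invphi = 0.6180339887498949;
  double a = lo, b = hi;
  double c = b - invphi * (b - a);
  double d = a + invphi * (b - a);
  double fc = f(c), fd = f(d);
  for (int it = 0; it < 200 && (b - a) > tol; ++it) {
    if (fc >= fd) { b = d; d = c; fd = fc; c = b - invphi * (b - a); fc = f(c); }
    else { a = c; c = d; fc = fd; d = a + invphi * (b - a); fd = f(d); }
  }
  return fc >= fd ? fc : fd;
}

// profile log-likelihood for alpha in the linear-quadratic model:
// maximised over beta on (blo, bhi), kappa profiled analytically
// [[Rcpp::export]]
double cpp_profile_over_beta(NumericVector y, NumericVector off,
                             NumericVector dose, double alpha,
                             double blo, double bhi) {
  const double* py = y.begin(); const double* po = off.begin();
  const double* pd = dose.begin(); int G = y.size();
  return golden_max([&](double b) {
    return ll_rr(py, po, pd, G, alpha, b, 0.0, true);
  }, blo, bhi, 1e-9 * (1.0 + std::fabs(blo) + std::fabs(bhi)) * 1e-3 + 1e-10);
}

// profile log-likelihood for beta: maximised over alpha on (alo, ahi)
// [[Rcpp::export]]
double cpp_profile_over_alpha(NumericVector y, NumericVector off,
                              NumericVector dose, double beta,
                              double alo, double ahi) {
  const double* py = y.begin(); const double* po = off.begin();
  const double* pd = dose.begin(); int G = y.size();
  return golden_max([&](double a) {
    return ll_rr(py, po, pd, G, a, beta, 0.0, true);
  }, alo, ahi, 1e-9 * (1.0 + std::fabs(alo) + std::fabs(ahi)) * 1e-3 + 1e-10);
}

// Monte Carlo likelihood: log[(1/m) sum_j L_j(kappa, alpha, beta)] where
// L_j is the Poisson likelihood under dose vector j (rows of dosevec)
// [[Rcpp::export]]
double cpp_ll_mcml(NumericVector y, NumericVector off, NumericMatrix dosevec,
                   double alpha, double beta, double kappa) {
  int m = dosevec.nrow(), G = dosevec.ncol();
  std::vector<double> ll(m);
  std::vector<double> dj(G);
  double mx = R_NegInf;
  for (int j = 0; j < m; ++j) {
    for (int g = 0; g < G; ++g) dj[g] = dosevec(j, g);
    ll[j] = ll_rr(y.begin(), off.begin(), dj.data(), G,
                  alpha, beta, kappa, false);
    if (ll[j] > mx) mx = ll[j];
  }
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < m; ++j)
    if (std::isfinite(ll[j])) s += std::exp(ll[j] - mx);
  return mx + std::log(s) - std::log((double)m);
}

// ---------------------------------------------------------------------------
// quasi-2DMC with BMA: Metropolis-Hastings sampler for the mixture posterior
//   p(theta, lambda | Y) propto [ sum_k p_k(lambda) L_k(theta) ]
//                               * N(theta; 0, prior_sd^2) * N(lambda; 0, prior_sd^2)
// with p_k the softmax of (lambda_1, ..., lambda_{m-1}, 0).  theta is
// updated one component at a time (kappa, alpha[, beta]); lambda in fixed
// sequential blocks.  Uses R's RNG so set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

struct MixState {
  std::vector<double> ll;    // per-vector log-likelihood at current theta
  std::vector<double> logp;  // current log mixture weights
  double logmix;             // logSumExp(logp + ll)
};

static void fill_ll(const NumericVector& y, const NumericVector& off,
                    const NumericMatrix& dosevec, bool quadratic,
                    const double* theta, std::vector<double>& ll) {
  int m = dosevec.nrow(), G = dosevec.ncol();
  std::vector<double> dj(G);
  double kappa = theta[0], alpha = theta[1];
  double beta = quadratic ? theta[2] : 0.0;
  for (int j = 0; j < m; ++j) {
    for (int g = 0; g < G; ++g) dj[g] = dosevec(j, g);
    ll[j] = ll_rr(y.begin(), off.begin(), dj.data(), G,
                  alpha, beta, kappa, false);
  }
}

static void softmax_logp(const std::vector<double>& lambda,
                         std::vector<double>& logp) {
  int m = (int)logp.size();
  double mx = 0.0;  // reference category has lambda_m = 0
  for (int k = 0; k < m - 1; ++k) if (lambda[k] > mx) mx = lambda[k];
  double s = std::exp(-mx);
  for (int k = 0; k < m - 1; ++k) s += std::exp(lambda[k] - mx);
  double lse = mx + std::log(s);
  for (int k = 0; k < m - 1; ++k) logp[k] = lambda[k] - lse;
  logp[m - 1] = -lse;
}

static double logsumexp2(const std::vector<double>& a,
                         const std::vector<double>& b) {
  double mx = R_NegInf;
  int n = (int)a.size();
  for (int i = 0; i < n; ++i) {
    double v = a[i] + b[i];
    if (v > mx) mx = v;
  }
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = a[i] + b[i];
    if (std::isfinite(v)) s += std::exp(v - mx);
  }
  return mx + std::log(s);
}

// [[Rcpp::export]]
List cpp_bma_sampler(NumericVector y, NumericVector off,
                     NumericMatrix dosevec, bool quadratic,
                     NumericVector init_theta, int n_burnin, int n_keep,
                     int n_chains, double prior_sd,
                     NumericVector prop_sd_theta, double prop_sd_lambda,
                     int lambda_block) {
  RNGScope scope;
  int m = dosevec.nrow();
  int n_theta = quadratic ? 3 : 2;
  int L = m - 1;
  int n_iter = n_burnin + n_keep;
  double pr2 = 2.0 * prior_sd * prior_sd;

  List chains(n_chains);
  NumericMatrix acc(n_chains, n_theta + 1);  // theta components + lambda

  for (int c = 0; c < n_chains; ++c) {
    std::vector<double> theta(n_theta);
    for (int p = 0; p < n_theta; ++p)
      theta[p] = init_theta[p] +
        (c == 0 ? 0.0 : 2.0 * prop_sd_theta[p] * norm_rand());
    std::vector<double> lambda(L, 0.0);
    if (c > 0)
      for (int k = 0; k < L; ++k) lambda[k] = 0.5 * norm_rand();

    MixState st;
    st.ll.resize(m); st.logp.resize(m);
    fill_ll(y, off, dosevec, quadratic, theta.data(), st.ll);
    softmax_logp(lambda, st.logp);
    st.logmix = logsumexp2(st.logp, st.ll);
    double lp_theta = 0.0, lp_lambda = 0.0;
    for (int p = 0; p < n_theta; ++p) lp_theta -= theta[p] * theta[p] / pr2;
    // lambda prior starts at its init value
    for (int k = 0; k < L; ++k) lp_lambda -= lambda[k] * lambda[k] / pr2;

    NumericMatrix kept(n_keep, n_theta);
    std::vector<long> acc_n(n_theta + 1, 0), tot_n(n_theta + 1, 0);
    std::vector<double> ll_prop(m), logp_prop(m), lam_prop(L);

    for (int it = 0; it < n_iter; ++it) {
      // (a) theta components, one scalar MH step each
      for (int p = 0; p < n_theta; ++p) {
        std::vector<double> th = theta;
        th[p] += prop_sd_theta[p] * norm_rand();
        fill_ll(y, off, dosevec, quadratic, th.data(), ll_prop);
        double logmix_p = logsumexp2(st.logp, ll_prop);
        double lp_p = 0.0;
        for (int q = 0; q < n_theta; ++q) lp_p -= th[q] * th[q] / pr2;
        double dlt = (logmix_p + lp_p) - (st.logmix + lp_theta);
        ++tot_n[p];
        if (std::isfinite(logmix_p) && std::log(unif_rand()) < dlt) {
          theta = th; st.ll = ll_prop; st.logmix = logmix_p;
          lp_theta = lp_p; ++acc_n[p];
        }
      }
      // (b) lambda in fixed sequential blocks
      for (int b0 = 0; b0 < L; b0 += lambda_block) {
        int b1 = std::min(b0 + lambda_block, L);
        lam_prop = lambda;
        for (int k = b0; k < b1; ++k)
          lam_prop[k] += prop_sd_lambda * norm_rand();
        softmax_logp(lam_prop, logp_prop);
        double logmix_p = logsumexp2(logp_prop, st.ll);
        double lp_p = 0.0;
        for (int k = 0; k < L; ++k) lp_p -= lam_prop[k] * lam_prop[k] / pr2;
        double dlt = (logmix_p + lp_p) - (st.logmix + lp_lambda);
        ++tot_n[n_theta];
        if (std::isfinite(logmix_p) && std::log(unif_rand()) < dlt) {
          lambda = lam_prop; st.logp = logp_prop; st.logmix = logmix_p;
          lp_lambda = lp_p; ++acc_n[n_theta];
        }
      }
      if (it >= n_burnin)
        for (int p = 0; p < n_theta; ++p) kept(it - n_burnin, p) = theta[p];
    }
    chains[c] = kept;
    for (int p = 0; p <= n_theta; ++p)
      acc(c, p) = tot_n[p] > 0 ? (double)acc_n[p] / (double)tot_n[p]
                               : NA_REAL;
  }
  return List::create(_["chains"] = chains, _["acceptance"] = acc);
}
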
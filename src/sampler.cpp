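// Per-gene hybrid Metropolis-Hastings/Gibbs kernel for the Bayesian negative
// binomial GLMM  y_s ~ NB(mu_s, alpha),  log mu_s = C_s theta + rho_s,
// theta = (beta, b),  beta ~ MVN(M, T),  b_i ~ N(0, sigma2),
// log alpha ~ N(A, B),  sigma2 ~ InvGamma(shape U, scale V).
//
// The regression block (beta, b) is updated jointly with a one-step weighted
// least squares (Gamerman-style) proposal; log alpha with an adaptive random
// walk (adaptation runs only during burn-in); sigma2 with an exact
// inverse-gamma Gibbs draw.
//
// Internally the regression block is ordered (b, beta): the random-intercept
// columns are unit indicators, so with them first the WLS normal matrix is
// arrow-shaped (diagonal b block, dense p x p tail) and both its assembly
// and its Cholesky factor stay cheap and sparse. The external interface
// keeps the conventional (beta, b) ordering. The hot path uses flat loops
// over preallocated workspaces; at these dimensions (a few dozen unknowns)
// factorization-library call overhead would dominate the arithmetic.
//
// All randomness comes from a local 64-bit Mersenne Twister seeded per gene,
// so chains are reproducible independently of R's RNG, worker count and gene
// ordering.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstdint>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double ETA_CLAMP = 30.0;

// FNV-1a hash of the gene id mixed with the master seed; reduced mod 2^53 so
// the value survives a round trip through an R double.
// [[Rcpp::export(name = ".gene_seed_cpp")]]
double gene_seed_cpp(int master_seed, std::string gene_id) {
  std::uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : gene_id) {
    h ^= static_cast<std::uint64_t>(c);
    h *= 1099511628211ULL;
  }
  h ^= static_cast<std::uint64_t>(static_cast<std::uint32_t>(master_seed)) *
       0x9E3779B97F4A7C15ULL;
  h ^= h >> 33;
  return static_cast<double>(h % 9007199254740992ULL);  // 2^53
}

// NB log pmf with mean mu and dispersion alpha (Var = mu + alpha mu^2),
// via log-gamma so large counts do not overflow.
// [[Rcpp::export(name = ".nb_loglik_cpp")]]
arma::vec nb_loglik_cpp(const arma::vec& y, const arma::vec& mu, double alpha) {
  const double r = 1.0 / alpha;
  arma::vec out(y.n_elem);
  for (arma::uword s = 0; s < y.n_elem; ++s) {
    out[s] = std::lgamma(y[s] + r) - std::lgamma(r) - std::lgamma(y[s] + 1.0) +
             r * std::log(r / (r + mu[s])) + y[s] * std::log(mu[s] / (r + mu[s]));
  }
  return out;
}

// Exposed for unit testing: n draws from the sigma2 full conditional
// InvGamma(shape U + I/2, scale V + ssq/2).
// [[Rcpp::export(name = ".draw_sigma2_cpp")]]
NumericVector draw_sigma2_cpp(int n, double U, double V, double ssq,
                              int n_subjects, double seed) {
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  const double shape = U + 0.5 * n_subjects;
  const double scale = V + 0.5 * ssq;
  std::gamma_distribution<double> g(shape, 1.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = scale / g(rng);
  return out;
}

namespace {

// Upper Cholesky Q = R'R of the d x d column-major symmetric matrix
// (upper triangle referenced), factor stored in place of the upper
// triangle. Returns false on a non-positive pivot.
bool chol_upper(std::vector<double>& A, int d) {
  for (int j = 0; j < d; ++j) {
    double sum = A[j * d + j];
    for (int k = 0; k < j; ++k) sum -= A[j * d + k] * A[j * d + k];
    if (sum <= 0.0 || !std::isfinite(sum)) return false;
    const double rjj = std::sqrt(sum);
    A[j * d + j] = rjj;
    for (int i = j + 1; i < d; ++i) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = s / rjj;
    }
  }
  return true;
}

// Solve R' y = b then R x = y in place (R upper, column-major: R[k <= j] at
// A[j*d + k]).
void chol_solve(const std::vector<double>& R, int d, std::vector<double>& x) {
  for (int j = 0; j < d; ++j) {
    double s = x[j];
    for (int k = 0; k < j; ++k) s -= R[j * d + k] * x[k];
    x[j] = s / R[j * d + j];
  }
  for (int j = d - 1; j >= 0; --j) {
    double s = x[j];
    for (int k = j + 1; k < d; ++k) s -= R[k * d + j] * x[k];
    x[j] = s / R[j * d + j];
  }
}

// Back-solve R x = z in place (for theta* = mean + R^{-1} z).
void backsolve_upper(const std::vector<double>& R, int d,
                     std::vector<double>& z) {
  for (int j = d - 1; j >= 0; --j) {
    double s = z[j];
    for (int k = j + 1; k < d; ++k) s -= R[k * d + j] * z[k];
    z[j] = s / R[j * d + j];
  }
}

// ||R (x - m)||^2 with R upper column-major.
double quad_prec(const std::vector<double>& R, int d, const double* x,
                 const std::vector<double>& m, std::vector<double>& diff) {
  for (int j = 0; j < d; ++j) diff[j] = x[j] - m[j];
  double q = 0.0;
  for (int k = 0; k < d; ++k) {
    double s = 0.0;
    for (int j = k; j < d; ++j) s += R[j * d + k] * diff[j];
    q += s * s;
  }
  return q;
}

// Workspace-owning sampler for one gene; internal ordering (b, beta).
struct GeneSampler {
  int S, d, p, I;           // d = I + p
  std::vector<double> X;    // S x p column-major fixed-effect block
  std::vector<int> subj;    // sample -> subject (q = 1), empty otherwise
  std::vector<double> y, off;
  std::vector<double> Tinv;   // p x p column-major
  std::vector<double> TinvM;  // Tinv * M
  std::vector<double> M;

  std::vector<double> Q, R, rhs, mean, diff;
  std::vector<double> w, wz;

  GeneSampler(int S_, int p_, int I_)
      : S(S_), d(I_ + p_), p(p_), I(I_), X(S_ * p_), y(S_), off(S_),
        Tinv(p_ * p_), TinvM(p_), M(p_), Q(d * d), R(d * d), rhs(d), mean(d),
        diff(d), w(S_), wz(S_) {}

  // eta and mu for a state (internal ordering).
  void linpred(const double* th, double* eta, double* mu) const {
    for (int s = 0; s < S; ++s)
      eta[s] = off[s] + (I > 0 ? th[subj[s]] : 0.0);
    for (int i = 0; i < p; ++i) {
      const double b = th[I + i];
      const double* xi = &X[i * S];
      for (int s = 0; s < S; ++s) eta[s] += xi[s] * b;
    }
    for (int s = 0; s < S; ++s) {
      double e = eta[s];
      if (e > ETA_CLAMP) e = ETA_CLAMP;
      if (e < -ETA_CLAMP) e = -ETA_CLAMP;
      eta[s] = e;
      mu[s] = std::exp(e);
    }
  }

  // One WLS step at th (eta/mu must match th). Fills mean, R, logdet.
  bool wls(const double* th, const double* eta, const double* mu, double alpha,
           double sigma2, double& logdet) {
    (void)th;
    for (int s = 0; s < S; ++s) {
      const double m = mu[s];
      const double ww = m / (1.0 + alpha * m);
      w[s] = ww;
      wz[s] = ww * ((eta[s] - off[s]) + (y[s] - m) / m);
    }
    std::fill(Q.begin(), Q.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    // b block: diagonal subject sums; cross block Z'WX; rhs
    if (I > 0) {
      for (int s = 0; s < S; ++s) {
        const int j = subj[s];
        Q[j * d + j] += w[s];
        rhs[j] += wz[s];
      }
    }
    for (int i = 0; i < p; ++i) {
      const double* xi = &X[i * S];
      const int ci = I + i;
      double r = 0.0;
      for (int s = 0; s < S; ++s) r += xi[s] * wz[s];
      rhs[ci] = r;
      if (I > 0) {
        double* qc = &Q[ci * d];
        for (int s = 0; s < S; ++s) qc[subj[s]] += w[s] * xi[s];
      }
      for (int k = 0; k <= i; ++k) {
        const double* xk = &X[k * S];
        double q = 0.0;
        for (int s = 0; s < S; ++s) q += xi[s] * w[s] * xk[s];
        Q[ci * d + (I + k)] = q;
      }
    }
    // prior precision blockdiag(I/sigma2, Tinv) and prior-mean pull
    const double inv_s2 = (I > 0) ? 1.0 / sigma2 : 0.0;
    for (int j = 0; j < I; ++j) Q[j * d + j] += inv_s2;
    for (int i = 0; i < p; ++i) {
      for (int k = 0; k <= i; ++k)
        Q[(I + i) * d + (I + k)] += Tinv[i * p + k];
      rhs[I + i] += TinvM[i];
    }

    R = Q;
    if (!chol_upper(R, d)) {
      R = Q;
      for (int j = 0; j < d; ++j) R[j * d + j] += 1e-8;
      if (!chol_upper(R, d)) return false;
    }
    logdet = 0.0;
    for (int j = 0; j < d; ++j) logdet += std::log(R[j * d + j]);
    logdet *= 2.0;
    mean = rhs;
    chol_solve(R, d, mean);
    for (int j = 0; j < d; ++j)
      if (!std::isfinite(mean[j])) return false;
    return true;
  }

  // likelihood terms varying with theta at fixed alpha
  double loglik_theta(const double* eta, const double* mu, double r) const {
    double ll = 0.0;
    for (int s = 0; s < S; ++s)
      ll += y[s] * eta[s] - (y[s] + r) * std::log(r + mu[s]);
    return ll;
  }

  // likelihood terms varying with alpha at fixed mu
  double loglik_alpha(const double* mu, double r) const {
    double ll = S * (r * std::log(r) - std::lgamma(r));
    for (int s = 0; s < S; ++s)
      ll += std::lgamma(y[s] + r) - (y[s] + r) * std::log(r + mu[s]);
    return ll;
  }

  double log_prior_theta(const double* th, double sigma2) const {
    double lp = 0.0;
    if (I > 0) {
      double ssq = 0.0;
      for (int j = 0; j < I; ++j) ssq += th[j] * th[j];
      lp -= 0.5 * ssq / sigma2;
    }
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int k = 0; k < p; ++k)
        s += Tinv[i * p + k] * (th[I + k] - M[k]);
      lp -= 0.5 * (th[I + i] - M[i]) * s;
    }
    return lp;
  }
};

// Split the external combined design [X | Z] (beta first) into the internal
// dense block and subject index; Z columns must be unit indicators.
void load_design(GeneSampler& gs, const arma::mat& C, int p) {
  const int S = C.n_rows;
  for (int i = 0; i < p; ++i)
    for (int s = 0; s < S; ++s) gs.X[i * S + s] = C(s, i);
  if (gs.I > 0) {
    gs.subj.resize(S);
    for (int s = 0; s < S; ++s) {
      int hit = -1;
      for (int j = 0; j < gs.I; ++j) {
        const double v = C(s, p + j);
        if (v != 0.0) {
          if (v != 1.0 || hit >= 0)
            stop("random-effect columns must be unit subject indicators");
          hit = j;
        }
      }
      if (hit < 0) stop("sample without a subject indicator");
      gs.subj[s] = hit;
    }
  }
}

}  // namespace

// Exposed for unit testing: the WLS proposal mean and covariance at a state,
// in the external (beta, b) ordering.
// [[Rcpp::export(name = ".wls_proposal_cpp")]]
List wls_proposal_cpp(const arma::vec& y, const arma::mat& C,
                      const arma::vec& offset, const arma::vec& theta,
                      double alpha, const arma::mat& Tinv, const arma::vec& M,
                      double sigma2, int p) {
  const int S = C.n_rows, d = C.n_cols, I = d - p;
  GeneSampler gs(S, p, I);
  load_design(gs, C, p);
  std::copy(y.begin(), y.end(), gs.y.begin());
  std::copy(offset.begin(), offset.end(), gs.off.begin());
  std::copy(Tinv.begin(), Tinv.end(), gs.Tinv.begin());
  std::copy(M.begin(), M.end(), gs.M.begin());
  arma::vec tm = Tinv * M;
  std::copy(tm.begin(), tm.end(), gs.TinvM.begin());

  std::vector<double> th(d);  // internal ordering (b, beta)
  for (int j = 0; j < I; ++j) th[j] = theta[p + j];
  for (int i = 0; i < p; ++i) th[I + i] = theta[i];
  std::vector<double> eta(S), mu(S);
  gs.linpred(th.data(), eta.data(), mu.data());
  double logdet;
  if (!gs.wls(th.data(), eta.data(), mu.data(), alpha, sigma2, logdet))
    stop("WLS proposal system is numerically singular");

  arma::mat Rm(d, d, arma::fill::zeros);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i <= j; ++i) Rm(i, j) = gs.R[j * d + i];
  arma::mat Rinv = arma::inv(arma::trimatu(Rm));
  arma::mat cov_int = Rinv * Rinv.t();
  // permute back to external (beta, b)
  arma::uvec perm(d);
  for (int i = 0; i < p; ++i) perm[i] = I + i;
  for (int j = 0; j < I; ++j) perm[p + j] = j;
  arma::vec mean_ext(d);
  for (int j = 0; j < d; ++j) mean_ext[j] = gs.mean[perm[j]];
  arma::mat cov = cov_int.submat(perm, perm);
  return List::create(_["mean"] = mean_ext, _["cov"] = cov);
}

// Run one gene's chain. C is the S x d combined design [X | Z], d = p + I
// (random-intercept model) or d = p (no random effects, n_subjects = 0).
// Returns retained draws, acceptance flags for every iteration, and
// bookkeeping.
// [[Rcpp::export(name = ".fit_gene_cpp")]]
List fit_gene_cpp(const arma::vec& y, const arma::mat& C,
                  const arma::vec& offset, int p, int n_subjects,
                  const arma::vec& M, const arma::mat& Tinv, double A, double B,
                  double U, double V, int n_iter, int n_burn,
                  const arma::vec& theta0, double log_alpha0, double sigma2_0,
                  double step_sd0, double target_accept, double seed,
                  bool save_b, int thin_b) {
  const int S = C.n_rows;
  const int d = C.n_cols;
  const int I = d - p;
  const int q = (I > 0) ? 1 : 0;
  const int n_keep = n_iter - n_burn;

  GeneSampler gs(S, p, I);
  load_design(gs, C, p);
  std::copy(y.begin(), y.end(), gs.y.begin());
  std::copy(offset.begin(), offset.end(), gs.off.begin());
  std::copy(Tinv.begin(), Tinv.end(), gs.Tinv.begin());
  std::copy(M.begin(), M.end(), gs.M.begin());
  {
    arma::vec tm = Tinv * M;
    std::copy(tm.begin(), tm.end(), gs.TinvM.begin());
  }

  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  std::gamma_distribution<double> rgamma1;

  std::vector<double> theta(d);  // internal ordering (b, beta)
  for (int j = 0; j < I; ++j) theta[j] = theta0[p + j];
  for (int i = 0; i < p; ++i) theta[I + i] = theta0[i];
  double log_alpha = log_alpha0;
  double alpha = std::exp(log_alpha);
  double sigma2 = (q == 1) ? sigma2_0 : 1.0;

  arma::mat beta_out(n_keep, p);
  arma::vec la_out(n_keep);
  arma::vec s2_out(q == 1 ? n_keep : 0);
  IntegerVector acc_beta(n_iter), acc_alpha(n_iter);
  const int n_b_keep = (save_b && q == 1) ? (n_keep + thin_b - 1) / thin_b : 0;
  arma::mat b_out(n_b_keep, q == 1 ? n_subjects : 0);

  std::vector<double> eta_cur(S), mu_cur(S), eta_star(S), mu_star(S);
  std::vector<double> theta_star(d), zdraw(d);
  std::vector<double> mean_cur(d), R_cur(d * d);
  gs.linpred(theta.data(), eta_cur.data(), mu_cur.data());

  double ls = std::log(step_sd0);
  int n_bad = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- regression block: one-step WLS Metropolis-Hastings ---
    bool accepted = false;
    double logdet_cur;
    bool ok = gs.wls(theta.data(), eta_cur.data(), mu_cur.data(), alpha,
                     sigma2, logdet_cur);
    if (ok) {
      mean_cur = gs.mean;
      R_cur = gs.R;
      for (int j = 0; j < d; ++j) zdraw[j] = rnorm01(rng);
      backsolve_upper(R_cur, d, zdraw);
      for (int j = 0; j < d; ++j) theta_star[j] = mean_cur[j] + zdraw[j];

      gs.linpred(theta_star.data(), eta_star.data(), mu_star.data());
      double logdet_rev;
      bool ok_rev = gs.wls(theta_star.data(), eta_star.data(), mu_star.data(),
                           alpha, sigma2, logdet_rev);
      if (ok_rev) {
        const double r = 1.0 / alpha;
        const double ll_cur = gs.loglik_theta(eta_cur.data(), mu_cur.data(), r);
        const double ll_star =
            gs.loglik_theta(eta_star.data(), mu_star.data(), r);
        const double lq_fwd =
            0.5 * logdet_cur -
            0.5 * quad_prec(R_cur, d, theta_star.data(), mean_cur, gs.diff);
        const double lq_rev =
            0.5 * logdet_rev -
            0.5 * quad_prec(gs.R, d, theta.data(), gs.mean, gs.diff);
        const double log_ratio =
            (ll_star + gs.log_prior_theta(theta_star.data(), sigma2) + lq_rev) -
            (ll_cur + gs.log_prior_theta(theta.data(), sigma2) + lq_fwd);
        if (std::isfinite(log_ratio) && std::log(runif01(rng)) < log_ratio) {
          theta.swap(theta_star);
          eta_cur.swap(eta_star);
          mu_cur.swap(mu_star);
          accepted = true;
        }
      } else {
        ++n_bad;
      }
    } else {
      ++n_bad;
    }
    acc_beta[it] = accepted ? 1 : 0;

    // --- dispersion: random walk on log alpha ---
    const double la_star = log_alpha + std::exp(ls) * rnorm01(rng);
    double log_ratio_a =
        (S > 0) ? gs.loglik_alpha(mu_cur.data(), std::exp(-la_star)) -
                      gs.loglik_alpha(mu_cur.data(), std::exp(-log_alpha))
                : 0.0;
    log_ratio_a += (-(la_star - A) * (la_star - A) +
                    (log_alpha - A) * (log_alpha - A)) /
                   (2.0 * B);
    const bool acc_a =
        std::isfinite(log_ratio_a) && std::log(runif01(rng)) < log_ratio_a;
    if (acc_a) {
      log_alpha = la_star;
      alpha = std::exp(log_alpha);
    }
    acc_alpha[it] = acc_a ? 1 : 0;

    // Robbins-Monro adaptation of the random-walk scale, burn-in only
    if (it < n_burn) {
      ls += ((acc_a ? 1.0 : 0.0) - target_accept) /
            std::pow(static_cast<double>(it + 1), 0.6);
      ls = std::min(std::max(ls, std::log(1e-3)), std::log(10.0));
    }

    // --- sigma2: exact inverse-gamma Gibbs draw ---
    if (q == 1) {
      double ssq = 0.0;
      for (int j = 0; j < I; ++j) ssq += theta[j] * theta[j];
      rgamma1.param(std::gamma_distribution<double>::param_type(
          U + 0.5 * n_subjects, 1.0));
      sigma2 = (V + 0.5 * ssq) / rgamma1(rng);
    }

    if (it >= n_burn) {
      const int k = it - n_burn;
      for (int i = 0; i < p; ++i) beta_out(k, i) = theta[I + i];
      la_out[k] = log_alpha;
      if (q == 1) s2_out[k] = sigma2;
      if (n_b_keep > 0 && k % thin_b == 0)
        for (int j = 0; j < I; ++j) b_out(k / thin_b, j) = theta[j];
    }
  }

  const bool failed = n_bad > n_iter / 2;
  return List::create(
      _["beta"] = beta_out, _["log_alpha"] = la_out, _["sigma2"] = s2_out,
      _["b"] = b_out, _["accept_beta"] = acc_beta, _["accept_alpha"] = acc_alpha,
      _["step_sd"] = std::exp(ls), _["n_bad"] = n_bad, _["failed"] = failed);
}
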
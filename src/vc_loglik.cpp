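// Blocked Gaussian likelihood kernels for the variance-component models.
// The likelihood factorizes over the connected components of the
// relatedness matrix, so each evaluation is a loop over small family
// blocks; fixed effects are profiled out by GLS inside the same pass.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double BIG_NLL = 1e10;

struct GlsAccum {
  double logdet = 0.0, yy = 0.0;
  arma::mat A;    // X' Omega^-1 X
  arma::vec b;    // X' Omega^-1 y
  arma::uword n = 0;
  bool ok = true;

  void init(arma::uword p) {
    A.zeros(p, p);
    b.zeros(p);
  }
  // accumulate one block given its covariance, design and response
  void add(const arma::mat& Om, const arma::mat& X, const arma::vec& y) {
    arma::mat R;
    if (!arma::chol(R, Om)) { ok = false; return; }
    logdet += 2.0 * arma::sum(arma::log(R.diag()));
    arma::mat W = arma::solve(arma::trimatl(R.t()), X);
    arma::vec u = arma::solve(arma::trimatl(R.t()), y);
    A += W.t() * W;
    b += W.t() * u;
    yy += arma::dot(u, u);
    n += y.n_elem;
  }
  // -2 log L after profiling beta (or with beta fixed when supplied)
  double neg2ll(const arma::vec* beta_fixed, arma::vec& beta_out) {
    if (!ok) return 2.0 * BIG_NLL;
    arma::vec beta;
    if (beta_fixed) beta = *beta_fixed;
    else if (!arma::solve(beta, A, b, arma::solve_opts::no_approx))
      return 2.0 * BIG_NLL;
    beta_out = beta;
    double quad = yy - 2.0 * arma::dot(beta, b) +
      arma::as_scalar(beta.t() * A * beta);
    return n * std::log(2.0 * M_PI) + logdet + quad;
  }
};

// With beta fixed the quadratic form above is exact because
// r' Om^-1 r expands in the accumulated pieces; nothing else changes.

static arma::mat gxage_block_cov(const arma::mat& K, const arma::vec& a,
                                 double ag, double gg, double ae, double ge,
                                 double lambda) {
  arma::vec sg = arma::exp(0.5 * (ag + gg * a));
  arma::vec se2 = arma::exp(ae + ge * a);
  arma::uword m = a.n_elem;
  arma::mat Om(m, m);
  for (arma::uword i = 0; i < m; ++i)
    for (arma::uword j = 0; j < m; ++j)
      Om(i, j) = K(i, j) * sg(i) * sg(j) *
        std::exp(-lambda * std::abs(a(i) - a(j)));
  Om.diag() += se2;
  return Om;
}

// [[Rcpp::export]]
double cpp_gxage_nll(NumericVector par, List Kb, List ab, List Xb, List yb,
                     Nullable<NumericVector> beta_fixed = R_NilValue) {
  double ag = par[0], gg = par[1], ae = par[2], ge = par[3], lam = par[4];
  int nb = Kb.size();
  GlsAccum acc;
  arma::mat X0 = as<arma::mat>(Xb[0]);
  acc.init(X0.n_cols);
  for (int bidx = 0; bidx < nb; ++bidx) {
    arma::mat K = as<arma::mat>(Kb[bidx]);
    arma::vec a = as<arma::vec>(ab[bidx]);
    arma::mat X = as<arma::mat>(Xb[bidx]);
    arma::vec y = as<arma::vec>(yb[bidx]);
    acc.add(gxage_block_cov(K, a, ag, gg, ae, ge, lam), X, y);
    if (!acc.ok) return BIG_NLL;
  }
  arma::vec beta_out;
  const arma::vec bf = beta_fixed.isNotNull()
    ? as<arma::vec>(beta_fixed.get()) : arma::vec();
  double n2 = acc.neg2ll(beta_fixed.isNotNull() ? &bf : nullptr, beta_out);
  return 0.5 * n2;
}

// [[Rcpp::export]]
List cpp_gxage_details(NumericVector par, List Kb, List ab, List Xb, List yb) {
  double ag = par[0], gg = par[1], ae = par[2], ge = par[3], lam = par[4];
  GlsAccum acc;
  acc.init(as<arma::mat>(Xb[0]).n_cols);
  for (int bidx = 0; bidx < Kb.size(); ++bidx)
    acc.add(gxage_block_cov(as<arma::mat>(Kb[bidx]), as<arma::vec>(ab[bidx]),
                            ag, gg, ae, ge, lam),
            as<arma::mat>(Xb[bidx]), as<arma::vec>(yb[bidx]));
  arma::vec beta;
  double n2 = acc.neg2ll(nullptr, beta);
  arma::mat bcov;
  if (!arma::inv_sympd(bcov, acc.A)) bcov.reset();
  return List::create(_["loglik"] = -0.5 * n2, _["beta"] = beta,
                      _["beta_cov"] = bcov);
}

// Stacked bivariate block: genetic cross-covariance rg*sqrt(sg1 sg2)*K,
// environmental cross-covariance re*sqrt(se1 se2) on the within-person
// diagonal only; rows with a missing response are dropped from the block.
static bool bivar_block(const arma::mat& K, const arma::mat& X,
                        const NumericVector& y1, const NumericVector& y2,
                        double sg1, double se1, double sg2, double se2,
                        double rg, double re, GlsAccum& acc) {
  arma::uword m = K.n_rows, p = X.n_cols;
  std::vector<arma::uword> o1, o2;
  for (arma::uword i = 0; i < m; ++i) {
    if (!NumericVector::is_na(y1[i])) o1.push_back(i);
    if (!NumericVector::is_na(y2[i])) o2.push_back(i);
  }
  arma::uword n1 = o1.size(), n2 = o2.size();
  if (n1 + n2 == 0) return true;
  arma::mat Om(n1 + n2, n1 + n2);
  arma::vec y(n1 + n2);
  arma::mat Xs(n1 + n2, 2 * p, arma::fill::zeros);
  double gc = rg * std::sqrt(sg1 * sg2);
  for (arma::uword i = 0; i < n1; ++i) {
    y(i) = y1[o1[i]];
    Xs(i, arma::span(0, p - 1)) = X.row(o1[i]);
    for (arma::uword j = 0; j < n1; ++j)
      Om(i, j) = sg1 * K(o1[i], o1[j]) + (o1[i] == o1[j] ? se1 : 0.0);
    for (arma::uword j = 0; j < n2; ++j)
      Om(i, n1 + j) = gc * K(o1[i], o2[j]) +
        (o1[i] == o2[j] ? re * std::sqrt(se1 * se2) : 0.0);
  }
  for (arma::uword i = 0; i < n2; ++i) {
    y(n1 + i) = y2[o2[i]];
    Xs(n1 + i, arma::span(p, 2 * p - 1)) = X.row(o2[i]);
    for (arma::uword j = 0; j < n1; ++j)
      Om(n1 + i, j) = Om(j, n1 + i);
    for (arma::uword j = 0; j < n2; ++j)
      Om(n1 + i, n1 + j) = sg2 * K(o2[i], o2[j]) + (o2[i] == o2[j] ? se2 : 0.0);
  }
  acc.add(Om, Xs, y);
  return acc.ok;
}

// [[Rcpp::export]]
double cpp_bivar_nll(NumericVector par, List Kb, List Xb, List y1b, List y2b,
                     Nullable<NumericVector> beta_fixed = R_NilValue) {
  double sg1 = std::exp(par[0]), se1 = std::exp(par[1]);
  double sg2 = std::exp(par[2]), se2 = std::exp(par[3]);
  double rg = std::tanh(par[4]), re = std::tanh(par[5]);
  GlsAccum acc;
  acc.init(2 * as<arma::mat>(Xb[0]).n_cols);
  for (int bidx = 0; bidx < Kb.size(); ++bidx) {
    if (!bivar_block(as<arma::mat>(Kb[bidx]), as<arma::mat>(Xb[bidx]),
                     y1b[bidx], y2b[bidx], sg1, se1, sg2, se2, rg, re, acc))
      return BIG_NLL;
  }
  arma::vec beta_out;
  const arma::vec bf = beta_fixed.isNotNull()
    ? as<arma::vec>(beta_fixed.get()) : arma::vec();
  return 0.5 * acc.neg2ll(beta_fixed.isNotNull() ? &bf : nullptr, beta_out);
}

// [[Rcpp::export]]
List cpp_bivar_details(NumericVector par, List Kb, List Xb, List y1b,
                       List y2b) {
  double sg1 = std::exp(par[0]), se1 = std::exp(par[1]);
  double sg2 = std::exp(par[2]), se2 = std::exp(par[3]);
  double rg = std::tanh(par[4]), re = std::tanh(par[5]);
  GlsAccum acc;
  acc.init(2 * as<arma::mat>(Xb[0]).n_cols);
  for (int bidx = 0; bidx < Kb.size(); ++bidx)
    bivar_block(as<arma::mat>(Kb[bidx]), as<arma::mat>(Xb[bidx]),
                y1b[bidx], y2b[bidx], sg1, se1, sg2, se2, rg, re, acc);
  arma::vec beta;
  double n2 = acc.neg2ll(nullptr, beta);
  arma::mat bcov;
  if (!arma::inv_sympd(bcov, acc.A)) bcov.reset();
  return List::create(_["loglik"] = -0.5 * n2, _["beta"] = beta,
                      _["beta_cov"] = bcov);
}
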
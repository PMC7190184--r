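// Cox partial-likelihood machinery (Breslow ties) shared by the fitting,
// screening and penalized-selection layers. All routines assume subjects
// sorted by ascending observed time; `first` holds, for each subject, the
// 0-based index of the first member of its tie group, so the risk set of
// subject i is {first[i], ..., n-1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log partial likelihood, per-subject gradient g and diagonal Hessian w
// (both with respect to the linear predictor eta); returns the likelihood.
static double cox_gw(const arma::vec& eta, const arma::vec& delta,
                     const arma::ivec& first, arma::vec* g, arma::vec* w) {
  const int n = eta.n_elem;
  arma::vec theta = arma::exp(eta);
  arma::vec rs(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) { acc += theta[i]; rs[i] = acc; }

  double ll = 0.0, h1 = 0.0, h2 = 0.0;
  int i = 0;
  while (i < n) {
    const int gf = first[i];
    int j = i;
    double dg = 0.0;
    const double S = rs[gf];
    while (j < n && first[j] == gf) {
      if (delta[j] > 0) { dg += 1.0; ll += eta[j]; }
      ++j;
    }
    if (dg > 0) {
      ll -= dg * std::log(S);
      h1 += dg / S;
      h2 += dg / (S * S);
    }
    if (g != nullptr) {
      for (int l = i; l < j; ++l) {
        (*g)[l] = delta[l] - theta[l] * h1;
        (*w)[l] = theta[l] * h1 - theta[l] * theta[l] * h2;
      }
    }
    i = j;
  }
  return ll;
}

// [[Rcpp::export]]
double cox_loglik_cpp(const arma::vec& eta, const arma::vec& delta,
                      const arma::ivec& first) {
  return cox_gw(eta, delta, first, nullptr, nullptr);
}

// [[Rcpp::export]]
List cox_gradient_cpp(const arma::vec& eta, const arma::vec& delta,
                      const arma::ivec& first) {
  const int n = eta.n_elem;
  arma::vec g(n), w(n);
  double ll = cox_gw(eta, delta, first, &g, &w);
  return List::create(_["loglik"] = ll, _["g"] = g, _["w"] = w);
}

// exact score vector and observed information at beta; allocation-free hot
// loops (the screening layer calls this thousands of times per dataset)
static double cox_score_info(const arma::mat& X, const arma::vec& delta,
                             const arma::ivec& first, const arma::vec& beta,
                             arma::vec& score, arma::mat& info) {
  const int n = X.n_rows, d = X.n_cols;
  arma::vec eta = X * beta;
  arma::vec theta = arma::exp(eta);
  score.zeros(d);
  info.zeros(d, d);
  double ll = 0.0, s0 = 0.0;
  arma::vec s1(d, arma::fill::zeros), xbar(d);
  arma::mat s2(d, d, arma::fill::zeros);
  int i = n - 1;
  while (i >= 0) {
    const int gf = first[i];
    for (int l = i; l >= gf; --l) {
      const double th = theta[l];
      s0 += th;
      for (int a = 0; a < d; ++a) {
        const double xa = X(l, a);
        s1[a] += th * xa;
        for (int b = 0; b <= a; ++b) s2(a, b) += th * xa * X(l, b);
      }
    }
    for (int l = i; l >= gf; --l) {
      if (delta[l] > 0) {
        ll += eta[l] - std::log(s0);
        for (int a = 0; a < d; ++a) xbar[a] = s1[a] / s0;
        for (int a = 0; a < d; ++a) {
          score[a] += X(l, a) - xbar[a];
          for (int b = 0; b <= a; ++b)
            info(a, b) += s2(a, b) / s0 - xbar[a] * xbar[b];
        }
      }
    }
    i = gf - 1;
  }
  for (int a = 0; a < d; ++a)
    for (int b = a + 1; b < d; ++b) info(a, b) = info(b, a);
  return ll;
}

// Newton-Raphson with step halving on likelihood decrease.
// [[Rcpp::export]]
List cox_newton_cpp(const arma::mat& X, const arma::vec& delta,
                    const arma::ivec& first, const arma::vec& beta0,
                    const int maxit = 100, const double tol = 1e-9) {
  const int d = X.n_cols;
  arma::vec beta = beta0, score(d);
  arma::mat info(d, d);
  double ll = cox_score_info(X, delta, first, beta, score, info);
  if (!std::isfinite(ll)) stop("non-finite linear predictor");
  bool conv = false, singular = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    arma::vec step;
    const bool ok = arma::solve(step, info, score,
                                arma::solve_opts::no_approx);
    if (!ok) { singular = true; break; }
    double t = 1.0, llnew = R_NegInf;
    arma::vec bnew = beta, snew(d);
    arma::mat inew(d, d);
    for (int h = 0; h < 40; ++h) {
      bnew = beta + t * step;
      llnew = cox_score_info(X, delta, first, bnew, snew, inew);
      if (std::isfinite(llnew) && llnew >= ll - 1e-12) break;
      t /= 2.0;
    }
    if (!std::isfinite(llnew)) { singular = true; break; }
    const double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
    beta = bnew;
    ll = llnew;
    score = snew;
    info = inew;
    if (rel < tol) { conv = true; break; }
  }
  return List::create(_["coefficients"] = beta, _["loglik"] = ll,
                      _["score"] = score, _["information"] = info,
                      _["iterations"] = it, _["converged"] = conv,
                      _["singular"] = singular);
}

// Marginal Cox fits (Xfixed plus one mediator column at a time) for sure
// independence screening and the naive comparator. Returns the mediator
// coefficient, its SE and the standardized utility |b|/se; failures give
// utility 0 instead of an error.
// [[Rcpp::export]]
List cox_sis_cpp(const arma::mat& Xfixed, const arma::mat& M,
                 const arma::vec& delta, const arma::ivec& first,
                 const int maxit = 30, const double tol = 1e-8) {
  const int n = M.n_rows, p = M.n_cols, q = Xfixed.n_cols;
  const int d = q + 1;
  arma::vec coef(p), se(p), util(p);
  coef.fill(NA_REAL);
  se.fill(NA_REAL);
  util.zeros();
  int n_failed = 0;

  // warm start: fit the fixed columns once
  arma::vec bfix(q, arma::fill::zeros);
  if (q > 0) {
    arma::vec sc(q);
    arma::mat in_(q, q);
    double ll = cox_score_info(Xfixed, delta, first, bfix, sc, in_);
    for (int it = 0; it < maxit; ++it) {
      arma::vec stp;
      if (!arma::solve(stp, in_, sc, arma::solve_opts::no_approx)) break;
      double t = 1.0, llnew = R_NegInf;
      arma::vec bnew = bfix;
      for (int h = 0; h < 30; ++h) {
        bnew = bfix + t * stp;
        llnew = cox_score_info(Xfixed, delta, first, bnew, sc, in_);
        if (std::isfinite(llnew) && llnew >= ll - 1e-12) break;
        t /= 2.0;
      }
      const double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
      bfix = bnew;
      ll = llnew;
      if (rel < tol) break;
    }
  }

  arma::mat X(n, d);
  if (q > 0) X.cols(0, q - 1) = Xfixed;
  arma::vec score(d);
  arma::mat info(d, d);

  for (int k = 0; k < p; ++k) {
    const arma::vec mk = M.col(k);
    const double sd = arma::stddev(mk, 1);
    if (!std::isfinite(sd) || sd < 1e-12) { ++n_failed; continue; }
    X.col(d - 1) = mk;
    arma::vec beta(d, arma::fill::zeros);
    if (q > 0) beta.subvec(0, q - 1) = bfix;
    bool ok = true;
    double ll = cox_score_info(X, delta, first, beta, score, info);
    for (int it = 0; it < maxit; ++it) {
      arma::vec stp;
      if (!arma::solve(stp, info, score, arma::solve_opts::no_approx)) {
        ok = false;
        break;
      }
      double t = 1.0, llnew = R_NegInf;
      arma::vec bnew = beta;
      for (int h = 0; h < 30; ++h) {
        bnew = beta + t * stp;
        llnew = cox_score_info(X, delta, first, bnew, score, info);
        if (std::isfinite(llnew) && llnew >= ll - 1e-12) break;
        t /= 2.0;
      }
      if (!std::isfinite(llnew)) { ok = false; break; }
      const double rel = std::fabs(llnew - ll) / (std::fabs(ll) + 1.0);
      beta = bnew;
      ll = llnew;
      if (rel < tol) break;
    }
    if (!ok || arma::abs(beta).max() > 50.0) { ++n_failed; continue; }
    arma::mat cov;
    if (!arma::inv_sympd(cov, info)) {
      if (!arma::inv(cov, info)) { ++n_failed; continue; }
    }
    const double v = cov(d - 1, d - 1);
    if (!std::isfinite(v) || v <= 0) { ++n_failed; continue; }
    coef[k] = beta[d - 1];
    se[k] = std::sqrt(v);
    util[k] = std::fabs(coef[k]) / se[k];
  }
  return List::create(_["coef"] = coef, _["se"] = se, _["utility"] = util,
                      _["n_failed"] = n_failed);
}

// ---- penalized Cox path (MCP / lasso) ------------------------------------

static double pen_value(const double b, const double lam, const double a,
                        const int kind) {
  const double ab = std::fabs(b);
  if (kind == 1) return lam * ab;  // lasso
  if (ab <= a * lam) return lam * ab - b * b / (2.0 * a);
  return a * lam * lam / 2.0;
}

static double pen_sum(const arma::vec& bp, const double lam, const double a,
                      const int kind) {
  double s = 0.0;
  for (arma::uword j = 0; j < bp.n_elem; ++j)
    s += pen_value(bp[j], lam, a, kind);
  return s;
}

// exact minimizer of q(b) = v/2 b^2 - u b + P_lam(|b|) by candidate
// enumeration (valid also when v <= 1/a, where the MCP middle piece is
// concave and the usual closed form does not apply)
static double cd_update(const double u, const double v, const double lam,
                        const double a, const int kind) {
  if (lam <= 0.0) return u / v;
  if (kind == 1) {
    double s = 0.0;
    if (u > lam) s = u - lam;
    else if (u < -lam) s = u + lam;
    return s / v;
  }
  double best_b = 0.0, best_q = 0.0;  // q(0) = 0
  const double alam = a * lam;
  auto consider = [&](const double b) {
    const double q = 0.5 * v * b * b - u * b + pen_value(b, lam, a, 0);
    if (q < best_q) { best_q = q; best_b = b; }
  };
  const double denom = v - 1.0 / a;
  double su = 0.0;
  if (u > lam) su = u - lam;
  else if (u < -lam) su = u + lam;
  if (denom > 1e-12 && su != 0.0) {
    const double b1 = su / denom;
    if (std::fabs(b1) <= alam) consider(b1);
  }
  const double b2 = u / v;
  if (std::fabs(b2) >= alam) consider(b2);
  consider(alam);
  consider(-alam);
  return best_b;
}

// [[Rcpp::export]]
double mcp_threshold_cpp(const double u, const double v, const double lam,
                         const double a, const int kind) {
  return cd_update(u, v, lam, a, kind);
}

// Penalized Cox path by iteratively reweighted least squares with
// coordinate descent: each cycle re-approximates the partial likelihood by
// its diagonal-Hessian quadratic at the current coefficients, sweeps the
// unpenalized columns (plain coordinate-Newton) and the active penalized
// columns with the exact MCP/soft thresholding update, and step-halves if
// the true penalized objective (1/n) loglik - sum P_lam decreased. When the
// active-set cycles stabilize below `tol`, a full sweep over all penalized
// columns verifies the KKT conditions before the lambda is declared
// converged. Warm starts along the (decreasing) lambda grid.
// [[Rcpp::export]]
List cox_pen_path_cpp(const arma::mat& Xu, const arma::mat& Xp,
                      const arma::vec& delta, const arma::ivec& first,
                      const arma::vec& lambdas, const double a,
                      const int kind, const double tol = 1e-7,
                      const int max_cycles = 2000,
                      Nullable<NumericVector> bu_init = R_NilValue,
                      Nullable<NumericVector> bp_init = R_NilValue) {
  const int n = Xp.n_rows, pu = Xu.n_cols, pp = Xp.n_cols;
  const int nl = lambdas.n_elem;
  arma::vec bu(pu, arma::fill::zeros), bp(pp, arma::fill::zeros);
  if (bu_init.isNotNull()) bu = as<arma::vec>(bu_init);
  if (bp_init.isNotNull()) bp = as<arma::vec>(bp_init);

  arma::mat BU(pu, nl), BP(pp, nl);
  arma::vec lls(nl), objs(nl);
  arma::ivec iters(nl), convs(nl);

  arma::vec eta(n, arma::fill::zeros);
  if (pu > 0) eta += Xu * bu;
  if (pp > 0) eta += Xp * bp;
  arma::vec g(n), w(n), wv(n), r(n);
  arma::vec eta_prev(n), bu_prev(pu), bp_prev(pp);
  std::vector<char> active(pp);

  // one coordinate update of column `col` (penalized iff lam >= 0)
  auto update_col = [&](const double* x, double& bj, const double lam) {
    double u = 0.0, v = 0.0;
    for (int i = 0; i < n; ++i) {
      const double wx = wv[i] * x[i];
      u += wx * r[i];
      v += wx * x[i];
    }
    u = u / n + (v / n) * bj;
    v /= n;
    const double bnew = (lam < 0.0) ? u / v : cd_update(u, v, lam, a, kind);
    const double db = bnew - bj;
    if (db != 0.0) {
      for (int i = 0; i < n; ++i) {
        r[i] -= db * x[i];
        eta[i] += db * x[i];
      }
      bj = bnew;
    }
    return std::fabs(db);
  };

  for (int li = 0; li < nl; ++li) {
    const double lam = lambdas[li];
    for (int j = 0; j < pp; ++j) active[j] = (bp[j] != 0.0);
    bool conv = false, do_full = true;  // first cycle sweeps everything
    int it = 0;
    double ll = cox_gw(eta, delta, first, &g, &w);
    double obj = ll / n - pen_sum(bp, lam, a, kind);
    while (it < max_cycles) {
      ++it;
      eta_prev = eta;
      bu_prev = bu;
      bp_prev = bp;
      const double obj_prev = obj;
      for (int i = 0; i < n; ++i) wv[i] = (w[i] < 1e-10) ? 1e-10 : w[i];
      for (int i = 0; i < n; ++i) r[i] = g[i] / wv[i];
      double maxch = 0.0;
      bool grew = false;
      const bool was_full = do_full;
      for (int j = 0; j < pu; ++j)
        maxch = std::max(maxch, update_col(Xu.colptr(j), bu[j], -1.0));
      for (int j = 0; j < pp; ++j) {
        if (!do_full && !active[j]) continue;
        const bool was_nz = active[j];
        maxch = std::max(maxch, update_col(Xp.colptr(j), bp[j], lam));
        active[j] = (bp[j] != 0.0);
        if (active[j] && !was_nz) grew = true;
      }
      ll = cox_gw(eta, delta, first, &g, &w);
      obj = ll / n - pen_sum(bp, lam, a, kind);
      int halv = 0;
      while ((!std::isfinite(obj) || obj < obj_prev - 1e-10) && halv < 30) {
        bu = 0.5 * (bu + bu_prev);
        bp = 0.5 * (bp + bp_prev);
        eta = 0.5 * (eta + eta_prev);
        ll = cox_gw(eta, delta, first, &g, &w);
        obj = ll / n - pen_sum(bp, lam, a, kind);
        maxch *= 0.5;
        ++halv;
        for (int j = 0; j < pp; ++j) active[j] = (bp[j] != 0.0);
      }
      if (maxch < tol) {
        if (was_full && !grew) { conv = true; break; }
        do_full = true;  // KKT sweep over all penalized columns
      } else {
        do_full = false;
      }
    }
    BU.col(li) = bu;
    BP.col(li) = bp;
    lls[li] = ll;
    objs[li] = obj;
    iters[li] = it;
    convs[li] = conv ? 1 : 0;
  }
  return List::create(_["beta_unpen"] = BU, _["beta_pen"] = BP,
                      _["loglik"] = lls, _["objective"] = objs,
                      _["iterations"] = iters, _["converged"] = convs);
}
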
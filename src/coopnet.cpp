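// Penalized cause-specific Cox solver: IRLS (diagonal Hessian) wrapped around
// cyclic coordinate descent with per-feature penalty factors, pathwise over a
// decreasing lambda sequence with warm starts, sequential strong-rule
// screening and deviance-based early stopping, plus the scalar theta step for
// the feature-weighted penalty.
//
// Objective at one (lambda, pf):
//   f(beta) = NLL(beta)/n + lambda * sum_j pf_j (alpha|beta_j| + (1-alpha)/2 beta_j^2)
// where NLL is the (sum-scale) negative Cox log partial likelihood with the
// Breslow convention for ties.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct CoxWork {
  arma::vec g;   // dNLL/deta, original observation order
  arma::vec w;   // diagonal Hessian of NLL wrt eta, clamped >= 0
  double nll;    // sum-scale negative log partial likelihood
};

// ord: 0-based permutation sorting times ascending; firsts/lasts: for each
// sorted position, the first/last sorted position sharing the same time.
static CoxWork cox_working(const arma::vec& eta, const arma::uvec& ord,
                           const arma::uvec& firsts, const arma::uvec& lasts,
                           const arma::vec& delta) {
  const int n = eta.n_elem;
  CoxWork out;
  out.g.zeros(n);
  out.w.zeros(n);
  out.nll = 0.0;
  const double m = arma::mean(eta);  // centering: partial likelihood invariant
  arma::vec es(n), ds(n), etas(n);
  for (int i = 0; i < n; ++i) {
    etas[i] = eta[ord[i]] - m;
    es[i] = std::exp(etas[i]);
    ds[i] = delta[ord[i]];
  }
  arma::vec s0rev(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    acc += es[i];
    s0rev[i] = acc;
  }
  arma::vec term(n, arma::fill::zeros), term2(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    if (ds[i] > 0) {
      const double s0 = s0rev[firsts[i]];
      term[i] = ds[i] / s0;
      term2[i] = ds[i] / (s0 * s0);
      out.nll += ds[i] * (std::log(s0) - etas[i]);
    }
  }
  double a1 = 0.0, a2 = 0.0;
  arma::vec cum1(n), cum2(n);
  for (int i = 0; i < n; ++i) {
    a1 += term[i];
    a2 += term2[i];
    cum1[i] = a1;
    cum2[i] = a2;
  }
  for (int i = 0; i < n; ++i) {
    const double A = cum1[lasts[i]];
    const double B = cum2[lasts[i]];
    const double gi = -ds[i] + es[i] * A;
    double wi = es[i] * A - es[i] * es[i] * B;
    if (!(wi > 0)) wi = 0.0;
    out.g[ord[i]] = gi;
    out.w[ord[i]] = wi;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cox_working(const arma::vec& eta, const arma::uvec& ord,
                     const arma::uvec& firsts, const arma::uvec& lasts,
                     const arma::vec& delta) {
  CoxWork cw = cox_working(eta, ord, firsts, lasts, delta);
  return List::create(_["g_eta"] = cw.g, _["w"] = cw.w, _["nll"] = cw.nll);
}

// NLL for each column of a linear-predictor matrix (batched CV helper).
// [[Rcpp::export]]
arma::vec cpp_cox_nll_multi(const arma::mat& Eta, const arma::uvec& ord,
                            const arma::uvec& firsts, const arma::uvec& lasts,
                            const arma::vec& delta) {
  arma::vec out(Eta.n_cols);
  for (arma::uword l = 0; l < Eta.n_cols; ++l)
    out[l] = cox_working(Eta.col(l), ord, firsts, lasts, delta).nll;
  return out;
}

static double penalty_val(const arma::vec& beta, const arma::vec& pf,
                          double alpha, double lam,
                          const std::vector<int>& active) {
  double s = 0.0;
  for (int j : active) {
    const double b = beta[j];
    if (b != 0.0)
      s += pf[j] * (alpha * std::fabs(b) + 0.5 * (1.0 - alpha) * b * b);
  }
  return lam * s;
}

// Cache of sqrt(weight)-scaled active columns, rebuilt per IRLS iteration so
// that each coordinate update is a pure two-array dot/axpy.
struct ColCache {
  std::vector<arma::vec> col;
  std::vector<char> have;
  arma::vec xv;  // (1/n) sum_i w_i x_ij^2
  void reset(int p) {
    col.assign(p, arma::vec());
    have.assign(p, 0);
    xv.zeros(p);
  }
  void ensure(int j, const arma::mat& X, const arma::vec& sqw) {
    if (!have[j]) {
      col[j] = X.col(j) % sqw;
      xv[j] = arma::dot(col[j], col[j]) / X.n_rows;
      have[j] = 1;
    }
  }
};

// Cyclic coordinate descent over the active set for the weighted
// least-squares subproblem; rs = sqrt(w) .* (z - X beta) maintained in place.
static void cd_active(const arma::mat& X, const arma::vec& sqw, arma::vec& rs,
                      arma::vec& beta, const std::vector<int>& active,
                      ColCache& cache, double alpha, double lam,
                      const arma::vec& pf, double tol, int maxit) {
  const int n = X.n_rows;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int j : active) {
      cache.ensure(j, X, sqw);
      const double bj = beta[j];
      const double rho = arma::dot(cache.col[j], rs) / n + cache.xv[j] * bj;
      const double l1 = lam * alpha * pf[j];
      const double denom = cache.xv[j] + lam * (1.0 - alpha) * pf[j];
      double bnew = 0.0;
      if (denom > 0) {
        const double st = std::fabs(rho) - l1;
        if (st > 0) bnew = std::copysign(st, rho) / denom;
      }
      const double d = bnew - bj;
      if (d != 0.0) {
        rs -= cache.col[j] * d;
        beta[j] = bnew;
        // glmnet-style convergence measure: curvature-weighted squared change
        const double chg = d * d * (cache.xv[j] > 0 ? cache.xv[j] : 1.0);
        if (chg > dmax) dmax = chg;
      }
    }
    if (dmax < tol) break;
  }
}

// Scan coords in `cand` not yet active for KKT violations of the WLS
// subproblem at beta_j = 0; add violators to active. Returns count added.
// wr = w .* (z - X beta) = sqw .* rs.
static int add_violators(const arma::mat& X, const arma::vec& wr,
                         std::vector<int>& active,
                         std::vector<char>& in_active,
                         const std::vector<int>& cand, double alpha,
                         double lam, const arma::vec& pf) {
  const double n = X.n_rows;
  int added = 0;
  for (int j : cand) {
    if (in_active[j]) continue;
    const double s = arma::dot(X.col(j), wr) / n;
    if (std::fabs(s) > lam * alpha * pf[j] * (1.0 + 1e-9) + 1e-12) {
      active.push_back(j);
      in_active[j] = 1;
      ++added;
    }
  }
  return added;
}

// Solve at fixed (lam, pf) by IRLS with step halving. beta/eta updated in
// place; active/in_active grow as coordinates enter. `screened` is the strong
// candidate set searched during inner iterations; a final full scan certifies
// the solution. Returns the objective.
static double irls_solve(const arma::mat& X, const arma::vec& delta,
                         const arma::uvec& ord, const arma::uvec& firsts,
                         const arma::uvec& lasts, double alpha, double lam,
                         const arma::vec& pf, arma::vec& beta, arma::vec& eta,
                         std::vector<int>& active, std::vector<char>& in_active,
                         const std::vector<int>& screened,
                         const std::vector<int>& all_idx, double cd_tol,
                         int cd_maxit, int irls_maxit, double irls_tol,
                         int& flag_maxit) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  CoxWork cw = cox_working(eta, ord, firsts, lasts, delta);
  ColCache cache;

  for (int full_pass = 0; full_pass < 5; ++full_pass) {
    double obj = cw.nll / n + penalty_val(beta, pf, alpha, lam, active);
    for (int it = 0; it < irls_maxit; ++it) {
      arma::vec wv = cw.w;
      arma::vec z = eta;
      for (int i = 0; i < n; ++i) {
        if (wv[i] > 1e-10) z[i] = eta[i] - cw.g[i] / wv[i];
        else wv[i] = 0.0;
      }
      arma::vec sqw = arma::sqrt(wv);
      cache.reset(p);
      arma::vec beta_old = beta, eta_old = eta;
      const double obj_old = obj;
      arma::vec rs = sqw % (z - eta);
      for (;;) {
        cd_active(X, sqw, rs, beta, active, cache, alpha, lam, pf, cd_tol,
                  cd_maxit);
        arma::vec wr = sqw % rs;
        if (add_violators(X, wr, active, in_active, screened, alpha, lam, pf) == 0)
          break;
      }
      eta = eta_old;
      for (int j : active) {
        const double d = beta[j] - beta_old[j];
        if (d != 0.0) eta += X.col(j) * d;
      }
      CoxWork cw_new = cox_working(eta, ord, firsts, lasts, delta);
      double obj_new = cw_new.nll / n + penalty_val(beta, pf, alpha, lam, active);
      int h = 0;
      while (obj_new > obj_old + 1e-12 && h < 15) {
        beta = 0.5 * (beta + beta_old);
        eta = 0.5 * (eta + eta_old);
        cw_new = cox_working(eta, ord, firsts, lasts, delta);
        obj_new = cw_new.nll / n + penalty_val(beta, pf, alpha, lam, active);
        ++h;
      }
      if (obj_new > obj_old + 1e-12) {  // could not descend: restore and stop
        beta = beta_old;
        eta = eta_old;
        obj = obj_old;
        cw = cox_working(eta, ord, firsts, lasts, delta);
        break;
      }
      cw = cw_new;
      obj = obj_new;
      if (obj_old - obj < irls_tol * (std::fabs(obj_old) + 1e-10)) break;
      if (it == irls_maxit - 1) flag_maxit++;
    }
    // certify against every coordinate (true KKT on the quadratic at optimum)
    arma::vec wv = cw.w;
    arma::vec z = eta;
    for (int i = 0; i < n; ++i) {
      if (wv[i] > 1e-10) z[i] = eta[i] - cw.g[i] / wv[i];
      else wv[i] = 0.0;
    }
    arma::vec wr = wv % (z - eta);
    if (add_violators(X, wr, active, in_active, all_idx, alpha, lam, pf) == 0)
      return obj;
  }
  return cw.nll / n + penalty_val(beta, pf, alpha, lam, active);
}

// Eq.-4 style weights: w_j = sum_l exp(z_l th) / (p exp(z_j th)), guarded by
// subtracting max(z th) before exponentiation.
static arma::vec theta_weights(const arma::vec& z, double theta) {
  const int p = z.n_elem;
  arma::vec s = z * theta;
  const double m = s.max();
  double tot = 0.0;
  arma::vec e(p);
  for (int j = 0; j < p; ++j) {
    e[j] = std::exp(s[j] - m);
    tot += e[j];
  }
  arma::vec w(p);
  for (int j = 0; j < p; ++j) w[j] = tot / (p * e[j]);
  return w;
}

// [[Rcpp::export]]
arma::vec cpp_theta_weights(const arma::vec& z, double theta) {
  return theta_weights(z, theta);
}

// Penalty term as a function of theta: lambda/p * S+(th) * S-(th) with
// S+ = sum_l exp(z_l th), S- = sum_j c_j exp(-z_j th); computed via
// log-sum-exp. Also returns d/dtheta through `grad`.
static double pen_of_theta(const arma::vec& z, const arma::vec& cpen,
                           double lam, double theta, double* grad) {
  const int p = z.n_elem;
  double m1 = -std::numeric_limits<double>::infinity();
  double m2 = -std::numeric_limits<double>::infinity();
  bool any_c = false;
  for (int j = 0; j < p; ++j) {
    if (z[j] * theta > m1) m1 = z[j] * theta;
    if (cpen[j] > 0) {
      any_c = true;
      const double t = std::log(cpen[j]) - z[j] * theta;
      if (t > m2) m2 = t;
    }
  }
  if (!any_c) {
    if (grad) *grad = 0.0;
    return 0.0;
  }
  double s1 = 0.0, s2 = 0.0, d1 = 0.0, d2 = 0.0;
  for (int j = 0; j < p; ++j) {
    const double e1 = std::exp(z[j] * theta - m1);
    s1 += e1;
    d1 += z[j] * e1;
    if (cpen[j] > 0) {
      const double e2 = std::exp(std::log(cpen[j]) - z[j] * theta - m2);
      s2 += e2;
      d2 += -z[j] * e2;
    }
  }
  const double f = lam / p * std::exp(m1 + m2) * s1 * s2;
  if (grad) *grad = f * (d1 / s1 + d2 / s2);
  return f;
}

// Scalar theta step: gradient descent with backtracking from step t_init;
// golden-section fallback on [-clip, clip] if the gradient step stalls.
// Guarantees objective(theta_out) <= objective(theta_init).
// const_term is the theta-free part of the objective (NLL/n).
// [[Rcpp::export]]
double cpp_theta_step(const arma::vec& z, const arma::vec& cpen, double lam,
                      double theta_init, double t_init, double thresh,
                      double clip, double const_term) {
  double theta = std::max(-clip, std::min(clip, theta_init));
  double g = 0.0;
  double f = pen_of_theta(z, cpen, lam, theta, &g);
  if (f == 0.0) return theta;  // no active penalty: any theta equivalent
  bool stalled = false;
  for (int it = 0; it < 200; ++it) {
    double t = t_init;
    double theta_new = theta, f_new = f;
    bool ok = false;
    for (int h = 0; h < 60; ++h) {
      double cand = std::max(-clip, std::min(clip, theta - t * g));
      double fc = pen_of_theta(z, cpen, lam, cand, nullptr);
      if (fc < f - 1e-18) {
        theta_new = cand;
        f_new = fc;
        ok = true;
        break;
      }
      t *= 0.5;
    }
    if (!ok) {
      stalled = (it == 0);
      break;
    }
    const double obj_old = const_term + f;
    const double obj_new = const_term + f_new;
    theta = theta_new;
    f = f_new;
    pen_of_theta(z, cpen, lam, theta, &g);
    if (obj_old - obj_new < thresh * (std::fabs(obj_old) + 1e-12)) break;
  }
  if (stalled) {
    // golden-section search; log f is convex in theta so the minimum is global
    const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
    double a = -clip, b = clip;
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = pen_of_theta(z, cpen, lam, x1, nullptr);
    double f2 = pen_of_theta(z, cpen, lam, x2, nullptr);
    for (int it = 0; it < 120 && (b - a) > 1e-10; ++it) {
      if (f1 < f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = pen_of_theta(z, cpen, lam, x1, nullptr);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = pen_of_theta(z, cpen, lam, x2, nullptr);
      }
    }
    const double xm = 0.5 * (a + b);
    const double fm = pen_of_theta(z, cpen, lam, xm, nullptr);
    if (fm < f) theta = xm;
  }
  return theta;
}

static arma::vec cvec(const arma::vec& beta, double alpha) {
  arma::vec c(beta.n_elem);
  for (arma::uword j = 0; j < beta.n_elem; ++j)
    c[j] = alpha * std::fabs(beta[j]) + 0.5 * (1.0 - alpha) * beta[j] * beta[j];
  return c;
}

// Pathwise solver. X must already be standardized; lambda decreasing.
// Penalty-factor modes: z of length 0 => plain factors pf_fixed throughout;
// z given with alternate=true => pf = theta_weights(z, theta) with theta
// refit by alternation at each lambda; z given with alternate=false and
// theta_fixed of length L => pf = theta_weights(z, theta_fixed[k]) per
// lambda without alternation (used by CV folds, which re-estimate
// coefficients at the full-data tilt). The path stops early (after at least
// one lambda) when the deviance ratio exceeds dev_ratio_max or the
// fractional deviance gain drops below fdev (the pathwise-solver
// convention); n_lambda_used reports how many lambdas were actually fitted.
// [[Rcpp::export]]
List cpp_cox_path(const arma::mat& X, const arma::vec& delta,
                  const arma::uvec& ord, const arma::uvec& firsts,
                  const arma::uvec& lasts, double alpha,
                  const arma::vec& lambda, const arma::vec& pf_fixed,
                  const arma::vec& z, bool alternate, double theta_init,
                  double t_init, double theta_clip, double thresh,
                  int max_outer, int irls_maxit, double irls_tol,
                  double cd_tol, int cd_maxit, const arma::vec& beta_init,
                  double dev_ratio_max, double fdev,
                  const arma::vec& theta_fixed) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int L = lambda.n_elem;
  arma::mat betas(p, L, arma::fill::zeros);
  arma::vec thetas(L, arma::fill::zeros);
  arma::vec nlls(L, arma::fill::zeros), objs(L, arma::fill::zeros);
  IntegerVector outer_iters(L);
  List traces(L);
  int flag_maxit = 0;

  arma::vec beta = beta_init;
  arma::vec eta = X * beta;
  double theta = theta_init;
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  for (int j = 0; j < p; ++j)
    if (beta[j] != 0.0) { active.push_back(j); in_active[j] = 1; }
  std::vector<int> all_idx(p);
  for (int j = 0; j < p; ++j) all_idx[j] = j;

  const bool use_z = alternate && z.n_elem == (arma::uword)p;
  const bool use_frozen = !alternate && z.n_elem == (arma::uword)p &&
                          theta_fixed.n_elem == (arma::uword)L;
  const int n_events = (int)arma::accu(delta);
  const double nll0 =
      cox_working(arma::vec(n, arma::fill::zeros), ord, firsts, lasts, delta).nll;

  int L_used = 0;
  double dev_prev = 0.0;
  for (int k = 0; k < L; ++k) {
    const double lam = lambda[k];
    if (use_frozen) theta = theta_fixed[k];
    arma::vec pf = (use_z || use_frozen) ? theta_weights(z, theta) : pf_fixed;

    // sequential strong screen from the gradient at the previous solution
    CoxWork cw = cox_working(eta, ord, firsts, lasts, delta);
    arma::vec gb = X.t() * cw.g / n;
    const double lam_prev = (k == 0) ? lam : lambda[k - 1];
    std::vector<int> screened;
    screened.reserve(p);
    for (int j = 0; j < p; ++j) {
      if (in_active[j] ||
          std::fabs(gb[j]) >= alpha * pf[j] * (2.0 * lam - lam_prev) - 1e-12)
        screened.push_back(j);
    }

    std::vector<double> trace;
    double obj = 0.0;
    int outer = 0;
    if (n_events == 0) {
      beta.zeros();
      eta.zeros();
      obj = 0.0;
    } else {
      double obj_prev = std::numeric_limits<double>::infinity();
      const int max_o = use_z ? max_outer : 1;
      for (outer = 0; outer < max_o; ++outer) {
        obj = irls_solve(X, delta, ord, firsts, lasts, alpha, lam, pf, beta,
                         eta, active, in_active, screened, all_idx, cd_tol,
                         cd_maxit, irls_maxit, irls_tol, flag_maxit);
        if (use_z) {
          CoxWork cwc = cox_working(eta, ord, firsts, lasts, delta);
          const double theta_new =
              cpp_theta_step(z, cvec(beta, alpha), lam, theta, t_init, thresh,
                             theta_clip, cwc.nll / n);
          theta = theta_new;
          pf = theta_weights(z, theta);
          obj = cwc.nll / n + penalty_val(beta, pf, alpha, lam, active);
          // weights changed: stale screen could miss entrants; refresh
          arma::vec gb2 = X.t() * cwc.g / n;
          screened.clear();
          for (int j = 0; j < p; ++j) {
            if (in_active[j] || std::fabs(gb2[j]) >= alpha * pf[j] * lam - 1e-12)
              screened.push_back(j);
          }
        }
        trace.push_back(obj);
        if (obj_prev - obj < thresh * (std::fabs(obj_prev) + 1e-12) &&
            std::isfinite(obj_prev))
          break;
        obj_prev = obj;
      }
    }
    CoxWork cwf = cox_working(eta, ord, firsts, lasts, delta);
    betas.col(k) = beta;
    thetas[k] = theta;
    nlls[k] = cwf.nll;
    objs[k] = obj;
    outer_iters[k] = outer + 1;
    traces[k] = wrap(trace);
    L_used = k + 1;

    if (n_events > 0 && nll0 > 0 && k > 0) {
      const double dev = 2.0 * (nll0 - cwf.nll);
      if (dev / (2.0 * nll0) > dev_ratio_max) break;
      if (dev - dev_prev < fdev * dev && dev > 0) break;
      dev_prev = dev;
    }
  }
  return List::create(_["beta"] = betas, _["theta"] = thetas, _["nll"] = nlls,
                      _["objective"] = objs, _["outer_iters"] = outer_iters,
                      _["trace"] = traces, _["n_irls_maxed"] = flag_maxit,
                      _["n_lambda_used"] = L_used);
}
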
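// Left-truncated Cox partial likelihood (Efron ties, case weights),
// Breslow baseline increments, and the Aalen-Johansen product integral.
// Counting-process convention throughout: subject i is at risk at time t
// iff entry_i < t <= exit_i.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct CoxData {
  arma::vec entry, exit, status, w;
  arma::mat X;
  arma::uvec exit_desc;    // indices sorted by exit descending
  arma::uvec entry_desc;   // indices sorted by entry descending
  arma::vec etimes;        // unique event times, descending
  std::vector<std::vector<arma::uword>> deaths;  // death indices per etime
};

CoxData prepare(const arma::vec& entry, const arma::vec& exit,
                const arma::vec& status, const arma::mat& X,
                const arma::vec& w) {
  CoxData d;
  d.entry = entry; d.exit = exit; d.status = status; d.X = X; d.w = w;
  d.exit_desc = arma::sort_index(exit, "descend");
  d.entry_desc = arma::sort_index(entry, "descend");
  arma::uvec ev = arma::find(status > 0.5);
  arma::vec t = arma::unique(exit.elem(ev));  // ascending unique
  d.etimes = arma::reverse(t);                // descending
  d.deaths.resize(d.etimes.n_elem);
  // deaths grouped per event time via one sweep of the exit-sorted order
  arma::uword k = 0;
  for (arma::uword s = 0; s < d.exit_desc.n_elem; ++s) {
    arma::uword i = d.exit_desc(s);
    if (d.status(i) < 0.5) continue;
    while (k < d.etimes.n_elem && d.etimes(k) > d.exit(i)) ++k;
    d.deaths[k].push_back(i);
  }
  return d;
}

// One pass over the data: log partial likelihood and, if grad/info are
// non-null, the score vector and observed information (Efron, weighted).
// Hand-rolled accumulation (no armadillo temporaries): this is the hot
// loop of the bootstrap.
double cox_pass(const CoxData& d, const arma::vec& beta,
                arma::vec* grad, arma::mat* info, const bool efron = true) {
  const arma::uword n = d.X.n_rows, p = d.X.n_cols;
  arma::vec eta = p ? arma::vec(d.X * beta) : arma::zeros(n);
  arma::vec r = d.w % arma::exp(eta);
  const double* Xm = d.X.memptr();  // column-major, n x p

  double S0 = 0.0;
  std::vector<double> S1(p, 0.0), S2(p * p, 0.0);
  std::vector<double> Sd1(p), Sd2(p * p), R1(p), mu(p);
  double ll = 0.0;
  if (grad) grad->zeros(p);
  if (info) info->zeros(p, p);
  double* g = grad ? grad->memptr() : nullptr;
  double* H = info ? info->memptr() : nullptr;

  arma::uword ia = 0, ir = 0;  // pointers into exit_desc / entry_desc
  for (arma::uword k = 0; k < d.etimes.n_elem; ++k) {
    const double t = d.etimes(k);
    // add subjects with exit >= t
    while (ia < n && d.exit(d.exit_desc(ia)) >= t) {
      const arma::uword i = d.exit_desc(ia);
      const double ri = r(i);
      S0 += ri;
      for (arma::uword a = 0; a < p; ++a) {
        const double xa = Xm[a * n + i];
        S1[a] += ri * xa;
        for (arma::uword b = 0; b <= a; ++b)
          S2[a * p + b] += ri * xa * Xm[b * n + i];
      }
      ++ia;
    }
    // remove subjects whose entry >= t (not yet at risk at t)
    while (ir < n && d.entry(d.entry_desc(ir)) >= t) {
      const arma::uword i = d.entry_desc(ir);
      if (d.exit(i) >= t) {  // only remove what was added
        const double ri = r(i);
        S0 -= ri;
        for (arma::uword a = 0; a < p; ++a) {
          const double xa = Xm[a * n + i];
          S1[a] -= ri * xa;
          for (arma::uword b = 0; b <= a; ++b)
            S2[a * p + b] -= ri * xa * Xm[b * n + i];
        }
      }
      ++ir;
    }
    // deaths at t
    const std::vector<arma::uword>& D = d.deaths[k];
    const arma::uword m = D.size();
    double Sd0 = 0.0, wsum = 0.0;
    std::fill(Sd1.begin(), Sd1.end(), 0.0);
    std::fill(Sd2.begin(), Sd2.end(), 0.0);
    for (arma::uword jj = 0; jj < m; ++jj) {
      const arma::uword j = D[jj];
      const double rj = r(j);
      wsum += d.w(j);
      Sd0 += rj;
      for (arma::uword a = 0; a < p; ++a) {
        const double xa = Xm[a * n + j];
        Sd1[a] += rj * xa;
        for (arma::uword b = 0; b <= a; ++b)
          Sd2[a * p + b] += rj * xa * Xm[b * n + j];
      }
      ll += d.w(j) * eta(j);
      if (g)
        for (arma::uword a = 0; a < p; ++a) g[a] += d.w(j) * Xm[a * n + j];
    }
    const double wmean = wsum / m;
    for (arma::uword j = 0; j < m; ++j) {
      const double f = efron ? static_cast<double>(j) / m : 0.0;
      const double R0 = S0 - f * Sd0;
      ll -= wmean * std::log(R0);
      if (p && (g || H)) {
        for (arma::uword a = 0; a < p; ++a) {
          R1[a] = S1[a] - f * Sd1[a];
          mu[a] = R1[a] / R0;
        }
        if (g)
          for (arma::uword a = 0; a < p; ++a) g[a] -= wmean * mu[a];
        if (H)
          for (arma::uword a = 0; a < p; ++a)
            for (arma::uword b = 0; b <= a; ++b) {
              const double v =
                  wmean * ((S2[a * p + b] - f * Sd2[a * p + b]) / R0 -
                           mu[a] * mu[b]);
              H[a * p + b] += v;
            }
      }
    }
  }
  if (H)  // accumulation filled (row b <= col a); mirror into the rest
    for (arma::uword a = 0; a < p; ++a)
      for (arma::uword b = a + 1; b < p; ++b) H[a * p + b] = H[b * p + a];
  return ll;
}

}  // namespace

// [[Rcpp::export(name = ".cox_loglik_cpp")]]
double cox_loglik_cpp(const arma::vec& entry, const arma::vec& exit,
                      const arma::vec& status, const arma::mat& X,
                      const arma::vec& weights, const arma::vec& beta,
                      const bool efron) {
  CoxData d = prepare(entry, exit, status, X, weights);
  return cox_pass(d, beta, nullptr, nullptr, efron);
}

// [[Rcpp::export(name = ".cox_fit_cpp")]]
List cox_fit_cpp(const arma::vec& entry, const arma::vec& exit,
                 const arma::vec& status, const arma::mat& X,
                 const arma::vec& weights, const int max_iter,
                 const double tol, const bool efron) {
  CoxData d = prepare(entry, exit, status, X, weights);
  const arma::uword p = X.n_cols;
  arma::vec beta = arma::zeros(p);
  arma::vec grad(p);
  arma::mat info(p, p);

  double ll = cox_pass(d, beta, &grad, &info, efron);
  const double ll0 = ll;
  bool converged = false, singular = false;
  int iter = 0;

  for (iter = 0; iter < max_iter && p > 0; ++iter) {
    arma::vec step;
    bool ok = arma::solve(step, info, grad, arma::solve_opts::no_approx);
    if (!ok) {  // rank-deficient information: fall back to pseudo-inverse
      singular = true;
      arma::mat pi;
      if (!arma::pinv(pi, info)) break;
      step = pi * grad;
    }
    double llnew = 0.0;
    arma::vec bnew, gnew(p);
    arma::mat inew(p, p);
    int halv = 0;
    for (halv = 0; halv < 25; ++halv) {
      bnew = beta + step;
      llnew = cox_pass(d, bnew, &gnew, &inew, efron);
      if (std::isfinite(llnew) && llnew >= ll - 1e-12) break;
      step *= 0.5;
    }
    if (halv == 25) break;  // could not improve
    const bool done = std::abs(llnew - ll) < tol * (std::abs(ll) + 0.1);
    beta = bnew;
    ll = llnew;
    grad = gnew;
    info = inew;
    if (done) {
      converged = true; ++iter;
      // one polishing Newton step (quadratic convergence): pins the
      // optimum to near machine precision for the cross-check harness
      arma::vec extra;
      if (!singular &&
          arma::solve(extra, info, grad, arma::solve_opts::no_approx)) {
        beta += extra;
        ll = cox_pass(d, beta, &grad, &info, efron);
      }
      break;
    }
  }
  if (p == 0) converged = true;
  // monotone-likelihood / separation heuristic
  bool diverged = p > 0 && arma::abs(beta).max() > 20.0;
  if (diverged) converged = false;

  arma::mat vcov(p, p, arma::fill::zeros);
  if (p > 0) {
    arma::mat vi;
    if (arma::inv_sympd(vi, info)) vcov = vi;
    else if (arma::pinv(vi, info)) { vcov = vi; singular = true; }
  }
  return List::create(
      _["beta"] = beta, _["loglik"] = ll, _["loglik0"] = ll0,
      _["iter"] = iter, _["converged"] = converged,
      _["singular"] = singular, _["diverged"] = diverged,
      _["score"] = grad, _["imat"] = info, _["vcov"] = vcov);
}

// Breslow baseline cumulative-hazard increments at the reference profile.
// eta must already be centered at the reference: eta_j = beta'(x_j - x0).
// increment(t) = sum_{deaths at t} w_i / sum_{risk set at t} w_j exp(eta_j)
// [[Rcpp::export(name = ".breslow_cpp")]]
List breslow_cpp(const arma::vec& entry, const arma::vec& exit,
                 const arma::vec& status, const arma::vec& eta,
                 const arma::vec& weights) {
  const arma::uword n = exit.n_elem;
  arma::vec r = weights % arma::exp(eta);
  arma::uvec exit_desc = arma::sort_index(exit, "descend");
  arma::uvec entry_desc = arma::sort_index(entry, "descend");
  arma::uvec ev = arma::find(status > 0.5);
  arma::vec tasc = arma::unique(exit.elem(ev));
  arma::vec tdesc = arma::reverse(tasc);

  // death weight totals per event time, grouped in one sweep
  arma::vec dsum(tdesc.n_elem, arma::fill::zeros);
  {
    arma::uword k = 0;
    for (arma::uword s = 0; s < n; ++s) {
      arma::uword i = exit_desc(s);
      if (status(i) < 0.5) continue;
      while (k < tdesc.n_elem && tdesc(k) > exit(i)) ++k;
      dsum(k) += weights(i);
    }
  }

  arma::vec inc(tdesc.n_elem, arma::fill::zeros);
  double S0 = 0.0;
  arma::uword ia = 0, ir = 0;
  for (arma::uword k = 0; k < tdesc.n_elem; ++k) {
    const double t = tdesc(k);
    while (ia < n && exit(exit_desc(ia)) >= t) { S0 += r(exit_desc(ia)); ++ia; }
    while (ir < n && entry(entry_desc(ir)) >= t) {
      arma::uword i = entry_desc(ir);
      if (exit(i) >= t) S0 -= r(i);
      ++ir;
    }
    inc(k) = dsum(k) / S0;
  }
  return List::create(_["time"] = tasc, _["increment"] = arma::reverse(inc));
}

// Aalen-Johansen product integral for the irreversible illness-death model.
// States: 1 = event-free, 2 = alive with disease, 3 = dead.
// Inputs: a common ascending grid of jump ages with per-age increments
// dA12, dA13, dA23 (zero where a transition has no jump). Returns the five
// non-trivial entries of P(t0, t) after each jump plus a truncation count
// for rows whose off-diagonal increments summed above one.
// [[Rcpp::export(name = ".aj_cpp")]]
List aj_cpp(const arma::vec& times, arma::vec d12, arma::vec d13,
            arma::vec d23) {
  const arma::uword m = times.n_elem;
  arma::mat P = arma::eye(3, 3);
  arma::mat out(m, 5);
  int truncated = 0;
  for (arma::uword k = 0; k < m; ++k) {
    double a12 = d12(k), a13 = d13(k), a23 = d23(k);
    double row1 = a12 + a13;
    if (row1 > 1.0) { a12 /= row1; a13 /= row1; ++truncated; }
    if (a23 > 1.0) { a23 = 1.0; ++truncated; }
    arma::mat M = {{1.0 - a12 - a13, a12, a13},
                   {0.0, 1.0 - a23, a23},
                   {0.0, 0.0, 1.0}};
    P = P * M;
    out(k, 0) = P(0, 0); out(k, 1) = P(0, 1); out(k, 2) = P(0, 2);
    out(k, 3) = P(1, 1); out(k, 4) = P(1, 2);
  }
  return List::create(_["prob"] = out, _["truncated"] = truncated);
}
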
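// Hot paths of the dual-probe fitting routines: exponential-basis
// construction via symmetrized eigendecomposition of the compartment
// generator, the randomized column Kaczmarz-Tikhonov solver, and the
// profiled residual objectives evaluated inside the nonlinear searches.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generator over the active compartments (free first). The matrix is
// Metzler with reversible exchange edges, hence symmetrizable by
// D = diag(1, sqrt(ka/kd)) per edge; eig_sym then gives real eigenvalues
// and an orthogonal basis even at degenerate spectra.
//
// Returns basis of total-concentration curves: column j = total from a
// unit initial amount in active compartment j, under washout when
// washout_active. Exchange pairs with zero rates must be excluded by the
// caller (pass only active compartments via the k arguments > 0 or the
// 1-compartment fast path).
static mat total_basis(double Fw, const std::vector<double>& ka,
                       const std::vector<double>& kd, const vec& times) {
  const uword m = 1 + ka.size();
  if (m == 1) {
    mat B(times.n_elem, 1);
    B.col(0) = exp(-Fw * times);
    return B;
  }
  vec d(m);
  d(0) = 1.0;
  mat S(m, m, fill::zeros);
  double diag0 = -Fw;
  for (uword j = 1; j < m; ++j) {
    double a = ka[j - 1], b = kd[j - 1];
    d(j) = std::sqrt(a / b);
    double c = std::sqrt(a * b);
    S(0, j) = c;
    S(j, 0) = c;
    S(j, j) = -b;
    diag0 -= a;
  }
  S(0, 0) = diag0;
  vec lam;
  mat V;
  eig_sym(lam, V, S);
  // B[t,j] = sum_m u_m exp(lam_m t) W_{m j},  u = (d' V), W = V' * diag(1/d)
  rowvec u = (d.t() * V);
  mat W = V.t();
  for (uword j = 0; j < m; ++j) W.col(j) /= d(j);
  mat E(times.n_elem, m);
  for (uword k = 0; k < m; ++k) E.col(k) = exp(lam(k) * times);
  for (uword k = 0; k < m; ++k) E.col(k) *= u(k);
  return E * W;
}

// Compartment state after propagating a unit of free probe (no washout)
// for t minutes; returns the active-compartment state vector.
static vec stain_unit_state(const std::vector<double>& ka,
                            const std::vector<double>& kd, double t) {
  const uword m = 1 + ka.size();
  vec s(m, fill::zeros);
  if (m == 1) {
    s(0) = 1.0;
    return s;
  }
  vec d(m);
  d(0) = 1.0;
  mat S(m, m, fill::zeros);
  double diag0 = 0.0;
  for (uword j = 1; j < m; ++j) {
    double a = ka[j - 1], b = kd[j - 1];
    d(j) = std::sqrt(a / b);
    double c = std::sqrt(a * b);
    S(0, j) = c;
    S(j, 0) = c;
    S(j, j) = -b;
    diag0 -= a;
  }
  S(0, 0) = diag0;
  vec lam;
  mat V;
  eig_sym(lam, V, S);
  // exp(A t) e_1 = D V exp(L t) V' D^-1 e_1,  D^-1 e_1 = e_1
  vec w = V.t() * vec({1.0, 0.0, 0.0}).head(m);
  w %= exp(lam * t);
  vec st = V * w;
  st %= d;
  return st;
}

// Randomized column Kaczmarz with Tikhonov penalty; exact coordinate
// updates visited in a freshly shuffled order each sweep (mt19937 seeded
// deterministically). nonneg projects each update onto c_j >= 0.
static vec kaczmarz_core(const mat& B, const vec& y, double lambda,
                         int max_sweeps, double tol, unsigned int seed,
                         bool nonneg, bool* converged, int* sweeps_out,
                         double* resnorm) {
  const uword k = B.n_cols;
  vec csq = sum(square(B), 0).t();
  vec c(k, fill::zeros);
  vec r = y;
  std::mt19937 rng(seed);
  std::vector<uword> order(k);
  for (uword j = 0; j < k; ++j) order[j] = j;
  *converged = false;
  int s = 0;
  for (s = 1; s <= max_sweeps; ++s) {
    std::shuffle(order.begin(), order.end(), rng);
    double delta = 0.0, cmax = 1.0;
    for (uword idx = 0; idx < k; ++idx) {
      uword j = order[idx];
      if (csq(j) == 0.0) continue;
      vec rj = r + B.col(j) * c(j);
      double cj = dot(B.col(j), rj) / (csq(j) + lambda);
      if (nonneg && cj < 0.0) cj = 0.0;
      r = rj - B.col(j) * cj;
      delta = std::max(delta, std::fabs(cj - c(j)));
      c(j) = cj;
      cmax = std::max(cmax, std::fabs(cj));
    }
    if (delta <= tol * cmax) {
      *converged = true;
      break;
    }
  }
  *sweeps_out = std::min(s, max_sweeps);
  *resnorm = norm(r);
  return c;
}

// [[Rcpp::export(name = ".cpp_kaczmarz")]]
Rcpp::List cpp_kaczmarz(const arma::mat& B, const arma::vec& y, double lambda,
                        int max_sweeps, double tol, int seed, bool nonneg) {
  bool conv;
  int sweeps;
  double rn;
  vec c = kaczmarz_core(B, y, lambda, max_sweeps, tol,
                        static_cast<unsigned int>(seed), nonneg,
                        &conv, &sweeps, &rn);
  return Rcpp::List::create(Rcpp::Named("coef") = c,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("sweeps") = sweeps,
                            Rcpp::Named("residual_norm") = rn);
}

// Small dense NNLS by active-set enumeration (k <= 3 in the fits).
static vec nnls_small(const mat& B, const vec& y, double* rss) {
  const uword k = B.n_cols;
  vec best;
  double best_rss = datum::inf;
  const uword nsub = (1u << k);
  for (uword mask = 0; mask < nsub; ++mask) {
    uvec idx;
    for (uword j = 0; j < k; ++j)
      if (mask & (1u << j)) idx.insert_rows(idx.n_rows, uvec({j}));
    vec c(k, fill::zeros);
    if (idx.n_rows > 0) {
      mat Bs = B.cols(idx);
      vec cs;
      if (!solve(cs, Bs.t() * Bs, Bs.t() * y, solve_opts::no_approx)) continue;
      if (cs.min() < 0) continue;
      c.elem(idx) = cs;
    }
    double r = accu(square(y - B * c));
    if (r < best_rss) {
      best_rss = r;
      best = c;
    }
  }
  *rss = best_rss;
  return best;
}

// ---- Profiled residual objectives (rates -> rss with amplitudes solved) --

// Untargeted washout + nonspecific model, stain-anchored amplitudes:
// initial rinse state = C0 * stain_unit_state(k5,k6,stain_dur); C0 >= 0
// solved in closed form with ridge penalty (the 1-column Kaczmarz limit).
// [[Rcpp::export(name = ".cpp_obj_u_dpmns_stain")]]
Rcpp::List cpp_obj_u_dpmns_stain(double F, double k5, double k6,
                                 const arma::vec& times, const arma::vec& y,
                                 double stain_dur, double lambda_scale) {
  vec u0 = stain_unit_state({k5}, {k6}, stain_dur);
  mat B2 = total_basis(F, {k5}, {k6}, times);
  vec b = B2 * u0;                       // total curve per unit applied conc
  double bb = dot(b, b);
  double lambda = lambda_scale * bb;     // scale-free ridge on the one coef
  double c0 = dot(b, y) / (bb + lambda);
  if (c0 < 0) c0 = 0;
  vec r = y - b * c0;
  return Rcpp::List::create(Rcpp::Named("rss") = dot(r, r),
                            Rcpp::Named("scale") = c0,
                            Rcpp::Named("state") = c0 * u0);
}

// Untargeted model with free non-negative amplitudes (biexponential basis,
// Kaczmarz-Tikhonov solve). Retained as the literal free-amplitude variant.
// [[Rcpp::export(name = ".cpp_obj_u_dpmns_free")]]
Rcpp::List cpp_obj_u_dpmns_free(double F, double k5, double k6,
                                const arma::vec& times, const arma::vec& y,
                                double lambda, int max_sweeps, double tol,
                                int seed) {
  mat B = total_basis(F, {k5}, {k6}, times);
  double lam = lambda >= 0 ? lambda : 1e-4 * accu(square(B)) / B.n_cols;
  bool conv;
  int sweeps;
  double rn;
  vec c = kaczmarz_core(B, y, lam, max_sweeps, tol, seed, true,
                        &conv, &sweeps, &rn);
  vec r = y - B * c;
  return Rcpp::List::create(Rcpp::Named("rss") = dot(r, r),
                            Rcpp::Named("coef") = c,
                            Rcpp::Named("converged") = conv);
}

// Targeted two-compartment model (free + specific), F fixed, free
// non-negative amplitudes by exact small NNLS.
// [[Rcpp::export(name = ".cpp_obj_t_dpm")]]
Rcpp::List cpp_obj_t_dpm(double k3, double k4, double F,
                         const arma::vec& times, const arma::vec& y) {
  mat B = total_basis(F, {k3}, {k4}, times);
  double rss;
  vec c = nnls_small(B, y, &rss);
  return Rcpp::List::create(Rcpp::Named("rss") = rss,
                            Rcpp::Named("coef") = c);
}

// Targeted three-compartment model, (F,k5,k6) fixed, stain-anchored
// amplitudes: initial rinse state = C0 * stain_unit_state(k3,k5,...);
// the scale C0 >= 0 is the 1-column Kaczmarz-Tikhonov solution.
// [[Rcpp::export(name = ".cpp_obj_t_dpmns_stain")]]
Rcpp::List cpp_obj_t_dpmns_stain(double k3, double k4, double F, double k5,
                                 double k6, const arma::vec& times,
                                 const arma::vec& y, double stain_dur,
                                 double lambda_scale) {
  vec u0 = stain_unit_state({k3, k5}, {k4, k6}, stain_dur);
  mat B = total_basis(F, {k3, k5}, {k4, k6}, times);
  vec b = B * u0;
  double bb = dot(b, b);
  double lambda = lambda_scale * bb;
  double c0 = dot(b, y) / (bb + lambda);
  if (c0 < 0) c0 = 0;
  vec r = y - b * c0;
  return Rcpp::List::create(Rcpp::Named("rss") = dot(r, r),
                            Rcpp::Named("scale") = c0,
                            Rcpp::Named("state") = c0 * u0);
}

// Targeted three-compartment model, (F,k5,k6) fixed, triexponential basis
// with free non-negative Kaczmarz-Tikhonov amplitudes.
// [[Rcpp::export(name = ".cpp_obj_t_dpmns")]]
Rcpp::List cpp_obj_t_dpmns(double k3, double k4, double F, double k5,
                           double k6, const arma::vec& times,
                           const arma::vec& y, double lambda, int max_sweeps,
                           double tol, int seed) {
  mat B = total_basis(F, {k3, k5}, {k4, k6}, times);
  double lam = lambda >= 0 ? lambda : 1e-4 * accu(square(B)) / B.n_cols;
  bool conv;
  int sweeps;
  double rn;
  vec c = kaczmarz_core(B, y, lam, max_sweeps, tol, seed, true,
                        &conv, &sweeps, &rn);
  vec r = y - B * c;
  return Rcpp::List::create(Rcpp::Named("rss") = dot(r, r),
                            Rcpp::Named("coef") = c,
                            Rcpp::Named("converged") = conv);
}

// Exposed for cross-checking the R-side eigen solution path in tests.
// [[Rcpp::export(name = ".cpp_total_basis")]]
arma::mat cpp_total_basis(double F, Rcpp::NumericVector ka,
                          Rcpp::NumericVector kd, const arma::vec& times) {
  std::vector<double> a = Rcpp::as<std::vector<double>>(ka);
  std::vector<double> d = Rcpp::as<std::vector<double>>(kd);
  return total_basis(F, a, d, times);
}

// [[Rcpp::export(name = ".cpp_stain_unit_state")]]
arma::vec cpp_stain_unit_state(Rcpp::NumericVector ka, Rcpp::NumericVector kd,
                               double t) {
  std::vector<double> a = Rcpp::as<std::vector<double>>(ka);
  std::vector<double> d = Rcpp::as<std::vector<double>>(kd);
  return stain_unit_state(a, d, t);
}
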
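// Exact LP / binary-MILP solver used for FBA, FVA and minimal-network
// enumeration. Bounded-variable revised simplex (Dantzig pricing with a
// Bland anti-cycling fallback, two phases) plus depth-first branch-and-bound
// over binary variables with parent-basis warm starts. Problem sizes in this
// package are small (tens to a few hundred variables), so the simplex
// refactorises the basis densely at every iteration for numerical
// robustness rather than maintaining an incremental inverse.

#include <RcppArmadillo.h>
#include <chrono>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-9;      // reduced-cost tolerance
static const double PIVTOL = 1e-7;   // minimum pivot magnitude
static const double FEAS = 1e-7;     // phase-1 feasibility tolerance
static const double INTTOL = 1e-6;   // integrality tolerance

enum VarState { BASIC = 0, AT_LB = 1, AT_UB = 2, NB_FREE = 3 };

struct LP {
  mat A;          // m x n, equality form A x = b
  vec b, c, lb, ub;
};

struct Basis {
  std::vector<int> state;
  uvec basis;
  bool valid = false;
};

struct LPOut {
  int status;     // 0 optimal, 1 infeasible, 2 unbounded, 3 iter limit
  double obj;
  vec x;
};

// value of a nonbasic variable given its state
static inline double nbval(int st, double l, double u) {
  if (st == AT_LB) return l;
  if (st == AT_UB) return u;
  return 0.0; // free nonbasic
}

// Solve B y = r and B^T z = s from one LU factorisation of the basis.
struct BasisLU {
  mat L, U;
  mat P;
  bool ok;
  void factor(const mat &B) {
    ok = lu(L, U, P, B);
    if (ok && U.n_rows > 0) {
      vec d = abs(U.diag());
      if (d.min() < 1e-11 * std::max(1.0, d.max())) ok = false;
    }
  }
  bool solveB(const vec &r, vec &y) const {
    // B = P^T L U  =>  L U y' = P r, y = y'
    vec t;
    if (!solve(t, trimatl(L), P * r)) return false;
    return solve(y, trimatu(U), t);
  }
  bool solveBt(const vec &s, vec &z) const {
    // B^T = U^T L^T P : U^T w = s ; L^T u = w ; z = P^T u
    vec w, u;
    if (!solve(w, trimatl(U.t()), s)) return false;
    if (!solve(u, trimatu(L.t()), w)) return false;
    z = P.t() * u;
    return true;
  }
};

// Bounded simplex on min c'x s.t. A x = b, lb <= x <= ub, starting from the
// given basis/state (modified in place). Dantzig pricing; switches to
// Bland's rule after `blandAfter` iterations to guarantee termination.
static int simplex_core(const mat &A, const vec &b, const vec &c,
                        const vec &lb, const vec &ub,
                        std::vector<int> &state, uvec &basis,
                        vec &x, int maxit, int blandAfter = 800) {
  const uword m = A.n_rows, n = A.n_cols;
  BasisLU f;
  for (int it = 0; it < maxit; ++it) {
    bool bland = it >= blandAfter;
    mat B = A.cols(basis);
    f.factor(B);
    if (!f.ok) return 1;
    // basic solution
    vec rhs = b;
    for (uword j = 0; j < n; ++j)
      if (state[j] != BASIC) {
        double v = nbval(state[j], lb[j], ub[j]);
        if (v != 0.0) rhs -= A.col(j) * v;
      }
    vec xB;
    if (!f.solveB(rhs, xB)) return 1;
    x.zeros(n);
    for (uword j = 0; j < n; ++j)
      if (state[j] != BASIC) x[j] = nbval(state[j], lb[j], ub[j]);
    for (uword i = 0; i < m; ++i) x[basis[i]] = xB[i];

    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = c[basis[i]];
    vec pi;
    if (!f.solveBt(cB, pi)) return 1;

    // entering variable
    sword q = -1; int dir = 0; double bestScore = EPS;
    for (uword j = 0; j < n; ++j) {
      if (state[j] == BASIC) continue;
      if (lb[j] == ub[j]) continue; // fixed
      double d = c[j] - dot(pi, A.col(j));
      double score = 0; int dd = 0;
      if (state[j] == AT_LB && d < -EPS) { score = -d; dd = +1; }
      else if (state[j] == AT_UB && d > EPS) { score = d; dd = -1; }
      else if (state[j] == NB_FREE && std::fabs(d) > EPS) {
        score = std::fabs(d); dd = (d < 0) ? +1 : -1;
      } else continue;
      if (bland) { q = j; dir = dd; break; }        // smallest index
      if (score > bestScore) { bestScore = score; q = j; dir = dd; }
    }
    if (q < 0) return 0; // optimal

    vec w;
    if (!f.solveB(A.col((uword)q), w)) return 1;

    // ratio test: x_q moves by t*dir, basics move by -t*dir*w.
    // Only elements above the pivot tolerance may block (or pivot); among
    // near-tied ratios prefer the largest pivot magnitude for stability
    // (smallest variable index in Bland mode).
    double tmax = std::numeric_limits<double>::infinity();
    sword leave = -1;          // index into basis, -1 = bound flip
    double span = ub[q] - lb[q];
    if (std::isfinite(span)) tmax = span;
    for (uword i = 0; i < m; ++i) {
      double g = dir * w[i];
      double t;
      uword bi = basis[i];
      if (g > PIVTOL) {
        if (!std::isfinite(lb[bi])) continue;
        t = (xB[i] - lb[bi]) / g;
      } else if (g < -PIVTOL) {
        if (!std::isfinite(ub[bi])) continue;
        t = (ub[bi] - xB[i]) / (-g);
      } else continue;
      if (t < -1e-11) t = 0;
      bool take = false;
      if (t < tmax - 1e-11) take = true;
      else if (t < tmax + 1e-11 && leave >= 0) {
        if (bland) take = bi < basis[leave];
        else take = std::fabs(w[i]) > std::fabs(w[leave]);
      }
      if (take) { tmax = t; leave = i; }
    }
    if (!std::isfinite(tmax)) return 2; // unbounded

    if (leave < 0) {
      // bound flip of the entering variable
      state[q] = (state[q] == AT_LB) ? AT_UB : AT_LB;
    } else {
      uword lv = basis[leave];
      double g = dir * w[leave];
      state[lv] = (g > 0) ? AT_LB : AT_UB;
      if (!std::isfinite(nbval(state[lv], lb[lv], ub[lv]))) state[lv] = NB_FREE;
      basis[leave] = (uword)q;
      state[q] = BASIC;
    }
  }
  return 3; // iteration limit
}

// try to resume from a stored basis: recompute basic values under the
// (possibly changed) bounds; usable when they remain within bounds
static bool warm_feasible(const mat &A, const vec &b, const vec &lb,
                          const vec &ub, std::vector<int> &state,
                          const uvec &basis) {
  const uword m = A.n_rows, n = A.n_cols;
  // nonbasic states must sit on existing finite bounds
  for (uword j = 0; j < n; ++j) {
    if (state[j] == AT_LB && !std::isfinite(lb[j])) return false;
    if (state[j] == AT_UB && !std::isfinite(ub[j])) return false;
    if (state[j] == AT_LB && lb[j] == ub[j]) continue;
    if (state[j] == AT_UB && lb[j] == ub[j]) state[j] = AT_LB;
  }
  mat B = A.cols(basis);
  BasisLU f;
  f.factor(B);
  if (!f.ok) return false;
  vec rhs = b;
  for (uword j = 0; j < n; ++j)
    if (state[j] != BASIC) {
      double v = nbval(state[j], lb[j], ub[j]);
      if (v != 0.0) rhs -= A.col(j) * v;
    }
  vec xB;
  if (!f.solveB(rhs, xB)) return false;
  for (uword i = 0; i < m; ++i) {
    uword bi = basis[i];
    if (xB[i] < lb[bi] - FEAS || xB[i] > ub[bi] + FEAS) return false;
  }
  return true;
}

// Two-phase solve of an equality-form LP; optionally warm-started from and
// reporting a basis.
static LPOut lp_equalform(const LP &p, int maxit, Basis *warm = nullptr,
                          Basis *out = nullptr) {
  const uword m = p.A.n_rows, n = p.A.n_cols;
  LPOut o; o.status = 1; o.obj = NA_REAL;

  if (warm && warm->valid && warm->basis.n_elem == m &&
      warm->state.size() == n) {
    std::vector<int> state = warm->state;
    uvec basis = warm->basis;
    if (warm_feasible(p.A, p.b, p.lb, p.ub, state, basis)) {
      vec x;
      int st = simplex_core(p.A, p.b, p.c, p.lb, p.ub, state, basis, x,
                            maxit);
      if (st == 0) {
        o.status = 0;
        o.x = x;
        for (uword j = 0; j < n; ++j) {
          if (std::isfinite(p.lb[j]) && o.x[j] < p.lb[j]) o.x[j] = p.lb[j];
          if (std::isfinite(p.ub[j]) && o.x[j] > p.ub[j]) o.x[j] = p.ub[j];
        }
        o.obj = dot(p.c, o.x);
        if (out) { out->state = state; out->basis = basis; out->valid = true; }
        return o;
      }
      if (st == 2) { o.status = 2; return o; }
      // fall through to a cold start on iteration trouble
    }
  }

  // cold start: each structural var at a finite bound (or free at 0),
  // artificials basic
  std::vector<int> state(n + m);
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(p.lb[j])) state[j] = AT_LB;
    else if (std::isfinite(p.ub[j])) state[j] = AT_UB;
    else state[j] = NB_FREE;
  }
  vec x0(n);
  for (uword j = 0; j < n; ++j) x0[j] = nbval(state[j], p.lb[j], p.ub[j]);
  vec resid = p.b - p.A * x0;

  mat A2(m, n + m, fill::zeros);
  A2.cols(0, n - 1) = p.A;
  vec lb2(n + m), ub2(n + m), c1(n + m, fill::zeros), c2(n + m, fill::zeros);
  lb2.subvec(0, n - 1) = p.lb; ub2.subvec(0, n - 1) = p.ub;
  c2.subvec(0, n - 1) = p.c;
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    A2(i, n + i) = (resid[i] >= 0) ? 1.0 : -1.0;
    lb2[n + i] = 0.0;
    ub2[n + i] = std::numeric_limits<double>::infinity();
    c1[n + i] = 1.0;
    basis[i] = n + i;
    state[n + i] = BASIC;
  }

  vec x;
  int st = simplex_core(A2, p.b, c1, lb2, ub2, state, basis, x, maxit);
  if (st == 3) { o.status = 3; return o; }
  if (st != 0) { o.status = st; return o; }
  double art = 0;
  for (uword i = 0; i < m; ++i) art += x[n + i];
  if (art > FEAS) { o.status = 1; return o; }

  // phase 2: freeze artificials at zero
  for (uword i = 0; i < m; ++i) { lb2[n + i] = 0.0; ub2[n + i] = 0.0; }
  st = simplex_core(A2, p.b, c2, lb2, ub2, state, basis, x, maxit);
  if (st != 0) { o.status = st; return o; }
  o.status = 0;
  o.x = x.subvec(0, n - 1);
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(p.lb[j]) && o.x[j] < p.lb[j]) o.x[j] = p.lb[j];
    if (std::isfinite(p.ub[j]) && o.x[j] > p.ub[j]) o.x[j] = p.ub[j];
  }
  o.obj = dot(p.c, o.x);
  if (out) {
    // report the basis in structural-variable space when it contains no
    // artificial (otherwise leave the warm start invalid)
    bool clean = true;
    for (uword i = 0; i < m; ++i) if (basis[i] >= n) { clean = false; break; }
    if (clean) {
      out->state.assign(state.begin(), state.begin() + n);
      out->basis = basis;
      out->valid = true;
    } else out->valid = false;
  }
  return o;
}

// Convert sense rows (-1 '<=', 0 '=', 1 '>=') to equality form with slacks.
static LP make_equalform(const mat &A, const ivec &sense, const vec &b,
                         const vec &c, const vec &lb, const vec &ub) {
  const uword m = A.n_rows, n = A.n_cols;
  uword ns = 0;
  for (uword i = 0; i < m; ++i) if (sense[i] != 0) ++ns;
  LP p;
  p.A.set_size(m, n + ns); p.A.zeros();
  p.A.cols(0, n - 1) = A;
  p.b = b;
  p.c.set_size(n + ns); p.c.zeros(); p.c.subvec(0, n - 1) = c;
  p.lb.set_size(n + ns); p.ub.set_size(n + ns);
  p.lb.subvec(0, n - 1) = lb; p.ub.subvec(0, n - 1) = ub;
  uword k = n;
  for (uword i = 0; i < m; ++i) {
    if (sense[i] == 0) continue;
    p.A(i, k) = (sense[i] < 0) ? 1.0 : -1.0;
    p.lb[k] = 0.0; p.ub[k] = std::numeric_limits<double>::infinity();
    ++k;
  }
  return p;
}

// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::vec &c, const arma::mat &A,
                        const arma::ivec &sense, const arma::vec &b,
                        const arma::vec &lb, const arma::vec &ub,
                        int maxit = 20000) {
  LP p = make_equalform(A, sense, b, c, lb, ub);
  LPOut o = lp_equalform(p, maxit);
  Rcpp::NumericVector xr;
  if (o.status == 0)
    xr = Rcpp::NumericVector(o.x.begin(), o.x.begin() + A.n_cols);
  return Rcpp::List::create(Rcpp::Named("status") = o.status,
                            Rcpp::Named("obj") = o.obj,
                            Rcpp::Named("x") = xr);
}

// Branch-and-bound over binary variables, DFS, deterministic order:
// branch on the lowest-index fractional binary, explore the 1-branch first.
// Each node attempts a warm start from its parent's optimal basis.
// [[Rcpp::export(name = ".milp_solve_cpp")]]
Rcpp::List milp_solve_cpp(const arma::vec &c, const arma::mat &A,
                          const arma::ivec &sense, const arma::vec &b,
                          const arma::vec &lb, const arma::vec &ub,
                          const arma::uvec &binary, // 1-based indices
                          double time_limit = 1e9,
                          bool obj_integral = true,
                          int maxit = 20000) {
  using clock = std::chrono::steady_clock;
  auto t0 = clock::now();
  const uword n = A.n_cols;
  uvec bin = binary - 1;

  struct Node { vec lb, ub; Basis warm; };
  std::vector<Node> stack;
  stack.push_back(Node{lb, ub, Basis()});

  double best = std::numeric_limits<double>::infinity();
  vec bestx;
  bool have = false, proven = true;
  long nodes = 0;

  LP p0 = make_equalform(A, sense, b, c, lb, ub);

  while (!stack.empty()) {
    if (std::chrono::duration<double>(clock::now() - t0).count() > time_limit) {
      proven = false;
      break;
    }
    Node nd = std::move(stack.back()); stack.pop_back();
    ++nodes;
    LP p = p0;
    p.lb.subvec(0, n - 1) = nd.lb;
    p.ub.subvec(0, n - 1) = nd.ub;
    Basis outB;
    LPOut o = lp_equalform(p, maxit, &nd.warm, &outB);
    if (o.status != 0) continue; // infeasible (or failed) node: prune
    double bound = o.obj;
    if (obj_integral) bound = std::ceil(bound - 1e-6);
    if (have && bound >= best - 1e-9) continue;

    // find fractional binary
    sword frac = -1;
    for (uword k = 0; k < bin.n_elem; ++k) {
      double v = o.x[bin[k]];
      if (std::fabs(v - std::round(v)) > INTTOL) { frac = bin[k]; break; }
    }
    if (frac < 0) {
      if (o.obj < best - 1e-9) {
        best = o.obj; bestx = o.x; have = true;
      }
      continue;
    }
    Node n0, n1;
    n0.lb = nd.lb; n0.ub = nd.ub; n0.warm = outB;
    n1.lb = nd.lb; n1.ub = nd.ub; n1.warm = outB;
    n0.ub[frac] = 0.0; n0.lb[frac] = 0.0;
    n1.lb[frac] = 1.0; n1.ub[frac] = 1.0;
    stack.push_back(std::move(n0));   // popped second
    stack.push_back(std::move(n1));   // popped first: dive to a support
  }

  int status;
  if (have && proven) status = 0;
  else if (have) status = 3;           // incumbent, time limit hit
  else if (proven) status = 1;         // exhausted tree, no solution
  else status = 4;                     // time limit, no incumbent
  Rcpp::NumericVector xr;
  if (have) {
    for (uword k = 0; k < bin.n_elem; ++k)
      bestx[bin[k]] = std::round(bestx[bin[k]]);
    xr = Rcpp::NumericVector(bestx.begin(), bestx.begin() + n);
  }
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("obj") = have ? best : NA_REAL,
                            Rcpp::Named("x") = xr,
                            Rcpp::Named("nodes") = (double)nodes);
}
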
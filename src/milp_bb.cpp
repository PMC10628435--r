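// Branch-and-bound mixed integer linear programming solver over a dense
// two-phase primal simplex. Problems in this package are small (a few hundred
// variables and rows, all coefficients small integers), so a dense tableau
// with Dantzig pricing (switching to Bland's rule after an iteration budget,
// which guarantees termination) is adequate and fully deterministic.
//
// min/max c'x  s.t.  A x {<=,=,>=} b,  lb <= x <= ub,  x_j integer for j in I.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <chrono>

using namespace Rcpp;

static const double FEAS_TOL = 1e-7;
static const double INT_TOL = 1e-6;
static const double PIV_TOL = 1e-9;

enum LPStatus { LP_OPTIMAL = 0, LP_INFEASIBLE = 1, LP_ITERLIMIT = 2 };

// Dense simplex on: min c'y, rows: sum a_ij y_j {<=,=,>=} b_i, y >= 0.
// Returns status; on optimal fills y and obj.
static int simplex_solve(const std::vector<double>& c,
                         const std::vector<std::vector<double> >& A,
                         const std::vector<int>& sense,
                         const std::vector<double>& b,
                         int n, std::vector<double>& y, double& obj,
                         long& iter_budget) {
  int m = (int)A.size();
  // column layout: [0,n) structural, then one slack/surplus per <=|>= row,
  // then one artificial per >=|= row.
  int n_slack = 0, n_art = 0;
  // copy rows, flip so rhs >= 0
  std::vector<std::vector<double> > R(m, std::vector<double>(n, 0.0));
  std::vector<double> rhs(m);
  std::vector<int> sen(m);
  for (int i = 0; i < m; ++i) {
    double bi = b[i];
    int s = sense[i];
    if (bi < 0) {
      for (int j = 0; j < n; ++j) R[i][j] = -A[i][j];
      rhs[i] = -bi;
      sen[i] = -s;
    } else {
      R[i] = A[i];
      rhs[i] = bi;
      sen[i] = s;
    }
  }
  std::vector<int> slack_col(m, -1), art_col(m, -1);
  for (int i = 0; i < m; ++i) {
    if (sen[i] != 0) n_slack++;
  }
  for (int i = 0; i < m; ++i) {
    if (sen[i] != -1) n_art++; // >= and = rows get artificials
  }
  int ncol = n + n_slack + n_art;
  // tableau: m rows x (ncol + 1); last col rhs
  std::vector<std::vector<double> > T(m, std::vector<double>(ncol + 1, 0.0));
  std::vector<int> basis(m, -1);
  int sc = n, ac = n + n_slack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = R[i][j];
    T[i][ncol] = rhs[i];
    if (sen[i] == -1) {           // <=  : slack basic
      slack_col[i] = sc; T[i][sc] = 1.0; basis[i] = sc; sc++;
    } else if (sen[i] == 1) {     // >=  : surplus + artificial
      slack_col[i] = sc; T[i][sc] = -1.0; sc++;
      art_col[i] = ac; T[i][ac] = 1.0; basis[i] = ac; ac++;
    } else {                      // =   : artificial
      art_col[i] = ac; T[i][ac] = 1.0; basis[i] = ac; ac++;
    }
  }
  int art_start = n + n_slack;

  // price out with objective row: objrow[j] = cost_j - sum_i cost_basis(i)*T[i][j]
  std::vector<double> objrow(ncol + 1, 0.0);

  // generic pivot loop; phase: 1 or 2
  // allow_col[j]: whether column may enter
  std::vector<char> allow(ncol, 1);

  // lambda-free helper via local struct
  struct Pivoter {
    std::vector<std::vector<double> >& T;
    std::vector<double>& objrow;
    std::vector<int>& basis;
    int m, ncol;
    long& budget;
    Pivoter(std::vector<std::vector<double> >& T_, std::vector<double>& o_,
            std::vector<int>& b_, int m_, int nc_, long& bud)
      : T(T_), objrow(o_), basis(b_), m(m_), ncol(nc_), budget(bud) {}
    // returns 0 optimal, 2 iteration limit (treated as numeric failure)
    int run(const std::vector<char>& allow) {
      long iter = 0;
      long bland_after = 3L * (m + ncol) + 200;
      while (true) {
        if (budget-- <= 0) return LP_ITERLIMIT;
        // entering column
        int col = -1;
        if (iter < bland_after) {
          double best = -1e-9;
          for (int j = 0; j < ncol; ++j)
            if (allow[j] && objrow[j] < best - PIV_TOL) { best = objrow[j]; col = j; }
        } else { // Bland
          for (int j = 0; j < ncol; ++j)
            if (allow[j] && objrow[j] < -1e-9) { col = j; break; }
        }
        if (col < 0) return LP_OPTIMAL;
        // ratio test
        int prow = -1; double bestRatio = std::numeric_limits<double>::infinity();
        for (int i = 0; i < m; ++i) {
          double a = T[i][col];
          if (a > PIV_TOL) {
            double ratio = T[i][ncol] / a;
            if (ratio < bestRatio - 1e-12 ||
                (ratio < bestRatio + 1e-12 && (prow < 0 || basis[i] < basis[prow]))) {
              bestRatio = ratio; prow = i;
            }
          }
        }
        if (prow < 0) return LP_OPTIMAL; // unbounded direction; cannot occur
                                         // with explicit upper-bound rows, but
                                         // fail safe as "no improving pivot"
        // pivot
        double piv = T[prow][col];
        std::vector<double>& Pr = T[prow];
        double inv = 1.0 / piv;
        for (int j = 0; j <= ncol; ++j) Pr[j] *= inv;
        for (int i = 0; i < m; ++i) {
          if (i == prow) continue;
          double f = T[i][col];
          if (std::fabs(f) > PIV_TOL) {
            std::vector<double>& Ri = T[i];
            for (int j = 0; j <= ncol; ++j) Ri[j] -= f * Pr[j];
          }
        }
        double f = objrow[col];
        if (std::fabs(f) > PIV_TOL)
          for (int j = 0; j <= ncol; ++j) objrow[j] -= f * Pr[j];
        basis[prow] = col;
        iter++;
      }
    }
  } pivoter(T, objrow, basis, m, ncol, iter_budget);

  // ---- Phase 1: minimize sum of artificials
  bool have_art = n_art > 0;
  if (have_art) {
    std::fill(objrow.begin(), objrow.end(), 0.0);
    for (int j = art_start; j < ncol; ++j) objrow[j] = 1.0;
    // price out basic artificials
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= art_start) {
        for (int j = 0; j <= ncol; ++j) objrow[j] -= T[i][j];
      }
    }
    int st = pivoter.run(allow);
    if (st == LP_ITERLIMIT) return LP_ITERLIMIT;
    // phase-1 objective value = -objrow[ncol]
    double p1 = -objrow[ncol];
    if (p1 > 1e-6) return LP_INFEASIBLE;
    // drive artificials out of the basis
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= art_start) {
        int col = -1;
        for (int j = 0; j < art_start; ++j)
          if (std::fabs(T[i][j]) > 1e-7) { col = j; break; }
        if (col >= 0) {
          double piv = T[i][col];
          double inv = 1.0 / piv;
          for (int j = 0; j <= ncol; ++j) T[i][j] *= inv;
          for (int r = 0; r < m; ++r) {
            if (r == i) continue;
            double f = T[r][col];
            if (std::fabs(f) > PIV_TOL)
              for (int j = 0; j <= ncol; ++j) T[r][j] -= f * T[i][j];
          }
          basis[i] = col;
        } else {
          // redundant row: zero it out; it stays inert
          for (int j = 0; j <= ncol; ++j) T[i][j] = 0.0;
          if (art_col[i] >= 0) T[i][art_col[i]] = 1.0; // artificial basic at 0
        }
      }
    }
    for (int j = art_start; j < ncol; ++j) allow[j] = 0;
  }

  // ---- Phase 2
  std::fill(objrow.begin(), objrow.end(), 0.0);
  for (int j = 0; j < n; ++j) objrow[j] = c[j];
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    if (bj >= 0 && bj < n && std::fabs(c[bj]) > 0) {
      double cb = c[bj];
      for (int j = 0; j <= ncol; ++j) objrow[j] -= cb * T[i][j];
    }
  }
  int st = pivoter.run(allow);
  if (st == LP_ITERLIMIT) return LP_ITERLIMIT;

  y.assign(n, 0.0);
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    if (bj >= 0 && bj < n) y[bj] = T[i][ncol];
  }
  obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * y[j];
  return LP_OPTIMAL;
}

// Solve the LP relaxation of the node defined by bounds lo/hi.
// Fixed variables (lo == hi) are eliminated. Upper bounds become rows.
static int lp_relaxation(const std::vector<double>& cmin,
                         const std::vector<std::vector<double> >& A,
                         const std::vector<int>& sense,
                         const std::vector<double>& b,
                         const std::vector<double>& lo,
                         const std::vector<double>& hi,
                         std::vector<double>& x, double& obj,
                         long& iter_budget) {
  int n = (int)cmin.size();
  int m = (int)A.size();
  for (int j = 0; j < n; ++j) if (hi[j] < lo[j] - 1e-9) return LP_INFEASIBLE;
  // active (non-fixed) variables
  std::vector<int> act;
  act.reserve(n);
  for (int j = 0; j < n; ++j) if (hi[j] - lo[j] > 1e-12) act.push_back(j);
  int na = (int)act.size();
  // shifted problem in y = x_act - lo_act
  std::vector<double> c2(na);
  for (int q = 0; q < na; ++q) c2[q] = cmin[act[q]];
  std::vector<std::vector<double> > A2;
  std::vector<int> s2;
  std::vector<double> b2;
  A2.reserve(m + na); s2.reserve(m + na); b2.reserve(m + na);
  for (int i = 0; i < m; ++i) {
    double shift = 0.0;
    for (int j = 0; j < n; ++j) shift += A[i][j] * lo[j];
    std::vector<double> row(na, 0.0);
    bool nz = false;
    for (int q = 0; q < na; ++q) {
      row[q] = A[i][act[q]];
      if (std::fabs(row[q]) > 0) nz = true;
    }
    double bi = b[i] - shift;
    if (!nz) { // row fully fixed: check consistency
      if (sense[i] == -1 && bi < -FEAS_TOL) return LP_INFEASIBLE;
      if (sense[i] == 1 && bi > FEAS_TOL) return LP_INFEASIBLE;
      if (sense[i] == 0 && std::fabs(bi) > FEAS_TOL) return LP_INFEASIBLE;
      continue;
    }
    A2.push_back(row); s2.push_back(sense[i]); b2.push_back(bi);
  }
  // upper-bound rows for active vars with finite range
  for (int q = 0; q < na; ++q) {
    double range = hi[act[q]] - lo[act[q]];
    if (range < std::numeric_limits<double>::infinity()) {
      std::vector<double> row(na, 0.0);
      row[q] = 1.0;
      A2.push_back(row); s2.push_back(-1); b2.push_back(range);
    }
  }
  std::vector<double> y;
  double o2 = 0.0;
  int st = simplex_solve(c2, A2, s2, b2, na, y, o2, iter_budget);
  if (st != LP_OPTIMAL) return st;
  x.assign(n, 0.0);
  for (int j = 0; j < n; ++j) x[j] = lo[j];
  for (int q = 0; q < na; ++q) x[act[q]] = lo[act[q]] + y[q];
  obj = 0.0;
  for (int j = 0; j < n; ++j) obj += cmin[j] * x[j];
  return LP_OPTIMAL;
}

struct BBNode {
  std::vector<double> lo, hi;
};

// [[Rcpp::export]]
List milp_solve_cpp(NumericVector obj, NumericMatrix Amat, IntegerVector sense,
                    NumericVector rhs, NumericVector lb, NumericVector ub,
                    LogicalVector is_int, bool maximize, double time_limit,
                    int node_limit, double iter_limit) {
  int n = obj.size();
  int m = Amat.nrow();
  std::vector<double> cmin(n);
  for (int j = 0; j < n; ++j) cmin[j] = maximize ? -obj[j] : obj[j];
  std::vector<std::vector<double> > A(m, std::vector<double>(n));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) A[i][j] = Amat(i, j);
  std::vector<int> sen(sense.begin(), sense.end());
  std::vector<double> b(rhs.begin(), rhs.end());

  // objective integrality (ours always holds): enables bound rounding
  bool obj_integral = true;
  for (int j = 0; j < n; ++j) {
    if (std::fabs(cmin[j] - std::round(cmin[j])) > 1e-12) obj_integral = false;
    if (std::fabs(cmin[j]) > 1e-12 && !is_int[j]) obj_integral = false;
  }
  bool pure_feasibility = true;
  for (int j = 0; j < n; ++j) if (std::fabs(cmin[j]) > 1e-12) pure_feasibility = false;

  std::vector<BBNode> stack;
  {
    BBNode root;
    root.lo.assign(lb.begin(), lb.end());
    root.hi.assign(ub.begin(), ub.end());
    // round integer bounds inward
    for (int j = 0; j < n; ++j) {
      if (is_int[j]) {
        root.lo[j] = std::ceil(root.lo[j] - INT_TOL);
        root.hi[j] = std::floor(root.hi[j] + INT_TOL);
      }
    }
    stack.push_back(root);
  }

  bool have_inc = false, limit_hit = false;
  double inc_obj = std::numeric_limits<double>::infinity();
  std::vector<double> inc_x;
  long nodes = 0;
  long iter_budget = (long)iter_limit;
  std::chrono::steady_clock::time_point t0 = std::chrono::steady_clock::now();

  while (!stack.empty()) {
    if (nodes >= node_limit || iter_budget <= 0) { limit_hit = true; break; }
    double elapsed = std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t0).count();
    if (elapsed > time_limit) { limit_hit = true; break; }

    BBNode nd = stack.back();
    stack.pop_back();
    nodes++;

    std::vector<double> x;
    double lpobj;
    int st = lp_relaxation(cmin, A, sen, b, nd.lo, nd.hi, x, lpobj, iter_budget);
    if (st == LP_ITERLIMIT) { limit_hit = true; break; }
    if (st == LP_INFEASIBLE) continue;
    // bound pruning
    double bound = lpobj;
    if (obj_integral) bound = std::ceil(lpobj - 1e-6);
    if (have_inc && bound >= inc_obj - 1e-9) continue;

    // find fractional integer variable (most fractional; ties -> lowest index)
    int branch = -1;
    double bestfrac = INT_TOL;
    for (int j = 0; j < n; ++j) {
      if (!is_int[j]) continue;
      double f = x[j] - std::floor(x[j]);
      double dist = std::min(f, 1.0 - f);
      if (dist > bestfrac + 1e-12) { bestfrac = dist; branch = j; }
    }
    if (branch < 0) {
      // integral solution
      if (!have_inc || lpobj < inc_obj - 1e-9) {
        have_inc = true;
        inc_obj = lpobj;
        inc_x = x;
        for (int j = 0; j < n; ++j)
          if (is_int[j]) inc_x[j] = std::round(inc_x[j]);
        if (pure_feasibility) break; // any feasible point is optimal
      }
      continue;
    }
    double xv = x[branch];
    BBNode down = nd, up = nd;
    down.hi[branch] = std::floor(xv);
    up.lo[branch] = std::ceil(xv);
    double f = xv - std::floor(xv);
    // explore the nearer side first (it is pushed last)
    if (f < 0.5) { stack.push_back(up); stack.push_back(down); }
    else { stack.push_back(down); stack.push_back(up); }
  }

  std::string status;
  if (!limit_hit && have_inc) status = "optimal";
  else if (!limit_hit && !have_inc) status = "infeasible";
  else status = "timeout";
  // pure feasibility problems terminate the loop early on first incumbent
  if (pure_feasibility && have_inc) status = "optimal";

  NumericVector xout(n);
  double objout = NA_REAL;
  if (have_inc) {
    for (int j = 0; j < n; ++j) xout[j] = inc_x[j];
    objout = maximize ? -inc_obj : inc_obj;
  }
  return List::create(_["status"] = status,
                      _["x"] = have_inc ? xout : NumericVector(0),
                      _["objective"] = objout,
                      _["nodes"] = (double)nodes);
}
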
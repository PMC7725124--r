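// Exact branch-and-bound maximization of the per-entry-linear likelihood
// over complete, conflict-free extended matrices (Dollo(k) completions).
//
// Search space: for every (cell, mutation) pair the extended-matrix row
// fragment takes one of k+2 states -- absent (gain 0, losses 0, F = 0),
// present (gain 1, losses 0, F = 1), or gained-then-lost via loss copy l
// (gain 1, loss_l 1, F = 0).  These are exactly the assignments satisfying
// the linking constraint F = E(gain) - sum E(loss) with F binary.
//
// The pairwise perfect-phylogeny constraints (no column pair exhibiting all
// of (0,1), (1,0), (1,1)) are enforced by exact propagation: configuration
// counters per ordered column pair (p < q) are updated incrementally as
// entries are assigned, and a branch is abandoned the moment some pair
// accumulates all three configurations.  This is the same feasible set as
// the B-variable constraint block of the ILP statement (B = 1 iff the
// corresponding configuration count is positive).
//
// Bound: running objective plus the suffix sum of per-entry maxima (an
// admissible overestimate).  The all-zero matrix is installed as the
// initial incumbent, so the solver always holds a feasible solution and a
// timeout returns the best found so far.
//
// Loss-copy symmetry: copies of the same mutation are interchangeable, so a
// cell may only reuse an already-open copy or open the lowest-indexed
// unused one; this prunes relabelings of identical solutions and never
// removes an optimum.

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Inc { int idx; int which; };

struct Solver {
  int n, m, k, per, D;
  long max_losses;                            // -1 = unlimited
  std::vector<double> slope;                  // n*m, row-major [c*m + j]
  std::vector<double> suffix_best;            // admissible bound tail sums
  std::vector<std::array<double, 2>> contrib; // [entry]: contribution F=0 / F=1
  std::vector<int> c01, c10, c11;             // pair counters, flat p*D+q, p<q
  std::vector<int> rowmat;                    // n*D assigned column values
  std::vector<int> usage;                     // per column: #cells with a 1
  int used_loss_cols;
  std::vector<int> cur_opt, best_opt;         // n*m options
  double cur_obj, best_obj;
  bool timed_out;
  long long nodes;
  std::chrono::steady_clock::time_point t_end;
  bool use_timeout;
  std::vector<Inc> incs;

  inline int col(int j, int t) const { return j * per + t; }
  inline int colval(int o, int t) const {
    if (t == 0) return o >= 1 ? 1 : 0;
    return (o == 1 + t) ? 1 : 0;
  }

  bool time_up() const {
    return use_timeout && std::chrono::steady_clock::now() > t_end;
  }

  // assign mutation j of row c to option o, updating pair counters; on
  // conflict every increment is rolled back and false is returned
  bool apply(int c, int j, int o) {
    int *rv = &rowmat[(size_t)c * D];
    for (int t = 0; t <= k; ++t) rv[col(j, t)] = colval(o, t);
    incs.clear();
    bool conflict = false;
    for (int t = 0; t <= k && !conflict; ++t) {
      int q = col(j, t), vq = rv[q];
      int limit = col(j, 0) + t; // earlier mutations' columns + own earlier slots
      for (int p = 0; p < limit; ++p) {
        int vp = rv[p];
        if (vp == 0 && vq == 0) continue;
        int idx = p * D + q;
        if (vp == 0) {
          if (++c01[idx] == 1 && c10[idx] && c11[idx]) { conflict = true; }
          incs.push_back({idx, 0});
        } else if (vq == 0) {
          if (++c10[idx] == 1 && c01[idx] && c11[idx]) { conflict = true; }
          incs.push_back({idx, 1});
        } else {
          if (++c11[idx] == 1 && c01[idx] && c10[idx]) { conflict = true; }
          incs.push_back({idx, 2});
        }
        if (conflict) break;
      }
    }
    if (conflict) {
      for (auto it = incs.rbegin(); it != incs.rend(); ++it) {
        if (it->which == 0) --c01[it->idx];
        else if (it->which == 1) --c10[it->idx];
        else --c11[it->idx];
      }
      for (int t = 0; t <= k; ++t) rv[col(j, t)] = 0;
      return false;
    }
    for (int t = 1; t <= k; ++t) {
      if (colval(o, t) && usage[col(j, t)]++ == 0) ++used_loss_cols;
    }
    return true;
  }

  void undo(int c, int j, int o) {
    int *rv = &rowmat[(size_t)c * D];
    for (int t = 1; t <= k; ++t) {
      if (colval(o, t) && --usage[col(j, t)] == 0) --used_loss_cols;
    }
    for (int t = 0; t <= k; ++t) {
      int q = col(j, t), vq = rv[q];
      int limit = col(j, 0) + t;
      for (int p = 0; p < limit; ++p) {
        int vp = rv[p];
        if (vp == 0 && vq == 0) continue;
        int idx = p * D + q;
        if (vp == 0) --c01[idx]; else if (vq == 0) --c10[idx]; else --c11[idx];
      }
    }
    for (int t = 0; t <= k; ++t) rv[col(j, t)] = 0;
  }

  void dfs(int pos) {
    if (timed_out) return;
    if ((++nodes & 1023) == 0 && time_up()) { timed_out = true; return; }
    if (pos == n * m) {
      if (cur_obj > best_obj + 1e-12) {
        best_obj = cur_obj;
        best_opt = cur_opt;
      }
      return;
    }
    if (cur_obj + suffix_best[pos] <= best_obj + 1e-9) return;
    int c = pos / m, j = pos % m;
    double s = slope[pos];
    // option order: contribution descending, ties broken toward the absent
    // state then loss copies in index order
    for (int oi = 0; oi < k + 2; ++oi) {
      int o;
      if (s > 0) o = (oi == 0) ? 1 : (oi == 1 ? 0 : oi);
      else       o = (oi <= k) ? (oi == 0 ? 0 : oi + 1) : 1;
      if (o >= 2) {
        int l = o - 1;
        if (l > 1 && usage[col(j, l - 1)] == 0) continue; // symmetry order
        if (max_losses >= 0 && usage[col(j, l)] == 0 &&
            used_loss_cols >= max_losses) continue;       // loss budget
      }
      double add = contrib[pos][o == 1 ? 1 : 0];
      if (!apply(c, j, o)) continue;
      cur_opt[pos] = o;
      cur_obj += add;
      dfs(pos + 1);
      cur_obj -= add;
      undo(c, j, o);
      if (timed_out) return;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List bb_solve(NumericMatrix slope, NumericMatrix intercept, int k,
              int max_losses, double time_limit) {
  Solver s;
  s.n = slope.nrow();
  s.m = slope.ncol();
  s.k = k;
  s.per = k + 1;
  s.D = s.m * s.per;
  s.max_losses = max_losses;
  int nm = s.n * s.m;
  s.slope.resize(nm);
  s.contrib.resize(nm);
  double base = 0.0;
  for (int c = 0; c < s.n; ++c) {
    for (int j = 0; j < s.m; ++j) {
      int pos = c * s.m + j;
      s.slope[pos] = slope(c, j);
      s.contrib[pos] = {intercept(c, j), intercept(c, j) + slope(c, j)};
      base += intercept(c, j);
    }
  }
  s.suffix_best.assign(nm + 1, 0.0);
  for (int pos = nm - 1; pos >= 0; --pos) {
    s.suffix_best[pos] = s.suffix_best[pos + 1] +
      std::max(s.contrib[pos][0], s.contrib[pos][1]);
  }
  s.c01.assign((size_t)s.D * s.D, 0);
  s.c10.assign((size_t)s.D * s.D, 0);
  s.c11.assign((size_t)s.D * s.D, 0);
  s.rowmat.assign((size_t)s.n * s.D, 0);
  s.usage.assign(s.D, 0);
  s.used_loss_cols = 0;
  s.cur_opt.assign(nm, 0);
  s.best_opt.assign(nm, 0); // all-zero completion: always feasible incumbent
  s.best_obj = base;
  s.cur_obj = 0.0;
  // cur_obj accumulates absolute per-entry contributions from the root
  s.nodes = 0;
  s.timed_out = false;
  s.use_timeout = R_finite(time_limit) && time_limit > 0;
  if (s.use_timeout) {
    s.t_end = std::chrono::steady_clock::now() +
      std::chrono::microseconds((long long)(time_limit * 1e6));
  }
  if (s.use_timeout && s.time_up()) {
    s.timed_out = true;
  } else {
    s.dfs(0);
  }
  IntegerMatrix opts(s.n, s.m);
  for (int c = 0; c < s.n; ++c)
    for (int j = 0; j < s.m; ++j)
      opts(c, j) = s.best_opt[c * s.m + j];
  return List::create(
    _["options"] = opts,
    _["objective"] = s.best_obj,
    _["status"] = s.timed_out ? "feasible-timeout" : "optimal",
    _["nodes"] = (double)s.nodes);
}
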
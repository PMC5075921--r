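#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Normalized Hill transfer f(x) = x^p / (x^p + h^p); f(h) = 0.5, f(0) = 0.
static inline double hill(double x, int p, double hp) {
  if (x <= 0.0) return 0.0;
  double xp = (p == 2) ? x * x : std::pow(x, (double)p);
  return xp / (xp + hp);
}

// One synchronous update of all non-clamped nodes. Nodes without parents and
// clamped nodes keep their current value. clause buffer has length m + 1.
static void update_state(const IntegerMatrix& B, const IntegerMatrix& Rs,
                         const IntegerMatrix& C, int p, double hp,
                         bool boolean_mode, const NumericVector& clamp,
                         const std::vector<double>& x, std::vector<double>& xn,
                         std::vector<double>& clause) {
  int m = B.nrow();
  for (int j = 0; j < m; ++j) {
    if (!ISNAN(clamp[j])) { xn[j] = clamp[j]; continue; }
    int k = 0;
    for (int i = 0; i < m; ++i) k += B(i, j);
    if (k == 0) { xn[j] = x[j]; continue; }
    for (int v = 0; v <= m; ++v) clause[v] = -1.0; // -1 marks unused label
    for (int i = 0; i < m; ++i) {
      if (!B(i, j)) continue;
      double t = boolean_mode ? x[i] : hill(x[i], p, hp);
      if (Rs(i, j) == 0) t = 1.0 - t;
      int v = C(i, j);
      if (clause[v] < 0.0 || t < clause[v]) clause[v] = t;
    }
    double best = 0.0; bool any = false;
    for (int v = 0; v <= m; ++v) {
      if (clause[v] >= 0.0 && (!any || clause[v] > best)) { best = clause[v]; any = true; }
    }
    xn[j] = best;
  }
}

// [[Rcpp::export(name = ".sim_sync_cpp")]]
NumericMatrix sim_sync_cpp(IntegerMatrix B, IntegerMatrix Rs, IntegerMatrix C,
                           int p, double h, NumericVector init,
                           NumericVector clamp, int n_points,
                           bool boolean_mode) {
  int m = B.nrow();
  double hp = (p == 2) ? h * h : std::pow(h, (double)p);
  NumericMatrix out(n_points, m);
  std::vector<double> x(m), xn(m), clause(m + 1);
  for (int j = 0; j < m; ++j) x[j] = ISNAN(clamp[j]) ? init[j] : clamp[j];
  for (int j = 0; j < m; ++j) out(0, j) = x[j];
  for (int t = 1; t < n_points; ++t) {
    update_state(B, Rs, C, p, hp, boolean_mode, clamp, x, xn, clause);
    x = xn;
    for (int j = 0; j < m; ++j) out(t, j) = x[j];
  }
  return out;
}

// [[Rcpp::export(name = ".sim_steady_cpp")]]
List sim_steady_cpp(IntegerMatrix B, IntegerMatrix Rs, IntegerMatrix C,
                    int p, double h, NumericVector clamp, double eps,
                    int max_iter, bool boolean_mode) {
  int m = B.nrow();
  double hp = (p == 2) ? h * h : std::pow(h, (double)p);
  std::vector<double> x(m, 0.0), xn(m), clause(m + 1);
  for (int j = 0; j < m; ++j) if (!ISNAN(clamp[j])) x[j] = clamp[j];
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    update_state(B, Rs, C, p, hp, boolean_mode, clamp, x, xn, clause);
    ++it;
    double d = 0.0;
    for (int j = 0; j < m; ++j) {
      double dj = std::fabs(xn[j] - x[j]);
      if (dj > d) d = dj;
    }
    x = xn;
    if (d < eps) { converged = true; break; }
  }
  return List::create(_["state"] = NumericVector(x.begin(), x.end()),
                      _["converged"] = converged, _["iterations"] = it);
}

// DTW with squared-difference local cost, steps {(1,0),(0,1),(1,1)}, pinned
// endpoints; minimizes total cost, ties broken toward shorter paths. Returns
// the path-length-normalized loss.
// [[Rcpp::export(name = ".dtw_loss_cpp")]]
double dtw_loss_cpp(NumericVector y, NumericVector z) {
  int n = y.size(), m = z.size();
  std::vector<double> cost(n * m);
  std::vector<int> len(n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = y[i] - z[j]; d *= d;
      int idx = i * m + j;
      if (i == 0 && j == 0) { cost[idx] = d; len[idx] = 1; continue; }
      double bc = R_PosInf; int bl = 0;
      // diagonal preferred on exact ties (checked last with strict <)
      if (i > 0) { int q = (i - 1) * m + j; if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; } }
      if (j > 0) { int q = i * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; } }
      if (i > 0 && j > 0) { int q = (i - 1) * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] <= bl)) { bc = cost[q]; bl = len[q]; } }
      cost[idx] = bc + d; len[idx] = bl + 1;
    }
  }
  int idx = (n - 1) * m + (m - 1);
  return cost[idx] / (double)len[idx];
}

// Full DTW alignment: warp path (1-based index vectors) plus losses.
// [[Rcpp::export(name = ".dtw_align_cpp")]]
List dtw_align_cpp(NumericVector y, NumericVector z) {
  int n = y.size(), m = z.size();
  std::vector<double> cost(n * m);
  std::vector<int> len(n * m);
  std::vector<signed char> move(n * m); // 0 start, 1 from up, 2 from left, 3 diag
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = y[i] - z[j]; d *= d;
      int idx = i * m + j;
      if (i == 0 && j == 0) { cost[idx] = d; len[idx] = 1; move[idx] = 0; continue; }
      double bc = R_PosInf; int bl = 0; signed char bm = 0;
      if (i > 0) { int q = (i - 1) * m + j; if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; bm = 1; } }
      if (j > 0) { int q = i * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; bm = 2; } }
      if (i > 0 && j > 0) { int q = (i - 1) * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] <= bl)) { bc = cost[q]; bl = len[q]; bm = 3; } }
      cost[idx] = bc + d; len[idx] = bl + 1; move[idx] = bm;
    }
  }
  int i = n - 1, j = m - 1;
  int S = len[i * m + j];
  IntegerVector a(S), b(S);
  for (int s = S - 1; s >= 0; --s) {
    a[s] = i + 1; b[s] = j + 1;
    signed char mv = move[i * m + j];
    if (mv == 1) --i; else if (mv == 2) --j; else if (mv == 3) { --i; --j; }
  }
  double total = cost[(n - 1) * m + (m - 1)];
  return List::create(_["a"] = a, _["b"] = b, _["S"] = S,
                      _["total"] = total, _["loss"] = total / (double)S);
}

// Compressed column-wise adjacency for the fitness hot path: for target j,
// entries off[j]..off[j+1]-1 hold (parent index, sign, clause label).
struct CompiledNet {
  int m;
  std::vector<int> off, par, sgn, cl;
};

static void compile_net(const IntegerMatrix& B, const IntegerMatrix& Rs,
                        const IntegerMatrix& C, CompiledNet& net) {
  int m = B.nrow();
  net.m = m;
  net.off.assign(m + 1, 0);
  net.par.clear(); net.sgn.clear(); net.cl.clear();
  for (int j = 0; j < m; ++j) {
    net.off[j] = (int)net.par.size();
    for (int i = 0; i < m; ++i) {
      if (B(i, j)) {
        net.par.push_back(i);
        net.sgn.push_back(Rs(i, j));
        net.cl.push_back(C(i, j));
      }
    }
  }
  net.off[m] = (int)net.par.size();
}

static inline void update_state_fast(const CompiledNet& net, int p, double hp,
                                     bool boolean_mode, const double* clamp,
                                     const double* x, double* xn,
                                     double* clause) {
  int m = net.m;
  for (int j = 0; j < m; ++j) {
    if (!ISNAN(clamp[j])) { xn[j] = clamp[j]; continue; }
    int lo = net.off[j], hi = net.off[j + 1];
    if (lo == hi) { xn[j] = x[j]; continue; }
    int maxlab = 0;
    for (int e = lo; e < hi; ++e) {
      double t = boolean_mode ? x[net.par[e]] : hill(x[net.par[e]], p, hp);
      if (net.sgn[e] == 0) t = 1.0 - t;
      int v = net.cl[e];
      if (v > maxlab) { for (int w = maxlab + 1; w <= v; ++w) clause[w] = 2.0; maxlab = v; }
      if (t < clause[v]) clause[v] = t;
    }
    double best = 0.0;
    for (int v = 1; v <= maxlab; ++v) {
      if (clause[v] <= 1.0 && clause[v] > best) best = clause[v];
      clause[v] = 2.0;
    }
    xn[j] = best;
  }
}

// DTW loss on raw buffers with caller-provided scratch (size >= n*m each).
static double dtw_loss_fast(const double* y, int n, const double* z, int m,
                            std::vector<double>& cost, std::vector<int>& len) {
  if ((int)cost.size() < n * m) { cost.resize(n * m); len.resize(n * m); }
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = y[i] - z[j]; d *= d;
      int idx = i * m + j;
      if (i == 0 && j == 0) { cost[idx] = d; len[idx] = 1; continue; }
      double bc = R_PosInf; int bl = 0;
      if (i > 0) { int q = (i - 1) * m + j; if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; } }
      if (j > 0) { int q = i * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] < bl)) { bc = cost[q]; bl = len[q]; } }
      if (i > 0 && j > 0) { int q = (i - 1) * m + (j - 1); if (cost[q] < bc || (cost[q] == bc && len[q] <= bl)) { bc = cost[q]; bl = len[q]; } }
      cost[idx] = bc + d; len[idx] = bl + 1;
    }
  }
  int idx = (n - 1) * m + (m - 1);
  return cost[idx] / (double)len[idx];
}

// Time-series loss for one model over several series: simulate n_points
// synchronous steps from each initial state and sum, over series and
// measured nodes, the DTW loss between experimental and simulated series.
// [[Rcpp::export(name = ".ts_loss_cpp")]]
double ts_loss_cpp(IntegerMatrix B, IntegerMatrix Rs, IntegerMatrix C,
                   int p, double h, List inits, List ys,
                   IntegerVector meas_idx, IntegerVector n_points_vec,
                   List clamps, bool boolean_mode) {
  int m = B.nrow();
  double hp = (p == 2) ? h * h : std::pow(h, (double)p);
  int n_series = inits.size();
  int n_meas = meas_idx.size();
  double total = 0.0;
  CompiledNet net;
  compile_net(B, Rs, C, net);
  std::vector<double> x(m), xn(m), clause(m + 1, 2.0);
  std::vector<double> Z, ycol;
  std::vector<double> dtw_cost; std::vector<int> dtw_len;
  for (int s = 0; s < n_series; ++s) {
    NumericVector init = inits[s];
    NumericVector clamp = clamps[s];
    NumericMatrix Y = ys[s]; // n_y x n_meas
    int n_y = Y.nrow();
    int n_points = n_points_vec[s];
    if ((int)Z.size() < n_points * n_meas) Z.resize((size_t)n_points * n_meas);
    for (int j = 0; j < m; ++j) x[j] = ISNAN(clamp[j]) ? init[j] : clamp[j];
    for (int q = 0; q < n_meas; ++q) Z[(size_t)q * n_points] = x[meas_idx[q] - 1];
    for (int t = 1; t < n_points; ++t) {
      update_state_fast(net, p, hp, boolean_mode, REAL(clamp), x.data(),
                        xn.data(), clause.data());
      x.swap(xn);
      for (int q = 0; q < n_meas; ++q) Z[(size_t)q * n_points + t] = x[meas_idx[q] - 1];
    }
    if ((int)ycol.size() < n_y) ycol.resize(n_y);
    for (int q = 0; q < n_meas; ++q) {
      for (int i = 0; i < n_y; ++i) ycol[i] = Y(i, q);
      total += dtw_loss_fast(ycol.data(), n_y, &Z[(size_t)q * n_points],
                             n_points, dtw_cost, dtw_len);
    }
  }
  return total;
}

// Steady-state MSE loss: simulate every condition (rows of `clamps`, NaN =
// unclamped) to steady state from an all-zero start and compare measured
// nodes with Y (n_cond x n_meas); mean squared error over all cells.
// [[Rcpp::export(name = ".ss_loss_cpp")]]
double ss_loss_cpp(IntegerMatrix B, IntegerMatrix Rs, IntegerMatrix C,
                   int p, double h, NumericMatrix clamps, NumericMatrix Y,
                   IntegerVector meas_idx, double eps, int max_iter,
                   bool boolean_mode) {
  int m = B.nrow();
  double hp = (p == 2) ? h * h : std::pow(h, (double)p);
  int n_cond = clamps.nrow();
  CompiledNet net;
  compile_net(B, Rs, C, net);
  std::vector<double> x(m), xn(m), clause(m + 1, 2.0), cl(m);
  double sse = 0.0;
  long n_cells = 0;
  for (int c = 0; c < n_cond; ++c) {
    for (int j = 0; j < m; ++j) cl[j] = clamps(c, j);
    for (int j = 0; j < m; ++j) x[j] = ISNAN(cl[j]) ? 0.0 : cl[j];
    for (int it = 0; it < max_iter; ++it) {
      update_state_fast(net, p, hp, boolean_mode, cl.data(), x.data(),
                        xn.data(), clause.data());
      double d = 0.0;
      for (int j = 0; j < m; ++j) {
        double dj = std::fabs(xn[j] - x[j]);
        if (dj > d) d = dj;
      }
      x.swap(xn);
      if (d < eps) break;
    }
    for (int q = 0; q < meas_idx.size(); ++q) {
      double d = Y(c, q) - x[meas_idx[q] - 1];
      sse += d * d;
      ++n_cells;
    }
  }
  return sse / (double)n_cells;
}

// Synchronous Boolean attractor from a binary initial state (m <= 64).
// Returns the attractor states (cycle of length 1 = fixed point) and the
// number of transient steps before entering it.
// [[Rcpp::export(name = ".bool_attractor_cpp")]]
List bool_attractor_cpp(IntegerMatrix B, IntegerMatrix Rs, IntegerMatrix C,
                        IntegerVector init, NumericVector clamp,
                        int max_steps) {
  int m = B.nrow();
  if (m > 64) stop("Boolean attractor search supports at most 64 nodes");
  std::vector<double> x(m), xn(m), clause(m + 1);
  for (int j = 0; j < m; ++j) x[j] = ISNAN(clamp[j]) ? (double)init[j] : clamp[j];
  std::map<uint64_t, int> seen;
  std::vector<uint64_t> traj;
  uint64_t code = 0;
  for (int j = 0; j < m; ++j) if (x[j] > 0.5) code |= ((uint64_t)1 << j);
  seen[code] = 0; traj.push_back(code);
  int start = -1;
  for (int t = 1; t <= max_steps; ++t) {
    update_state(B, Rs, C, 1, 0.0, true, clamp, x, xn, clause);
    x = xn;
    code = 0;
    for (int j = 0; j < m; ++j) if (x[j] > 0.5) code |= ((uint64_t)1 << j);
    std::map<uint64_t, int>::iterator it = seen.find(code);
    if (it != seen.end()) { start = it->second; break; }
    seen[code] = t; traj.push_back(code);
  }
  if (start < 0) stop("no attractor found within max_steps (non-binary dynamics?)");
  int cyc_len = (int)traj.size() - start;
  IntegerMatrix states(cyc_len, m);
  for (int s = 0; s < cyc_len; ++s)
    for (int j = 0; j < m; ++j)
      states(s, j) = (traj[start + s] >> j) & 1 ? 1 : 0;
  return List::create(_["states"] = states, _["transient"] = start,
                      _["fixed_point"] = (cyc_len == 1));
}
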
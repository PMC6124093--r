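#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Lattice convention: 0-based (x = column, y = row); site index y * n_cols + x.
// Row 0 is the seeded edge. All RNG comes from R's stream so set.seed()
// controls every draw.

static inline int runif_int(int n) {
  // uniform on 0..n-1; unif_rand() is in (0,1) so the clamp never fires in
  // practice, it only guards against rounding at the top end
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List cpp_init_cells(int n_rows, int n_cols, int seeded_rows, int n_initial,
                    int n_tracked) {
  if (seeded_rows < 1 || seeded_rows > n_rows)
    stop("seeded_rows must be between 1 and n_rows");
  int n_sites = seeded_rows * n_cols;
  if (n_initial > n_sites)
    stop("infeasible placement: n_initial exceeds the number of seeded sites");
  if (n_tracked > n_initial)
    stop("n_tracked cannot exceed n_initial");

  // partial Fisher-Yates over the seeded block: the selected subset is
  // uniform over all subsets and the selection order is exchangeable, so the
  // first n_tracked selected cells are a uniform random tracked subset
  std::vector<int> ids(n_sites);
  for (int i = 0; i < n_sites; ++i) ids[i] = i;
  IntegerMatrix cells(n_initial, 2);
  for (int i = 0; i < n_initial; ++i) {
    int j = i + runif_int(n_sites - i);
    std::swap(ids[i], ids[j]);
    cells(i, 0) = ids[i] % n_cols;  // x (column)
    cells(i, 1) = ids[i] / n_cols;  // y (row)
  }
  IntegerVector tracked(n_tracked);
  for (int t = 0; t < n_tracked; ++t) tracked[t] = t + 1;  // 1-based
  return List::create(_["cells"] = cells, _["tracked"] = tracked);
}

static List simulate_core(const IntegerMatrix& cells0, int n_rows, int n_cols,
                          double pm, double pp, int n_steps,
                          const IntegerVector& tracked, int record_interval) {
  if (pm < 0 || pp < 0 || pm + pp > 1)
    stop("invalid parameters: need p_move >= 0, p_prolif >= 0, p_move + p_prolif <= 1");
  int n0 = cells0.nrow();
  std::vector<int> xs, ys;
  xs.reserve(4 * n0 + 64);
  ys.reserve(4 * n0 + 64);
  std::vector<unsigned char> grid((size_t)n_rows * n_cols, 0);
  for (int i = 0; i < n0; ++i) {
    int x = cells0(i, 0), y = cells0(i, 1);
    if (x < 0 || x >= n_cols || y < 0 || y >= n_rows)
      stop("cell coordinates out of bounds");
    size_t idx = (size_t)y * n_cols + x;
    if (grid[idx]) stop("duplicate cell coordinates violate volume exclusion");
    grid[idx] = 1;
    xs.push_back(x);
    ys.push_back(y);
  }

  int n_tracked = tracked.size();
  int n_rec = 0;
  IntegerVector traj(0);
  if (record_interval > 0 && n_tracked > 0) {
    if (n_steps % record_interval != 0)
      stop("record_interval must divide the number of steps");
    n_rec = n_steps / record_interval + 1;
    traj = IntegerVector((R_xlen_t)n_rec * 2 * n_tracked);
    traj.attr("dim") = IntegerVector::create(n_rec, 2, n_tracked);
    for (int t = 0; t < n_tracked; ++t) {
      int i = tracked[t] - 1;
      traj[0 + (R_xlen_t)n_rec * (0 + 2 * t)] = xs[i];
      traj[0 + (R_xlen_t)n_rec * (1 + 2 * t)] = ys[i];
    }
  }

  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  for (int step = 1; step <= n_steps; ++step) {
    int n_start = (int)xs.size();  // daughters born this step are not selectable
    for (int k = 0; k < n_start; ++k) {
      int i = runif_int(n_start);
      double r = unif_rand();
      bool move = r <= pm;
      bool birth = !move && r <= pm + pp;
      if (!move && !birth) continue;
      int d = runif_int(4);
      int nx = xs[i] + dx[d], ny = ys[i] + dy[d];
      if (nx < 0 || nx >= n_cols || ny < 0 || ny >= n_rows) continue;  // aborted
      size_t nidx = (size_t)ny * n_cols + nx;
      if (grid[nidx]) continue;  // aborted: target occupied
      if (move) {
        grid[(size_t)ys[i] * n_cols + xs[i]] = 0;
        grid[nidx] = 1;
        xs[i] = nx;
        ys[i] = ny;
      } else {
        grid[nidx] = 1;
        xs.push_back(nx);
        ys.push_back(ny);
      }
    }
    if (n_rec > 0 && step % record_interval == 0) {
      int rec = step / record_interval;
      for (int t = 0; t < n_tracked; ++t) {
        int i = tracked[t] - 1;
        traj[rec + (R_xlen_t)n_rec * (0 + 2 * t)] = xs[i];
        traj[rec + (R_xlen_t)n_rec * (1 + 2 * t)] = ys[i];
      }
    }
  }

  int n_final = (int)xs.size();
  IntegerMatrix cells(n_final, 2);
  for (int i = 0; i < n_final; ++i) {
    cells(i, 0) = xs[i];
    cells(i, 1) = ys[i];
  }
  return List::create(_["cells"] = cells, _["traj"] = traj);
}

// [[Rcpp::export]]
List cpp_simulate(IntegerMatrix cells, int n_rows, int n_cols, double pm,
                  double pp, int n_steps, IntegerVector tracked,
                  int record_interval) {
  return simulate_core(cells, n_rows, n_cols, pm, pp, n_steps, tracked,
                       record_interval);
}

// [[Rcpp::export]]
List cpp_run_dataset(int n_replicates, int n_rows, int n_cols, int seeded_rows,
                     int n_initial, int n_tracked, double pm, double pp,
                     int n_steps, int record_interval) {
  List out(n_replicates);
  for (int m = 0; m < n_replicates; ++m) {
    List init = cpp_init_cells(n_rows, n_cols, seeded_rows, n_initial,
                               n_tracked);
    out[m] = simulate_core(init["cells"], n_rows, n_cols, pm, pp, n_steps,
                           init["tracked"], record_interval);
  }
  return out;
}

// [[Rcpp::export]]
int cpp_largest_cluster(IntegerMatrix cells, int n_rows, int n_cols,
                        int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int n = cells.nrow();
  if (n == 0) return 0;
  std::vector<int> who((size_t)n_rows * n_cols, -1);
  for (int i = 0; i < n; ++i)
    who[(size_t)cells(i, 1) * n_cols + cells(i, 0)] = i;
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int n_dir = connectivity;
  int best = 0;
  for (int i = 0; i < n; ++i) {
    if (seen[i]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      ++size;
      int x = cells(c, 0), y = cells(c, 1);
      for (int d = 0; d < n_dir; ++d) {
        int nx = x + dx8[d], ny = y + dy8[d];
        if (nx < 0 || nx >= n_cols || ny < 0 || ny >= n_rows) continue;
        int j = who[(size_t)ny * n_cols + nx];
        if (j >= 0 && !seen[j]) {
          seen[j] = 1;
          stack.push_back(j);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_pair_counts(IntegerMatrix cells, int max_l, bool manhattan) {
  int n = cells.nrow();
  IntegerVector counts(max_l);
  for (int i = 0; i < n; ++i) {
    int xi = cells(i, 0), yi = cells(i, 1);
    for (int j = i + 1; j < n; ++j) {
      int l = abs(yi - cells(j, 1));
      if (manhattan) l += abs(xi - cells(j, 0));
      if (l >= 1 && l <= max_l) ++counts[l - 1];
    }
  }
  return counts;
}
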
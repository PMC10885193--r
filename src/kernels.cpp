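#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding trailing-window background per pixel. `t_by_px` is T x P (one
// column per pixel, frames contiguous within a column); returns
// (T - window) x P where output row k is the background of original frame
// (window + k), i.e. the mean/median over the `window` frames strictly
// preceding it. The median maintains a sorted window per pixel and updates
// it incrementally (binary search + memmove), O(T * w) worst case with a
// small constant.
// [[Rcpp::export]]
NumericMatrix cpp_running_background(const NumericMatrix& t_by_px, int window,
                                     bool use_median) {
  const int T = t_by_px.nrow(), P = t_by_px.ncol();
  if (window < 1 || window >= T)
    stop("window must satisfy 1 <= window < n_frames");
  const int Tout = T - window;
  NumericMatrix out(Tout, P);
  if (use_median) {
    std::vector<double> win(window);
    const int h = window / 2;
    const bool even = (window % 2 == 0);
    for (int p = 0; p < P; ++p) {
      const double* col = &t_by_px(0, p);
      win.assign(col, col + window);
      std::sort(win.begin(), win.end());
      for (int t = 0; t < Tout; ++t) {
        out(t, p) = even ? 0.5 * (win[h - 1] + win[h]) : win[h];
        if (t + 1 == Tout) break;
        // slide: drop frame t, add frame t + window
        double old_v = col[t], new_v = col[t + window];
        auto lo = std::lower_bound(win.begin(), win.end(), old_v);
        win.erase(lo);
        auto up = std::upper_bound(win.begin(), win.end(), new_v);
        win.insert(up, new_v);
      }
    }
  } else {
    for (int p = 0; p < P; ++p) {
      const double* col = &t_by_px(0, p);
      double s = 0.0;
      for (int k = 0; k < window; ++k) s += col[k];
      out(0, p) = s / window;
      for (int t = 1; t < Tout; ++t) {
        s += col[t + window - 1] - col[t - 1];
        out(t, p) = s / window;
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask (H x W, nonzero =
// foreground) with 4- or 8-connectivity. Labels are assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nd = connectivity;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        for (int d = 0; d < nd; ++d) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
    }
  }
  return lab;
}

// Jonker-Volgenant / Hungarian solver for the square linear assignment
// problem, O(n^3). Returns a 1-based vector a with a[i] = column assigned to
// row i. Forbidden entries should be encoded as a large finite cost.
// [[Rcpp::export]]
IntegerVector cpp_solve_lap(const NumericMatrix& cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  // e-maxx formulation with 1-based rows/cols and virtual column 0
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), R_PosInf);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = R_PosInf;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0 != 0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
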
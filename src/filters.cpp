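#include <Rcpp.h>
#include <set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mirror (symmetric, non-repeating edge) reflection of an out-of-range index
// onto 0..n-1.  -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Balanced two-multiset container for an exact sliding median of an
// even-sized sample: `lo` holds the smaller half (max at its end), `hi` the
// larger half; both always have equal size, median = mean of the extremes.
struct MedianWindow {
  std::multiset<double> lo, hi;
  void insert(double v) {
    if (lo.empty() || v <= *lo.rbegin()) lo.insert(v); else hi.insert(v);
    rebalance();
  }
  void remove(double v) {
    std::multiset<double>::iterator it = lo.find(v);
    if (it != lo.end()) lo.erase(it);
    else {
      it = hi.find(v);
      hi.erase(it);
    }
    rebalance();
  }
  void rebalance() {
    while (lo.size() > hi.size() + 1) {
      std::multiset<double>::iterator it = lo.end(); --it;
      hi.insert(*it); lo.erase(it);
    }
    while (hi.size() > lo.size() + 1) {
      std::multiset<double>::iterator it = hi.begin();
      lo.insert(*it); hi.erase(it);
    }
  }
  double median() const {
    // window size is even (4 r^2) so halves are equal: average the extremes
    if (lo.size() == hi.size()) return 0.5 * (*lo.rbegin() + *hi.begin());
    return lo.size() > hi.size() ? *lo.rbegin() : *hi.begin();
  }
};

// Sliding-window median with an even 2r x 2r window.  The window for output
// pixel (i, j) spans rows i-(r-1)..i+r and columns j-(r-1)..j+r (the window's
// top-left r x r quadrant covers the output pixel); borders are mirrored.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int r) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  int w = 2 * r;
  std::vector<double> colvals(w);
  for (int i = 0; i < nr; i++) {
    MedianWindow win;
    // seed window at column 0
    for (int dj = -(r - 1); dj <= r; dj++) {
      int j = reflect_idx(dj, nc);
      for (int di = -(r - 1); di <= r; di++)
        win.insert(img(reflect_idx(i + di, nr), j));
    }
    out(i, 0) = win.median();
    for (int j = 1; j < nc; j++) {
      int j_out = reflect_idx(j - r, nc);  // leaving column
      int j_in  = reflect_idx(j + r, nc);  // entering column
      for (int di = -(r - 1); di <= r; di++) {
        int ii = reflect_idx(i + di, nr);
        win.remove(img(ii, j_out));
        win.insert(img(ii, j_in));
      }
      out(i, j) = win.median();
    }
  }
  return out;
}

// Greedy exclusion-radius acceptance.  Candidates arrive already ordered
// (ascending score, ties broken upstream); a candidate is accepted iff its
// Euclidean distance to every previously accepted point is strictly greater
// than D.  A uniform grid hash of cell size D limits each test to the 3x3
// neighbouring cells.
// [[Rcpp::export]]
LogicalVector cpp_greedy_exclusion(NumericVector x, NumericVector y, double D) {
  int n = x.size();
  LogicalVector acc(n);
  if (n == 0) return acc;
  double xmin = *std::min_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymax = *std::max_element(y.begin(), y.end());
  double cell = D > 0 ? D : 1.0;
  int gx = (int)((xmax - xmin) / cell) + 1;
  int gy = (int)((ymax - ymin) / cell) + 1;
  std::vector< std::vector<int> > grid((size_t)gx * gy);
  double D2 = D * D;
  for (int k = 0; k < n; k++) {
    int cx = (int)((x[k] - xmin) / cell);
    int cy = (int)((y[k] - ymin) / cell);
    bool ok = true;
    for (int ax = std::max(0, cx - 1); ax <= std::min(gx - 1, cx + 1) && ok; ax++)
      for (int ay = std::max(0, cy - 1); ay <= std::min(gy - 1, cy + 1) && ok; ay++) {
        const std::vector<int> &bucket = grid[(size_t)ax * gy + ay];
        for (size_t b = 0; b < bucket.size(); b++) {
          double dx = x[k] - x[bucket[b]], dy = y[k] - y[bucket[b]];
          if (dx * dx + dy * dy <= D2) { ok = false; break; }
        }
      }
    acc[k] = ok;
    if (ok) grid[(size_t)cx * gy + cy].push_back(k);
  }
  return acc;
}
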
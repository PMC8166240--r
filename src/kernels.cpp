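#include <Rcpp.h>
using namespace Rcpp;

#include <deque>

// Running extremum over a window of 2*half_window+1 points, clipped at the
// spectrum edges (border handling by window shrinkage, as in grey-scale
// morphology on finite signals). Monotonic-deque algorithm, O(n).
static NumericVector running_extremum(const NumericVector& x, int half_window,
                                      bool maximum) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> q;  // indices with monotone values, front = current extremum
  for (int j = 0; j < n + half_window; ++j) {
    if (j < n) {
      while (!q.empty() &&
             (maximum ? x[q.back()] <= x[j] : x[q.back()] >= x[j]))
        q.pop_back();
      q.push_back(j);
    }
    int i = j - half_window;  // output position whose window [i-h, i+h] is complete
    if (i >= 0) {
      while (q.front() < i - half_window) q.pop_front();
      out[i] = x[q.front()];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".running_min")]]
NumericVector running_min(NumericVector x, int half_window) {
  return running_extremum(x, half_window, false);
}

// [[Rcpp::export(name = ".running_max")]]
NumericVector running_max(NumericVector x, int half_window) {
  return running_extremum(x, half_window, true);
}

// Indices (1-based) of points that are the maximum within +/- half_window
// points. Ties are broken toward the lower index: point i qualifies iff
// x[i] > x[j] for all j < i in the window and x[i] >= x[j] for all j > i.
// [[Rcpp::export(name = ".local_maxima")]]
IntegerVector local_maxima(NumericVector x, int half_window) {
  int n = x.size();
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half_window);
    int hi = std::min(n - 1, i + half_window);
    bool is_max = true;
    for (int j = lo; j < i && is_max; ++j) if (x[j] >= x[i]) is_max = false;
    for (int j = i + 1; j <= hi && is_max; ++j) if (x[j] > x[i]) is_max = false;
    if (is_max) idx.push_back(i + 1);
  }
  return wrap(idx);
}
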
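#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Naive O(n*w) sliding-window range: recomputes max and min over every
// window from scratch.  Reference implementation used to cross-check the
// deque algorithm below.
// [[Rcpp::export(name = ".roll_range_naive")]]
NumericVector roll_range_naive(NumericVector x, int w) {
  int n = x.size();
  if (w < 1 || w > n) stop("window must be in [1, length(x)]");
  int m = n - w + 1;
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    double mx = x[s], mn = x[s];
    for (int j = 1; j < w; ++j) {
      if (x[s + j] > mx) mx = x[s + j];
      if (x[s + j] < mn) mn = x[s + j];
    }
    out[s] = mx - mn;
  }
  return out;
}

// Sliding-window range (max - min) over windows of width w, one value per
// window start.  Monotonic-deque algorithm, O(n) per channel.
// [[Rcpp::export(name = ".roll_range")]]
NumericVector roll_range(NumericVector x, int w) {
  int n = x.size();
  if (w < 1 || w > n) stop("window must be in [1, length(x)]");
  int m = n - w + 1;
  NumericVector out(m);
  std::deque<int> qmax, qmin;
  for (int i = 0; i < n; ++i) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    int start = i - w + 1;
    if (start >= 0) {
      if (qmax.front() < start) qmax.pop_front();
      if (qmin.front() < start) qmin.pop_front();
      out[start] = x[qmax.front()] - x[qmin.front()];
    }
  }
  return out;
}
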
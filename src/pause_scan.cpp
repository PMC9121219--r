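#include <Rcpp.h>
using namespace Rcpp;

// Greedy anchor scan for within-stroke pauses over one stroke's samples.
// From anchor i, extend j while sample j stays within `radius` of sample i's
// position; if t[j] - t[i] exceeds `min_dur` strictly, emit [t[i], t[j]] and
// restart the anchor at j + 1, otherwise advance the anchor to i + 1.
// Returns a matrix with one row per pause: (start_t, end_t).
// [[Rcpp::export]]
NumericMatrix pause_scan_cpp(NumericVector x, NumericVector y,
                             NumericVector t, double radius, double min_dur) {
  const int n = x.size();
  const double r2 = radius * radius;
  std::vector<double> starts, ends;
  int i = 0;
  while (i < n - 1) {
    int j = i;
    while (j + 1 < n) {
      const double dx = x[j + 1] - x[i];
      const double dy = y[j + 1] - y[i];
      if (dx * dx + dy * dy > r2) break;
      ++j;
    }
    if (t[j] - t[i] > min_dur) {
      starts.push_back(t[i]);
      ends.push_back(t[j]);
      i = j + 1;
    } else {
      ++i;
    }
  }
  NumericMatrix out(starts.size(), 2);
  for (int k = 0; k < (int)starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  return out;
}
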
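#include <Rcpp.h>
using namespace Rcpp;

// Dispersion-threshold (I-DT) scanner over the valid samples of one trial.
//
// Inputs are the timestamps and coordinates of the *valid* samples only,
// in time order. `brk[i] == 1` marks a gap break between valid sample i-1
// and i (time difference above the gap tolerance): no window may span it.
//
// Greedy scan: grow the window while dispersion = max(range_x, range_y)
// stays at or below `dispersion`; at the maximal window, emit it as a
// fixation if its wall-clock span reaches `min_dur`, otherwise slide the
// window start by one sample.
//
// Returns a 2-column integer matrix of (start, end) indices (1-based) into
// the valid-sample vectors.
// [[Rcpp::export]]
IntegerMatrix idt_scan(NumericVector t, NumericVector x, NumericVector y,
                       IntegerVector brk, double dispersion, double min_dur) {
  int n = t.size();
  std::vector<int> starts, ends;
  int i = 0;
  while (i < n) {
    double xmin = x[i], xmax = x[i], ymin = y[i], ymax = y[i];
    int j = i;
    while (j + 1 < n && brk[j + 1] == 0) {
      double nx_min = std::min(xmin, x[j + 1]);
      double nx_max = std::max(xmax, x[j + 1]);
      double ny_min = std::min(ymin, y[j + 1]);
      double ny_max = std::max(ymax, y[j + 1]);
      if ((nx_max - nx_min) > dispersion || (ny_max - ny_min) > dispersion)
        break;
      xmin = nx_min; xmax = nx_max; ymin = ny_min; ymax = ny_max;
      ++j;
    }
    if (t[j] - t[i] >= min_dur) {
      starts.push_back(i + 1);
      ends.push_back(j + 1);
      i = j + 1;
    } else {
      ++i;
    }
  }
  IntegerMatrix out(starts.size(), 2);
  for (int k = 0; k < (int)starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  return out;
}
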
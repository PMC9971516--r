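#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Predictive-mean-matching donor draw against donors sorted by predicted
// mean. For each target predicted value, walks outward from its insertion
// point in the sorted donor means and returns the observed outcome of the
// pick-th nearest donor (pick pre-drawn in R, 1..k). O(m k) after the sort.
// [[Rcpp::export(name = ".pmm_match_cpp")]]
NumericVector pmm_match_cpp(NumericVector sorted_yhat,
                            NumericVector sorted_y,
                            NumericVector target_yhat,
                            IntegerVector pick) {
  const int n = sorted_yhat.size();
  const int m = target_yhat.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double t = target_yhat[i];
    int hi = std::upper_bound(sorted_yhat.begin(), sorted_yhat.end(), t) -
             sorted_yhat.begin();
    int lo = hi - 1;
    int chosen = -1;
    for (int step = 0; step < pick[i]; ++step) {
      if (lo < 0) { chosen = hi++; }
      else if (hi >= n) { chosen = lo--; }
      else if (t - sorted_yhat[lo] <= sorted_yhat[hi] - t) { chosen = lo--; }
      else { chosen = hi++; }
    }
    out[i] = sorted_y[chosen];
  }
  return out;
}
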
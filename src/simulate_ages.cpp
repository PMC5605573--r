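#include <Rcpp.h>
using namespace Rcpp;

// Replicate walks on the time-reversed absorbing chain, CSR layout.
// row_ptr: length n+1 offsets; entries of row s live in [row_ptr[s], row_ptr[s+1]).
// out_state: 0-based target state of each entry, -1 encodes the stop outcome.
// cum: per-row cumulative probabilities, last entry of each row == 1.
// Driven by R's RNG (set.seed upstream) for reproducibility.
// [[Rcpp::export]]
List simulate_ages_cpp(IntegerVector row_ptr, IntegerVector out_state,
                       NumericVector cum, int start, int nrep,
                       double max_steps) {
  NumericVector ages(nrep);
  int capped = 0;
  for (int r = 0; r < nrep; ++r) {
    int s = start;
    double steps = 0.0;
    bool stopped = false;
    for (;;) {
      double u = unif_rand();
      int lo = row_ptr[s], hi = row_ptr[s + 1] - 1;
      while (lo < hi) {
        int mid = lo + (hi - lo) / 2;
        if (cum[mid] >= u) hi = mid; else lo = mid + 1;
      }
      int nxt = out_state[lo];
      if (nxt < 0) { stopped = true; break; }
      s = nxt;
      steps += 1.0;
      if (steps >= max_steps) break;
    }
    if (stopped) ages[r] = steps;
    else { ages[r] = NA_REAL; ++capped; }
  }
  return List::create(_["ages"] = ages, _["capped"] = capped);
}
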
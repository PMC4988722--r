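#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Total marginal-tree branch length (below the local MRCA) at each query
// position, from an encoded backward event log. Event encoding, one row per
// event: type (1 = coalescence, 2 = recombination), time, id1, id2 or
// breakpoint, child or left id, right id. Leaves are ids 1..n at time 0.
// Used to place infinite-sites mutations with ms semantics: mutation
// positions are drawn with density proportional to the local tree length.

// [[Rcpp::export]]
NumericVector cpp_marginal_lengths(NumericMatrix events, int n,
                                   NumericVector xs) {
  const int ne = events.nrow();
  int max_id = n;
  for (int e = 0; e < ne; ++e) {
    int type = (int)events(e, 0);
    if (type == 1) {
      max_id = std::max(max_id, (int)events(e, 4));
    } else if (type == 2) {
      max_id = std::max(max_id, std::max((int)events(e, 4), (int)events(e, 5)));
    }
  }
  NumericVector out(xs.size());
  std::vector<double> t0(max_id + 1);
  std::vector<char> carrier(max_id + 1);
  for (int q = 0; q < xs.size(); ++q) {
    double x = xs[q];
    std::fill(t0.begin(), t0.end(), 0.0);
    std::fill(carrier.begin(), carrier.end(), 0);
    for (int i = 1; i <= n; ++i) carrier[i] = 1;
    int count = n;
    double total = 0.0;
    if (count <= 1) { out[q] = 0.0; continue; }
    for (int e = 0; e < ne && count > 1; ++e) {
      int type = (int)events(e, 0);
      double t = events(e, 1);
      if (type == 1) {
        int a = (int)events(e, 2), b = (int)events(e, 3),
            child = (int)events(e, 4);
        bool ca = carrier[a], cb = carrier[b];
        if (ca && cb) {
          total += (t - t0[a]) + (t - t0[b]);
          carrier[a] = carrier[b] = 0;
          --count;
          if (count > 1) { carrier[child] = 1; t0[child] = t; }
        } else if (ca || cb) {
          int keep = ca ? a : b;
          carrier[child] = 1;
          t0[child] = t0[keep];
          carrier[keep] = 0;
        }
      } else {
        int lin = (int)events(e, 2);
        if (carrier[lin]) {
          double bp = events(e, 3);
          int to = (x < bp) ? (int)events(e, 4) : (int)events(e, 5);
          carrier[to] = 1;
          t0[to] = t0[lin];
          carrier[lin] = 0;
        }
      }
    }
    out[q] = total;
  }
  return out;
}
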
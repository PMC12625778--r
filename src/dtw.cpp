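#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping over a precomputed local-cost matrix with steps
// {(1,0), (0,1), (1,1)} and anchored endpoints. Returns the optimal
// cumulative cost and the (1-based) warping path. Ties prefer the
// diagonal, then the vertical (0,1) step, so backtracking is
// deterministic.
// [[Rcpp::export]]
List dtw_cost_path(NumericMatrix cost) {
  const int na = cost.nrow(), nb = cost.ncol();
  if (na < 2 || nb < 2) stop("series must have length >= 2");
  NumericMatrix D(na, nb);
  IntegerMatrix from(na, nb);        // 0 diag, 1 up (a-1), 2 left (b-1)
  D(0, 0) = cost(0, 0);
  for (int i = 1; i < na; ++i) { D(i, 0) = D(i - 1, 0) + cost(i, 0); from(i, 0) = 1; }
  for (int j = 1; j < nb; ++j) { D(0, j) = D(0, j - 1) + cost(0, j); from(0, j) = 2; }
  for (int i = 1; i < na; ++i) {
    for (int j = 1; j < nb; ++j) {
      double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
      double m = dd; int f = 0;
      if (du < m) { m = du; f = 1; }
      if (dl < m) { m = dl; f = 2; }
      D(i, j) = m + cost(i, j);
      from(i, j) = f;
    }
  }
  // backtrack
  std::vector<int> pa, pb;
  int i = na - 1, j = nb - 1;
  pa.push_back(i + 1); pb.push_back(j + 1);
  while (i > 0 || j > 0) {
    int f = from(i, j);
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
    pa.push_back(i + 1); pb.push_back(j + 1);
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["cost"] = D(na - 1, nb - 1),
                      _["index_a"] = wrap(pa), _["index_b"] = wrap(pb));
}
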
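#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping by full dynamic programming over the step set
// {(1,1),(1,0),(0,1)}, ties broken in favour of the diagonal step.
// Local distance is the Euclidean distance between sample rows.
// [[Rcpp::export]]
List dtw_cpp(NumericMatrix ref, NumericMatrix qry) {
  const int n = ref.nrow(), m = qry.nrow(), k = ref.ncol();
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 = diagonal, 1 = (i-1,j), 2 = (i,j-1)

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = 0.0;
      for (int c = 0; c < k; ++c) {
        const double t = ref(i, c) - qry(j, c);
        d += t * t;
      }
      d = std::sqrt(d);
      if (i == 0 && j == 0) {
        D(i, j) = d;
        from(i, j) = -1;
      } else if (i == 0) {
        D(i, j) = d + D(i, j - 1);
        from(i, j) = 2;
      } else if (j == 0) {
        D(i, j) = d + D(i - 1, j);
        from(i, j) = 1;
      } else {
        double best = D(i - 1, j - 1);
        int s = 0;
        if (D(i - 1, j) < best) { best = D(i - 1, j); s = 1; }
        if (D(i, j - 1) < best) { best = D(i, j - 1); s = 2; }
        D(i, j) = d + best;
        from(i, j) = s;
      }
    }
  }

  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (!(i == 0 && j == 0)) {
    const int s = from(i, j);
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = D(n - 1, m - 1),
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}
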
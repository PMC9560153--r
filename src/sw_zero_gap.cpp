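#include <Rcpp.h>
using namespace Rcpp;

// Local alignment maximum with per-pair substitution scores and zero gap
// open/extension cost. With free gaps the recurrence collapses to
//   H[i][j] = max(0, H[i-1][j-1] + s(a_i, b_j), H[i-1][j], H[i][j-1])
// and the optimum is a maximum-scoring common subsequence of the two inputs.
// a and b are 0-based row/column indices into the substitution matrix.
// [[Rcpp::export]]
double sw_zero_gap_max(IntegerVector a, IntegerVector b, NumericMatrix s) {
    int n = a.size(), m = b.size();
    if (n == 0 || m == 0) return 0.0;
    std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
        cur[0] = 0.0;
        int ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            double h = prev[j - 1] + s(ai, b[j - 1]);
            if (prev[j] > h) h = prev[j];
            if (cur[j - 1] > h) h = cur[j - 1];
            if (h < 0.0) h = 0.0;
            cur[j] = h;
            if (h > best) best = h;
        }
        std::swap(prev, cur);
    }
    return best;
}
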
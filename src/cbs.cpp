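#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Scan every admissible arc (i, j] of y (0 <= i < j <= n, complement
// non-empty) and return the arc maximising |Z|, where
//   Z(i,j) = (mean_arc - mean_complement) / (s * sqrt(1/k + 1/(n-k))),
// with k = j - i and s the overall sample standard deviation of y.
// Admissibility (min segment width mw): an interior arc (0 < i < j < n)
// induces three linear pieces of widths i, j-i, n-j, all required >= mw;
// a boundary-touching arc induces two pieces of widths k and n-k.
// Ties broken by smallest i, then smallest j (loop order + strict compare).
static void best_arc(const std::vector<double> &y, int mw,
                     int &bi, int &bj, double &bT) {
    const int n = (int) y.size();
    bi = -1; bj = -1; bT = 0.0;
    if (n < 2 * mw) return;

    double sum = 0.0, ss = 0.0;
    for (int t = 0; t < n; ++t) { sum += y[t]; ss += y[t] * y[t]; }
    const double mean = sum / n;
    double var = (n > 1) ? (ss - n * mean * mean) / (n - 1) : 0.0;
    if (var <= 1e-24) return;          // zero-variance series: statistic 0
    const double s = std::sqrt(var);

    std::vector<double> S(n + 1, 0.0);
    for (int t = 0; t < n; ++t) S[t + 1] = S[t] + y[t];

    double best = 0.0;
    for (int i = 0; i <= n - 1; ++i) {
        for (int j = i + 1; j <= n; ++j) {
            const int k = j - i;
            if (k == n) continue;                      // complement empty
            if (i > 0 && j < n) {
                if (i < mw || k < mw || (n - j) < mw) continue;
            } else {
                if (k < mw || (n - k) < mw) continue;
            }
            const double ma = (S[j] - S[i]) / k;
            const double mc = (S[n] - S[j] + S[i]) / (n - k);
            const double z = std::fabs((ma - mc) /
                               (s * std::sqrt(1.0 / k + 1.0 / (n - k))));
            if (z > best + 1e-12) { best = z; bi = i; bj = j; }
        }
    }
    bT = (bi < 0) ? 0.0 : best;
}

// [[Rcpp::export]]
List cbs_max_stat(NumericVector y, int min_width) {
    std::vector<double> v(y.begin(), y.end());
    int bi, bj; double bT;
    best_arc(v, min_width, bi, bj, bT);
    return List::create(_["i"] = bi, _["j"] = bj, _["statistic"] = bT);
}

// Count permutations whose maximal arc statistic reaches t_obs.
// Uses R's RNG (so set.seed() governs the stream). If stop_count > 0 the
// loop terminates as soon as the count reaches it (the caller then knows
// p > alpha without finishing all nperm shuffles).
// [[Rcpp::export]]
List cbs_perm_test(NumericVector y, int min_width, int nperm, double t_obs,
                   int stop_count) {
    RNGScope scope;
    std::vector<double> p(y.begin(), y.end());
    const int n = (int) p.size();
    int count = 0, done = 0;
    for (int b = 0; b < nperm; ++b) {
        for (int t = n - 1; t > 0; --t) {      // Fisher-Yates shuffle
            int u = (int) (unif_rand() * (t + 1));
            if (u > t) u = t;
            std::swap(p[t], p[u]);
        }
        int bi, bj; double bT;
        best_arc(p, min_width, bi, bj, bT);
        if (bT >= t_obs - 1e-9) ++count;
        ++done;
        if (stop_count > 0 && count >= stop_count) break;
    }
    return List::create(_["count"] = count, _["done"] = done);
}
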
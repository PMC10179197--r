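#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Signed enrichment score for sorted 1-based hit positions, given the
// per-position hit weights |stat|^w precomputed for the whole ranking.
// Hits add weight[pos]/W, misses subtract 1/(N-k); the score is the
// running-sum value of maximal absolute deviation from zero, with a tie
// between the positive and negative extremes resolved to the positive one.
// If the total hit weight W is zero (all hit statistics zero) the hits
// contribute uniform increments (the unweighted limit).
static double es_sorted_positions(const std::vector<double>& weights,
                                  const int* pos, int k, int n) {
    double W = 0.0;
    for (int i = 0; i < k; ++i) W += weights[pos[i] - 1];
    const bool uniform = (W <= 0.0);
    if (uniform) W = k;
    const double miss = 1.0 / (double)(n - k);

    // Extremes occur just after a hit (top) or just before one (bottom);
    // between hits the walk decreases linearly.
    double cum = 0.0, top = 0.0, bottom = 0.0;
    for (int i = 0; i < k; ++i) {
        double misses_before = (double)(pos[i] - 1 - i);
        double at_bottom = cum - misses_before * miss;
        if (at_bottom < bottom) bottom = at_bottom;
        cum += (uniform ? 1.0 : weights[pos[i] - 1]) / W;
        double at_top = cum - misses_before * miss;
        if (at_top > top) top = at_top;
    }
    // tie resolved to the positive extreme, with a tolerance so exact ties
    // are not flipped by floating-point summation order
    return (top >= -bottom - 1e-12) ? top : bottom;
}

static std::vector<double> hit_weights(const NumericVector& stats,
                                       double weight_exponent) {
    const int n = stats.size();
    std::vector<double> w(n);
    for (int i = 0; i < n; ++i) {
        double s = std::fabs(stats[i]);
        if (weight_exponent == 0.0) w[i] = 1.0;
        else if (weight_exponent == 1.0) w[i] = s;
        else w[i] = std::pow(s, weight_exponent);
    }
    return w;
}

//' @noRd
// [[Rcpp::export(name = ".calc_es_cpp")]]
double calc_es_cpp(NumericVector stats, IntegerVector positions,
                   double weight_exponent) {
    const int n = stats.size();
    const int k = positions.size();
    if (k <= 0 || k >= n)
        stop("hit set size must be in [1, N-1]");
    std::vector<int> pos(positions.begin(), positions.end());
    for (int i = 0; i < k; ++i)
        if (pos[i] < 1 || pos[i] > n) stop("hit position out of range");
    std::sort(pos.begin(), pos.end());
    std::vector<double> w = hit_weights(stats, weight_exponent);
    return es_sorted_positions(w, pos.data(), k, n);
}

//' @noRd
// [[Rcpp::export(name = ".perm_null_cpp")]]
NumericVector perm_null_cpp(NumericVector stats, int set_size, int n_perm,
                            double weight_exponent) {
    const int n = stats.size();
    if (set_size <= 0 || set_size >= n)
        stop("set_size must be in [1, N-1]");
    if (n_perm <= 0)
        stop("n_perm must be positive");
    NumericVector out(n_perm);
    std::vector<double> w = hit_weights(stats, weight_exponent);
    std::vector<int> idx(n);
    std::vector<int> pos(set_size);
    for (int i = 0; i < n; ++i) idx[i] = i + 1;
    for (int p = 0; p < n_perm; ++p) {
        // partial Fisher-Yates draw of set_size positions, driven by R's RNG
        for (int i = 0; i < set_size; ++i) {
            int j = i + (int)(unif_rand() * (double)(n - i));
            if (j >= n) j = n - 1;
            std::swap(idx[i], idx[j]);
            pos[i] = idx[i];
        }
        std::sort(pos.begin(), pos.end());
        out[p] = es_sorted_positions(w, pos.data(), set_size, n);
    }
    return out;
}
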
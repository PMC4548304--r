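#include <Rcpp.h>
using namespace Rcpp;

// Pairwise gap distances over binary masks (1 = gap, 0 = residue).
// metric: 1 = linear (Hamming on masks), 2 = affine (3 per mismatch
// opening, 1 per extension), 3 = cumulative (run position index summed,
// so a run of k mismatching columns contributes k(k+1)/2).

static double pair_dist(const int *a, const int *b, int L, int metric) {
    double s = 0.0;
    if (metric == 1) {
        for (int l = 0; l < L; ++l) s += (a[l] != b[l]);
    } else if (metric == 2) {
        int prev = 0;  // column -1 treated as agreeing: first mismatch opens
        for (int l = 0; l < L; ++l) {
            int d = (a[l] != b[l]);
            if (d) s += prev ? 1.0 : 3.0;
            prev = d;
        }
    } else {
        double c = 0.0;  // C_{-1} = 0
        for (int l = 0; l < L; ++l) {
            if (a[l] != b[l]) c += 1.0; else c = 0.0;
            s += c;
        }
    }
    return s;
}

// [[Rcpp::export]]
double pair_dist_cpp(IntegerVector a, IntegerVector b, int metric) {
    if (a.size() != b.size()) stop("mask rows have different lengths");
    return pair_dist(a.begin(), b.begin(), a.size(), metric);
}

// Full symmetric N x N matrix; exactly N(N-1)/2 pair evaluations.
// Mask is passed row-major (one contiguous row per sequence).
// [[Rcpp::export]]
NumericMatrix full_dist_cpp(IntegerVector mask_rowmajor, int n, int L,
                            int metric) {
    NumericMatrix out(n, n);
    const int *m = mask_rowmajor.begin();
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double d = pair_dist(m + (size_t)i * L, m + (size_t)j * L, L,
                                 metric);
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Rectangular M x N matrix of distances from each seed row to every row.
// Every non-self entry is evaluated: M*N - M evaluations.
// [[Rcpp::export]]
NumericMatrix seed_dist_cpp(IntegerVector mask_rowmajor, int n, int L,
                            IntegerVector seeds, int metric) {
    int M = seeds.size();
    NumericMatrix out(M, n);
    const int *m = mask_rowmajor.begin();
    for (int s = 0; s < M; ++s) {
        int i = seeds[s];  // 0-based
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            out(s, j) = pair_dist(m + (size_t)i * L, m + (size_t)j * L, L,
                                  metric);
        }
    }
    return out;
}
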
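#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Contrast-weighted histogram of all unordered pair distances.
// Bins are [i*dr, (i+1)*dr) for i = 0..n_bins-1 over [0, r_max]; the last
// bin is closed above so the maximum distance is always counted.
// Self terms (j == k) never enter. Returns the per-bin sum of w_j * w_k and
// the largest pair distance.
// [[Rcpp::export(name = ".pair_hist_cpp")]]
List pair_hist_cpp(NumericMatrix coords, NumericVector w, int n_bins,
                   double r_max) {
    const int n = coords.nrow();
    NumericVector p(n_bins);
    const double *x = &coords(0, 0);
    const double *y = &coords(0, 1);
    const double *z = &coords(0, 2);
    double dmax = 0.0;
    const double inv_dr = n_bins / r_max;
    for (int j = 0; j < n - 1; ++j) {
        const double xj = x[j], yj = y[j], zj = z[j], wj = w[j];
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[k] - xj, dy = y[k] - yj, dz = z[k] - zj;
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r > dmax) dmax = r;
            int bin = static_cast<int>(r * inv_dr);
            if (bin >= n_bins) bin = n_bins - 1;
            p[bin] += wj * w[k];
        }
    }
    return List::create(_["p"] = p, _["d_max"] = dmax);
}

// Largest pairwise distance only (used to size the histogram grid).
// [[Rcpp::export(name = ".max_pair_dist_cpp")]]
double max_pair_dist_cpp(NumericMatrix coords) {
    const int n = coords.nrow();
    const double *x = &coords(0, 0);
    const double *y = &coords(0, 1);
    const double *z = &coords(0, 2);
    double dmax = 0.0;
    for (int j = 0; j < n - 1; ++j) {
        const double xj = x[j], yj = y[j], zj = z[j];
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[k] - xj, dy = y[k] - yj, dz = z[k] - zj;
            const double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 > dmax) dmax = r2;
        }
    }
    return std::sqrt(dmax);
}
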
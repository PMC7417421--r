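#include <Rcpp.h>
using namespace Rcpp;

// Gaussian random walk confined to [-d, d] by redrawing the increment until
// the bound holds (truncation, not clipping). s(0) = 0. Degenerate cases
// (d = 0 or v = 0) short-circuit to the all-zero walk so the redraw loop
// always terminates.
// [[Rcpp::export(name = ".boundedWalkCpp")]]
NumericVector bounded_walk_cpp(int n, double d, double v) {
    NumericVector s(n);
    if (n <= 1 || d <= 0.0 || v <= 0.0)
        return s;
    for (int i = 1; i < n; ++i) {
        double z;
        do {
            z = s[i - 1] + R::rnorm(0.0, v);
        } while (std::fabs(z) > d);
        s[i] = z;
    }
    return s;
}
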
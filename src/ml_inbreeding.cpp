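#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) inbreeding recursion.
// sire/dam are 1-based indices into the (topologically sorted) pedigree,
// 0 for unknown. Animals with an unknown parent get F = 0 but still
// contribute their within-family variance D to descendants.
// [[Rcpp::export]]
NumericVector ml_inbreeding(IntegerVector sire, IntegerVector dam) {
    const int n = sire.size();
    // index 0 is the phantom unknown parent with F = -1 so that
    // D = 0.5 - 0.25 * (F_s + F_d) is correct when parents are unknown.
    std::vector<double> F(n + 1), D(n + 1), L(n + 1, 0.0);
    std::vector<int> point(n + 1, 0);
    F[0] = -1.0;

    for (int i = 1; i <= n; ++i) {
        const int s = sire[i - 1], d = dam[i - 1];
        if (s >= i || d >= i)
            stop("pedigree is not sorted with parents before offspring");
        D[i] = 0.5 - 0.25 * (F[s] + F[d]);
        if (s == 0 || d == 0) {
            F[i] = 0.0;
            continue;
        }
        double fi = -1.0;
        L[i] = 1.0;
        int j = i;
        while (j != 0) {
            int k = j;
            const double r = 0.5 * L[k];
            const int ks = sire[k - 1] > dam[k - 1] ? sire[k - 1] : dam[k - 1];
            const int kd = sire[k - 1] > dam[k - 1] ? dam[k - 1] : sire[k - 1];
            if (ks > 0) {
                while (point[k] > ks) k = point[k];
                L[ks] += r;
                if (ks != point[k]) {
                    point[ks] = point[k];
                    point[k] = ks;
                }
                if (kd > 0) {
                    while (point[k] > kd) k = point[k];
                    L[kd] += r;
                    if (kd != point[k]) {
                        point[kd] = point[k];
                        point[k] = kd;
                    }
                }
            }
            fi += L[j] * L[j] * D[j];
            L[j] = 0.0;
            k = j;
            j = point[j];
            point[k] = 0;
        }
        F[i] = fi;
    }
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = F[i + 1];
    return out;
}
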
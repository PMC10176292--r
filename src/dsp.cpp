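#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <vector>
using namespace Rcpp;

// Rolling peak-to-peak amplitude over windows of w rows, per column
// (monotonic-deque sliding max/min, O(n) per column).
// [[Rcpp::export(name = ".rollamp_cpp")]]
NumericMatrix rollamp_cpp(NumericMatrix X, int w) {
    int n = X.nrow(), k = X.ncol(), m = n - w + 1;
    NumericMatrix out(m, k);
    for (int j = 0; j < k; ++j) {
        std::deque<int> qmax, qmin;
        for (int i = 0; i < n; ++i) {
            double v = X(i, j);
            while (!qmax.empty() && X(qmax.back(), j) <= v) qmax.pop_back();
            qmax.push_back(i);
            while (!qmin.empty() && X(qmin.back(), j) >= v) qmin.pop_back();
            qmin.push_back(i);
            if (i >= w - 1) {
                while (qmax.front() <= i - w) qmax.pop_front();
                while (qmin.front() <= i - w) qmin.pop_front();
                out(i - w + 1, j) = X(qmax.front(), j) - X(qmin.front(), j);
            }
        }
    }
    return out;
}

// R type-7 quantile of a scratch vector (modified in place).
static double quantile7(std::vector<double>& v, double p) {
    double h = (v.size() - 1) * p;
    size_t lo = (size_t)std::floor(h);
    std::nth_element(v.begin(), v.begin() + lo, v.end());
    double xlo = v[lo];
    if (lo + 1 >= v.size()) return xlo;
    std::nth_element(v.begin() + lo + 1, v.begin() + lo + 1, v.end());
    return xlo + (h - lo) * (v[lo + 1] - xlo);
}

// Periodic Daubechies-2 analysis/synthesis on columns.
static void db2_filters(double* h, double* g) {
    const double s3 = std::sqrt(3.0), s2 = std::sqrt(2.0);
    h[0] = (1 + s3) / (4 * s2); h[1] = (3 + s3) / (4 * s2);
    h[2] = (3 - s3) / (4 * s2); h[3] = (1 - s3) / (4 * s2);
    g[0] = h[3]; g[1] = -h[2]; g[2] = h[1]; g[3] = -h[0];
}

// [[Rcpp::export(name = ".dwt_cpp")]]
List dwt_cpp(NumericMatrix X) {
    int n = X.nrow(), k = X.ncol(), n2 = n / 2;
    double h[4], g[4];
    db2_filters(h, g);
    NumericMatrix a(n2, k), d(n2, k);
    for (int j = 0; j < k; ++j) {
        for (int i = 0; i < n2; ++i) {
            double sa = 0, sd = 0;
            for (int t = 0; t < 4; ++t) {
                double v = X((2 * i + t) % n, j);
                sa += h[t] * v;
                sd += g[t] * v;
            }
            a(i, j) = sa;
            d(i, j) = sd;
        }
    }
    return List::create(_["a"] = a, _["d"] = d);
}

// Sample-level motion flags per column: sliding w-sample windows are marked
// when their peak-to-peak amplitude exceeds ampThresh or their SD exceeds
// sdFactor times the column's median rolling SD; window marks are expanded
// to the samples they cover and dilated by pad samples.
// [[Rcpp::export(name = ".motion_flags_cpp")]]
LogicalMatrix motion_flags_cpp(NumericMatrix X, int w, double ampThresh,
                               double sdFactor, int pad) {
    int n = X.nrow(), k = X.ncol();
    LogicalMatrix out(n, k);
    if (n < w) return out;
    int m = n - w + 1;
    std::vector<double> sds(m);
    std::vector<double> scratch(m);
    std::vector<int> winFlag(m), cum(n + 1);
    for (int j = 0; j < k; ++j) {
        // rolling SD via running sums
        double s1 = 0, s2 = 0;
        for (int i = 0; i < w; ++i) { s1 += X(i, j); s2 += X(i, j) * X(i, j); }
        for (int i = 0;; ++i) {
            double v = (s2 - s1 * s1 / w) / (w - 1);
            sds[i] = v > 0 ? std::sqrt(v) : 0.0;
            if (i + 1 >= m) break;
            double xout = X(i, j), xin = X(i + w, j);
            s1 += xin - xout;
            s2 += xin * xin - xout * xout;
        }
        scratch = sds;
        std::nth_element(scratch.begin(), scratch.begin() + m / 2, scratch.end());
        double med = scratch[m / 2];
        if (m % 2 == 0) {
            std::nth_element(scratch.begin(), scratch.begin() + m / 2 - 1,
                             scratch.begin() + m / 2);
            med = 0.5 * (med + scratch[m / 2 - 1]);
        }
        double sdThr = sdFactor * std::max(med, 1e-300);
        // rolling amplitude (monotonic deques)
        std::deque<int> qmax, qmin;
        for (int i = 0; i < n; ++i) {
            double v = X(i, j);
            while (!qmax.empty() && X(qmax.back(), j) <= v) qmax.pop_back();
            qmax.push_back(i);
            while (!qmin.empty() && X(qmin.back(), j) >= v) qmin.pop_back();
            qmin.push_back(i);
            if (i >= w - 1) {
                while (qmax.front() <= i - w) qmax.pop_front();
                while (qmin.front() <= i - w) qmin.pop_front();
                double amp = X(qmax.front(), j) - X(qmin.front(), j);
                winFlag[i - w + 1] = (amp > ampThresh || sds[i - w + 1] > sdThr);
            }
        }
        // windows -> samples, then dilate by pad, via prefix sums
        cum[0] = 0;
        for (int i = 0; i < m; ++i) cum[i + 1] = cum[i] + winFlag[i];
        std::vector<int> sf(n);
        for (int i = 0; i < n; ++i) {
            int lo = std::max(0, i - w + 1), hi = std::min(i, m - 1);
            sf[i] = (cum[hi + 1] - cum[lo]) > 0;
        }
        cum[0] = 0;
        for (int i = 0; i < n; ++i) cum[i + 1] = cum[i] + sf[i];
        for (int i = 0; i < n; ++i) {
            int lo = std::max(0, i - pad), hi = std::min(n - 1, i + pad);
            out(i, j) = (cum[hi + 1] - cum[lo]) > 0;
        }
    }
    return out;
}

// Full wavelet motion correction per column: multi-level periodic db2
// decomposition, zero detail coefficients farther than `iqrFactor` IQRs from
// their level median, reconstruct.  Depth limited by divisibility (shortest
// approximation >= 4) and capped at 8 levels.
// [[Rcpp::export(name = ".wavelet_correct_cpp")]]
NumericMatrix wavelet_correct_cpp(NumericMatrix X, double iqrFactor) {
    int n = X.nrow(), k = X.ncol();
    int depth = 0, len = n;
    while (len % 2 == 0 && len / 2 >= 4 && depth < 8) { len /= 2; ++depth; }
    NumericMatrix out(n, k);
    if (depth == 0) { std::copy(X.begin(), X.end(), out.begin()); return out; }
    double h[4], g[4];
    db2_filters(h, g);
    std::vector<std::vector<double> > details(depth);
    std::vector<double> a(n), next(n), scratch(n);
    for (int j = 0; j < k; ++j) {
        int m = n;
        for (int i = 0; i < n; ++i) a[i] = X(i, j);
        for (int lev = 0; lev < depth; ++lev) {
            int m2 = m / 2;
            details[lev].resize(m2);
            for (int i = 0; i < m2; ++i) {
                double sa = 0, sd = 0;
                for (int t = 0; t < 4; ++t) {
                    double v = a[(2 * i + t) % m];
                    sa += h[t] * v;
                    sd += g[t] * v;
                }
                next[i] = sa;
                details[lev][i] = sd;
            }
            std::copy(next.begin(), next.begin() + m2, a.begin());
            m = m2;
        }
        for (int lev = 0; lev < depth; ++lev) {
            std::vector<double>& d = details[lev];
            scratch.assign(d.begin(), d.end());
            double q1 = quantile7(scratch, 0.25);
            scratch.assign(d.begin(), d.end());
            double med = quantile7(scratch, 0.5);
            scratch.assign(d.begin(), d.end());
            double q3 = quantile7(scratch, 0.75);
            double thr = iqrFactor * (q3 - q1);
            for (size_t i = 0; i < d.size(); ++i)
                if (std::fabs(d[i] - med) > thr) d[i] = 0.0;
        }
        for (int lev = depth - 1; lev >= 0; --lev) {
            int m2 = n >> (lev + 1);
            std::fill(next.begin(), next.begin() + 2 * m2, 0.0);
            for (int i = 0; i < m2; ++i) {
                double av = a[i], dv = details[lev][i];
                for (int t = 0; t < 4; ++t) {
                    int p = (2 * i + t) % (2 * m2);
                    next[p] += h[t] * av + g[t] * dv;
                }
            }
            std::copy(next.begin(), next.begin() + 2 * m2, a.begin());
        }
        for (int i = 0; i < n; ++i) out(i, j) = a[i];
    }
    return out;
}

// [[Rcpp::export(name = ".idwt_cpp")]]
NumericMatrix idwt_cpp(NumericMatrix a, NumericMatrix d) {
    int n2 = a.nrow(), k = a.ncol(), n = 2 * n2;
    double h[4], g[4];
    db2_filters(h, g);
    NumericMatrix X(n, k);
    for (int j = 0; j < k; ++j) {
        for (int i = 0; i < n2; ++i) {
            double av = a(i, j), dv = d(i, j);
            for (int t = 0; t < 4; ++t) {
                int p = (2 * i + t) % n;
                X(p, j) += h[t] * av + g[t] * dv;
            }
        }
    }
    return X;
}
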
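#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimal deterministic SMO solver for the two-class soft-margin linear SVM
// (dual formulation, maximal-violating-pair working-set selection).  Problem
// sizes here are tiny (tens of patterns), so the full Gram matrix is held in
// memory and no shrinking or caching heuristics are needed.
//
//   min_a  0.5 * a' Q a - e' a,   0 <= a_i <= C,  y' a = 0,
//   Q_ij = y_i y_j x_i' x_j.
//
// Decision function: f(x) = w'x + b, prediction = sign(f).

struct LinearSVM {
    std::vector<double> w;
    double b;
    bool ok;
};

static LinearSVM solve_svm(const std::vector<double>& X, int n, int p,
                           const std::vector<double>& y, double C,
                           double eps = 1e-4, int max_iter = 10000) {
    LinearSVM out;
    out.ok = false;
    if (n < 2) return out;

    // Gram matrix
    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
            double s = 0.0;
            for (int k = 0; k < p; ++k) s += X[(size_t)i * p + k] * X[(size_t)j * p + k];
            K[(size_t)i * n + j] = s;
            K[(size_t)j * n + i] = s;
        }
    }

    std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = (Q a)_i - 1
    const double tau = 1e-12;

    int iter = 0;
    double m_up = 0.0, m_low = 0.0;
    while (iter++ < max_iter) {
        // second-order working-set selection (maximal violating pair for i,
        // maximal objective decrease for j)
        int i = -1, j = -1;
        m_up = -HUGE_VAL;
        m_low = HUGE_VAL;
        for (int t = 0; t < n; ++t) {
            double v = -y[t] * G[t];
            bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
            if (up && v > m_up) { m_up = v; i = t; }
            bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
            if (lo && v < m_low) m_low = v;
        }
        if (i < 0 || m_up - m_low < eps) break;
        double best = -HUGE_VAL;
        for (int t = 0; t < n; ++t) {
            bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
            if (!lo) continue;
            double b = m_up - (-y[t] * G[t]);
            if (b <= 0) continue;
            double a = K[(size_t)i * n + i] + K[(size_t)t * n + t] -
                       2.0 * K[(size_t)i * n + t];
            if (a <= 0) a = tau;
            double gain = b * b / a;
            if (gain > best) { best = gain; j = t; }
        }
        if (j < 0) break;

        double quad = K[(size_t)i * n + i] + K[(size_t)j * n + j] - 2.0 * K[(size_t)i * n + j];
        if (quad <= 0) quad = tau;
        double s = (m_up - (-y[j] * G[j])) / quad; // unconstrained step, s > 0

        // box constraints: a_i + y_i s in [0, C]; a_j - y_j s in [0, C]
        double smax = s;
        if (y[i] > 0) smax = std::min(smax, C - alpha[i]); else smax = std::min(smax, alpha[i]);
        if (y[j] > 0) smax = std::min(smax, alpha[j]); else smax = std::min(smax, C - alpha[j]);
        if (smax <= 0) break;

        double di = y[i] * smax, dj = -y[j] * smax;
        alpha[i] += di;
        alpha[j] += dj;
        for (int t = 0; t < n; ++t)
            G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * di + y[j] * K[(size_t)t * n + j] * dj) /
                    (y[i] * y[i]); // y in {-1,1}: factor is 1, kept explicit for clarity
    }

    // weight vector
    out.w.assign(p, 0.0);
    for (int i = 0; i < n; ++i) {
        if (alpha[i] != 0.0)
            for (int k = 0; k < p; ++k) out.w[k] += alpha[i] * y[i] * X[(size_t)i * p + k];
    }

    // intercept: average of y_t - F_t over free support vectors, else midpoint
    double bsum = 0.0;
    int nfree = 0;
    for (int t = 0; t < n; ++t) {
        if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * G[t]; ++nfree; }
    }
    out.b = nfree > 0 ? bsum / nfree : 0.5 * (m_up + m_low);
    out.ok = true;
    return out;
}

// [[Rcpp::export(name = ".svm_linear_cpp")]]
List svm_linear_cpp(NumericMatrix X, NumericVector y, double cost,
                    double eps = 1e-3) {
    int n = X.nrow(), p = X.ncol();
    std::vector<double> Xr((size_t)n * p), yy(n);
    for (int i = 0; i < n; ++i) {
        yy[i] = y[i];
        for (int k = 0; k < p; ++k) Xr[(size_t)i * p + k] = X(i, k);
    }
    LinearSVM m = solve_svm(Xr, n, p, yy, cost, eps);
    if (!m.ok) stop("SVM training failed: need at least 2 patterns");
    return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()), _["b"] = m.b);
}

// Leave-one-participant-out decoding over a pattern matrix with missing
// channels (NA entries).  Rows are participant x condition patterns (two per
// participant), columns are channels.  Per fold, the feature space is the set
// of channels available for the held-out participant, intersected (when
// `intersect` is true) with channels available for every training pattern;
// otherwise training participants with missing values on the kept channels
// are dropped pairwise.
static double lopo_core(const NumericMatrix& X, const IntegerVector& part,
                        const std::vector<double>& y, double cost, bool intersect,
                        double eps, IntegerVector* pred_out, int* nfolds_out) {
    int n = X.nrow(), p = X.ncol();
    int npart = 0;
    for (int i = 0; i < n; ++i) npart = std::max(npart, part[i]);

    int correct = 0, total = 0, nfolds = 0;
    std::vector<int> keep_col(p), train_rows;
    std::vector<double> Xtr, ytr;

    for (int pt = 1; pt <= npart; ++pt) {
        // columns available for the test participant (both of its rows finite)
        int nc = 0;
        std::fill(keep_col.begin(), keep_col.end(), 0);
        for (int k = 0; k < p; ++k) {
            bool okcol = true;
            for (int i = 0; i < n; ++i)
                if (part[i] == pt && !R_finite(X(i, k))) { okcol = false; break; }
            keep_col[k] = okcol ? 1 : 0;
        }
        if (intersect) {
            for (int k = 0; k < p; ++k) {
                if (!keep_col[k]) continue;
                for (int i = 0; i < n; ++i)
                    if (part[i] != pt && !R_finite(X(i, k))) { keep_col[k] = 0; break; }
            }
        }
        for (int k = 0; k < p; ++k) nc += keep_col[k];
        if (nc < 1) continue; // fold skipped

        // training rows: all other participants; under the test-only rule a
        // training participant missing any kept channel is dropped (both rows)
        train_rows.clear();
        std::vector<char> drop_part(npart + 1, 0);
        if (!intersect) {
            for (int i = 0; i < n; ++i) {
                if (part[i] == pt) continue;
                for (int k = 0; k < p; ++k)
                    if (keep_col[k] && !R_finite(X(i, k))) { drop_part[part[i]] = 1; break; }
            }
        }
        for (int i = 0; i < n; ++i)
            if (part[i] != pt && !drop_part[part[i]]) train_rows.push_back(i);
        if ((int)train_rows.size() < 2) continue;

        int ntr = (int)train_rows.size();
        Xtr.assign((size_t)ntr * nc, 0.0);
        ytr.resize(ntr);
        for (int r = 0; r < ntr; ++r) {
            int i = train_rows[r];
            ytr[r] = y[i];
            int c = 0;
            for (int k = 0; k < p; ++k)
                if (keep_col[k]) Xtr[(size_t)r * nc + c++] = X(i, k);
        }
        LinearSVM m = solve_svm(Xtr, ntr, nc, ytr, cost, eps);
        if (!m.ok) continue;
        ++nfolds;

        for (int i = 0; i < n; ++i) {
            if (part[i] != pt) continue;
            double f = m.b;
            int c = 0;
            for (int k = 0; k < p; ++k)
                if (keep_col[k]) f += m.w[c++] * X(i, k);
            int pr = f >= 0 ? 1 : -1;
            if (pred_out) (*pred_out)[i] = pr;
            if ((pr > 0) == (y[i] > 0)) ++correct;
            ++total;
        }
    }
    if (nfolds_out) *nfolds_out = nfolds;
    return total > 0 ? (double)correct / total : NA_REAL;
}

// [[Rcpp::export(name = ".lopo_cpp")]]
List lopo_cpp(NumericMatrix X, IntegerVector part, NumericVector y, double cost,
              bool intersect, double eps = 1e-3) {
    int n = X.nrow();
    std::vector<double> yy(y.begin(), y.end());
    IntegerVector pred(n, NA_INTEGER);
    int nfolds = 0;
    double acc = lopo_core(X, part, yy, cost, intersect, eps, &pred, &nfolds);
    return List::create(_["accuracy"] = acc, _["pred"] = pred, _["n_folds"] = nfolds);
}

// Permutation null: `flips` is n_perm x n_participants; a flipped participant
// has the labels of its two patterns exchanged before the LOPO accuracy is
// recomputed.
// [[Rcpp::export(name = ".perm_lopo_cpp")]]
NumericVector perm_lopo_cpp(NumericMatrix X, IntegerVector part, NumericVector y,
                            double cost, bool intersect, LogicalMatrix flips,
                            double eps = 1e-3) {
    int n = X.nrow(), nperm = flips.nrow();
    NumericVector acc(nperm);
    std::vector<double> yy(n);
    for (int b = 0; b < nperm; ++b) {
        for (int i = 0; i < n; ++i)
            yy[i] = flips(b, part[i] - 1) ? -y[i] : y[i];
        acc[b] = lopo_core(X, part, yy, cost, intersect, eps, nullptr, nullptr);
    }
    return acc;
}
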
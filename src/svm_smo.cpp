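#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// RBF-kernel C-SVC dual solver, SMO with second-order working-set selection
// (the libsvm algorithm, without shrinking or caching: the full kernel matrix
// is precomputed, which is fine at the problem sizes this package targets,
// n <= a few thousand).
//
// Dual: min 1/2 a'Qa - e'a  s.t. 0 <= a_i <= C, y'a = 0, Q_ij = y_i y_j K_ij,
// K(u,v) = exp(-gamma * ||u - v||^2).

static inline double rbf(const double *xi, const double *xj, int d,
                         double sqi, double sqj, double gamma) {
    double dot = 0.0;
    for (int k = 0; k < d; ++k) dot += xi[k] * xj[k];
    return std::exp(-gamma * (sqi + sqj - 2.0 * dot));
}

// [[Rcpp::export]]
List svc_train_cpp(NumericMatrix X, IntegerVector y, double cost, double gamma,
                   double eps = 1e-3, int max_iter = 200000) {
    const int n = X.nrow(), d = X.ncol();
    if (y.size() != n) stop("label length mismatch");
    for (int i = 0; i < n; ++i)
        if (y[i] != 1 && y[i] != -1) stop("labels must be +1/-1");
    const double C = cost;
    const double TAU = 1e-12;
    const double INF = std::numeric_limits<double>::infinity();

    // row-major copy of X for cache-friendly kernel evaluation
    std::vector<double> xr((size_t)n * d), sq(n, 0.0);
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
            double v = X(i, k);
            if (!std::isfinite(v)) stop("non-finite feature value");
            xr[(size_t)i * d + k] = v;
            s += v * v;
        }
        sq[i] = s;
    }
    std::vector<double> K((size_t)n * n);
    for (int i = 0; i < n; ++i) {
        K[(size_t)i * n + i] = 1.0;
        for (int j = i + 1; j < n; ++j) {
            double k = rbf(&xr[(size_t)i * d], &xr[(size_t)j * d], d,
                           sq[i], sq[j], gamma);
            K[(size_t)i * n + j] = k;
            K[(size_t)j * n + i] = k;
        }
    }

    std::vector<double> alpha(n, 0.0), G(n, -1.0);
    int iter = 0;
    while (iter < max_iter) {
        // i = argmax_{t in I_up} -y_t G_t
        double Gmax = -INF, Gmax2 = -INF;
        int i = -1;
        for (int t = 0; t < n; ++t) {
            bool up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
            if (up && -y[t] * G[t] >= Gmax) { Gmax = -y[t] * G[t]; i = t; }
        }
        if (i == -1) break;
        // j = argmin over I_low of the second-order objective decrease
        int j = -1;
        double obj_min = INF;
        const double *Ki = &K[(size_t)i * n];
        for (int t = 0; t < n; ++t) {
            bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
            if (!low) continue;
            double v = y[t] * G[t];
            if (v > Gmax2) Gmax2 = v;
            double diff = Gmax + v;
            if (diff > 0) {
                double quad = 2.0 - 2.0 * y[i] * y[t] * Ki[t]; // Kii=Ktt=1
                if (quad <= 0) quad = TAU;
                double dec = -(diff * diff) / quad;
                if (dec < obj_min) { obj_min = dec; j = t; }
            }
        }
        if (Gmax + Gmax2 < eps || j == -1) break;

        const double *Kj = &K[(size_t)j * n];
        double old_ai = alpha[i], old_aj = alpha[j];
        if (y[i] != y[j]) {
            double quad = 2.0 + 2.0 * Ki[j];
            if (quad <= 0) quad = TAU;
            double delta = (-G[i] - G[j]) / quad;
            double diff = alpha[i] - alpha[j];
            alpha[i] += delta; alpha[j] += delta;
            if (diff > 0) {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
            }
            if (diff > 0) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
            } else {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
            }
        } else {
            double quad = 2.0 - 2.0 * Ki[j];
            if (quad <= 0) quad = TAU;
            double delta = (G[i] - G[j]) / quad;
            double sum = alpha[i] + alpha[j];
            alpha[i] -= delta; alpha[j] += delta;
            if (sum > C) {
                if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
            } else {
                if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
            }
            if (sum > C) {
                if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
            } else {
                if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
            }
        }
        double dai = (alpha[i] - old_ai) * y[i], daj = (alpha[j] - old_aj) * y[j];
        for (int t = 0; t < n; ++t)
            G[t] += y[t] * (Ki[t] * dai + Kj[t] * daj);
        ++iter;
    }
    if (iter >= max_iter)
        warning("SMO reached the iteration cap (%d) before convergence", max_iter);

    // rho (offset): average y_t G_t over free SVs, else midpoint of the bounds
    double ub = INF, lb = -INF, sum_free = 0.0;
    int n_free = 0;
    for (int t = 0; t < n; ++t) {
        double yG = y[t] * G[t];
        if (alpha[t] >= C) {
            if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else if (alpha[t] <= 0) {
            if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
        } else {
            ++n_free; sum_free += yG;
        }
    }
    double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

    // keep support vectors only
    std::vector<int> sv_idx;
    for (int t = 0; t < n; ++t) if (alpha[t] > 0) sv_idx.push_back(t);
    int nsv = (int)sv_idx.size();
    NumericMatrix SV(nsv, d);
    NumericVector coef(nsv);
    for (int s = 0; s < nsv; ++s) {
        int t = sv_idx[s];
        coef[s] = alpha[t] * y[t];
        for (int k = 0; k < d; ++k) SV(s, k) = xr[(size_t)t * d + k];
    }
    double obj = 0.0;
    for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0) / 2.0;
    return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                        _["iterations"] = iter, _["n_sv"] = nsv,
                        _["objective"] = obj);
}

// decision values f(x) = sum_s coef_s K(sv_s, x) - rho
// [[Rcpp::export]]
NumericVector rbf_decision_cpp(NumericMatrix SV, NumericVector coef, double rho,
                               double gamma, NumericMatrix Xnew) {
    const int nsv = SV.nrow(), d = SV.ncol(), m = Xnew.nrow();
    if (m > 0 && Xnew.ncol() != d) stop("feature dimension mismatch");
    std::vector<double> svr((size_t)nsv * d), sqs(nsv, 0.0);
    for (int s = 0; s < nsv; ++s) {
        double ss = 0.0;
        for (int k = 0; k < d; ++k) {
            svr[(size_t)s * d + k] = SV(s, k);
            ss += SV(s, k) * SV(s, k);
        }
        sqs[s] = ss;
    }
    NumericVector out(m);
    std::vector<double> x(d);
    for (int i = 0; i < m; ++i) {
        double sx = 0.0;
        for (int k = 0; k < d; ++k) { x[k] = Xnew(i, k); sx += x[k] * x[k]; }
        double f = -rho;
        for (int s = 0; s < nsv; ++s)
            f += coef[s] * rbf(&svr[(size_t)s * d], &x[0], d, sqs[s], sx, gamma);
        out[i] = f;
    }
    return out;
}
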
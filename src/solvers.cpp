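// Numerical cores: multiplicative-update NMF, projected alternating
// least squares, and Lawson-Hanson non-negative least squares.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double frob(const mat& A, const mat& W, const mat& H) {
    return norm(A - W * H, "fro");
}

// Lee-Seung multiplicative updates for the Frobenius objective.
// Runs `steps` full (H, W) updates and records the objective after
// every step; the small epsilon only guards zero denominators.
// [[Rcpp::export(name = ".cpp_mu_nmf")]]
Rcpp::List cpp_mu_nmf(const arma::mat& A, arma::mat W, arma::mat H, int steps,
                      double eps = 1e-12) {
    vec obj(steps + 1);
    obj(0) = frob(A, W, H);
    for (int s = 0; s < steps; ++s) {
        H %= (W.t() * A) / (W.t() * W * H + eps);
        W %= (A * H.t()) / (W * H * H.t() + eps);
        obj(s + 1) = frob(A, W, H);
    }
    return Rcpp::List::create(Rcpp::Named("W") = W,
                              Rcpp::Named("H") = H,
                              Rcpp::Named("objective") = obj);
}

// Alternating least squares with non-negativity by projection
// (unconstrained normal-equation solve, negatives clipped to zero),
// the scheme of MATLAB's nnmf 'als' solver. A tiny ridge keeps the
// K x K systems solvable when a factor degenerates. The projection
// step is not formally monotone, so the best (W, H) pair seen --
// including the initial one -- is returned.
// [[Rcpp::export(name = ".cpp_als_nmf")]]
Rcpp::List cpp_als_nmf(const arma::mat& A, arma::mat W, arma::mat H,
                       double tol = 1e-6, int max_iter = 500) {
    const double ridge = 1e-10;
    const uword K = W.n_cols;
    mat eyeK = eye<mat>(K, K);
    double best_obj = frob(A, W, H);
    mat bestW = W, bestH = H;
    double prev = best_obj;
    int iters = 0;
    for (int it = 0; it < max_iter; ++it) {
        ++iters;
        mat G = W.t() * W;
        double scale = trace(G) / K;
        if (!(scale > 0)) scale = 1.0;
        mat Hn;
        bool ok = solve(Hn, G + ridge * scale * eyeK, W.t() * A,
                        solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok) Hn = pinv(G) * (W.t() * A);
        H = clamp(Hn, 0.0, datum::inf);

        mat Gh = H * H.t();
        double scale_h = trace(Gh) / K;
        if (!(scale_h > 0)) scale_h = 1.0;
        mat Wt;
        ok = solve(Wt, Gh + ridge * scale_h * eyeK, H * A.t(),
                   solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok) Wt = pinv(Gh) * (H * A.t());
        W = clamp(Wt.t(), 0.0, datum::inf);

        double cur = frob(A, W, H);
        if (!std::isfinite(cur)) break;
        if (cur < best_obj) { best_obj = cur; bestW = W; bestH = H; }
        double denom = std::max(prev, 1e-300);
        if (std::fabs(prev - cur) / denom < tol) { prev = cur; break; }
        prev = cur;
    }
    return Rcpp::List::create(Rcpp::Named("W") = bestW,
                              Rcpp::Named("H") = bestH,
                              Rcpp::Named("objective") = best_obj,
                              Rcpp::Named("iterations") = iters);
}

// Lawson-Hanson active-set NNLS: min ||Mx - b||_2 s.t. x >= 0.
static vec nnls_one(const mat& M, const vec& b, double tol) {
    const uword n = M.n_cols;
    vec x(n, fill::zeros);
    uvec passive(n, fill::zeros);     // 1 = in positive set
    vec w = M.t() * (b - M * x);
    uword iter = 0, max_iter = 10 * n + 30;
    while (true) {
        if (++iter > max_iter) break;
        // most violating zero-set coordinate
        double wmax = -datum::inf;
        sword t = -1;
        for (uword j = 0; j < n; ++j)
            if (!passive(j) && w(j) > wmax) { wmax = w(j); t = (sword) j; }
        if (t < 0 || wmax <= tol) break;
        passive((uword) t) = 1;
        while (true) {
            uvec P = find(passive == 1);
            if (P.is_empty()) { x.zeros(); break; }
            vec zP;
            bool ok = solve(zP, M.cols(P), b, solve_opts::no_approx);
            if (!ok) zP = pinv(M.cols(P)) * b;
            if (zP.min() > 0) {
                x.zeros();
                x(P) = zP;
                break;
            }
            // move as far as feasible, drop boundary coordinates
            double alpha = datum::inf;
            for (uword k = 0; k < P.n_elem; ++k) {
                if (zP(k) <= 0) {
                    double xj = x(P(k));
                    double a = xj / (xj - zP(k));
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < P.n_elem; ++k)
                x(P(k)) += alpha * (zP(k) - x(P(k)));
            for (uword k = 0; k < P.n_elem; ++k)
                if (x(P(k)) <= tol) { x(P(k)) = 0.0; passive(P(k)) = 0; }
        }
        w = M.t() * (b - M * x);
    }
    return x;
}

// [[Rcpp::export(name = ".cpp_nnls")]]
arma::vec cpp_nnls(const arma::mat& M, const arma::vec& b) {
    double tol = 10.0 * datum::eps * norm(M, 1) *
                 (double) std::max(M.n_rows, M.n_cols);
    return nnls_one(M, b, tol);
}

// One NNLS per column of B against a shared design matrix.
// [[Rcpp::export(name = ".cpp_nnls_cols")]]
arma::mat cpp_nnls_cols(const arma::mat& M, const arma::mat& B) {
    double tol = 10.0 * datum::eps * norm(M, 1) *
                 (double) std::max(M.n_rows, M.n_cols);
    mat X(M.n_cols, B.n_cols);
    for (uword i = 0; i < B.n_cols; ++i)
        X.col(i) = nnls_one(M, B.col(i), tol);
    return X;
}
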
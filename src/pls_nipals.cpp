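// NIPALS PLS1 and leave-one-out cross-validation kernels.
//
// With a single response the NIPALS inner relation closes in one step per
// factor: w_a = X'y (normalized), t_a = X w_a, p_a = X't_a / t't,
// q_a = y't_a / t't, then deflation of X (and y) by the rank-one update.
// Coefficients for every factor count 1..A are accumulated so cross-
// validation gets the whole PRESS curve from one pass per fold.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core fit on pre-centered data. Returns W, P, Q and the p x A matrix of
// regression vectors B(:, a) for models with 1..a factors.
static int nipals_pls1(const mat& X0, const vec& y0, int A,
                       mat& W, mat& P, vec& Q, mat& B) {
  const uword p = X0.n_cols;
  mat X = X0;
  vec y = y0;
  W.zeros(p, A); P.zeros(p, A); Q.zeros(A); B.zeros(p, A);
  int used = 0;
  for (int a = 0; a < A; ++a) {
    vec w = X.t() * y;
    double wn = norm(w);
    if (wn < 1e-14) break;               // response variance exhausted
    w /= wn;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-300) break;
    vec pv = X.t() * t / tt;
    double q = dot(y, t) / tt;
    X -= t * pv.t();
    y -= q * t;
    W.col(a) = w; P.col(a) = pv; Q(a) = q;
    ++used;
    // B_a = W_a (P_a' W_a)^{-1} q_a for the first a+1 factors
    mat Wa = W.cols(0, a);
    mat Pa = P.cols(0, a);
    vec qa = Q.subvec(0, a);
    vec R;
    bool ok = solve(R, trimatu(Pa.t() * Wa), qa, solve_opts::no_approx);
    if (!ok) { used = a; break; }
    B.col(a) = Wa * R;
  }
  // pad: extra factors add nothing once the response is exhausted
  for (int a = used; a < A; ++a) {
    B.col(a) = used > 0 ? B.col(used - 1) : vec(p, fill::zeros);
  }
  return used;
}

// [[Rcpp::export(name = "cpp_pls_fit")]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::vec& y, int n_factors) {
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W, P, B; vec Q;
  int used = nipals_pls1(Xc, yc, n_factors, W, P, Q, B);
  int k = used > 0 ? used : 1;
  mat Wu = W.cols(0, k - 1), Pu = P.cols(0, k - 1);
  mat T = Xc * Wu * inv(trimatu(Pu.t() * Wu));  // scores (orthogonal)
  return Rcpp::List::create(
    Rcpp::Named("x_mean") = xm.t(),
    Rcpp::Named("y_mean") = ym,
    Rcpp::Named("weights") = Wu,
    Rcpp::Named("x_loadings") = Pu,
    Rcpp::Named("y_loadings") = Q.subvec(0, k - 1),
    Rcpp::Named("coefficients") = B,   // p x A, per cumulative factor count
    Rcpp::Named("scores") = T,
    Rcpp::Named("n_factors_used") = used
  );
}

// Leave-one-out PRESS for factor counts 1..A_max. Each fold recenters on
// the training rows, refits and predicts the held-out sample.
// Returns PRESS(A) and the n x A matrix of LOO predictions.
// [[Rcpp::export(name = "cpp_loo_press")]]
Rcpp::List cpp_loo_press(const arma::mat& X, const arma::vec& y, int A_max) {
  const uword n = X.n_rows;
  mat pred(n, A_max, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    uvec keep = regspace<uvec>(0, n - 1);
    keep.shed_row(i);
    mat Xt = X.rows(keep);
    vec yt = y.elem(keep);
    rowvec xm = mean(Xt, 0);
    double ym = mean(yt);
    mat Xc = Xt.each_row() - xm;
    vec yc = yt - ym;
    mat W, P, B; vec Q;
    nipals_pls1(Xc, yc, A_max, W, P, Q, B);
    rowvec xi = X.row(i) - xm;
    pred.row(i) = xi * B + ym;
  }
  vec press(A_max);
  for (int a = 0; a < A_max; ++a) {
    vec r = pred.col(a) - y;
    press(a) = dot(r, r);
  }
  return Rcpp::List::create(
    Rcpp::Named("press") = press,
    Rcpp::Named("predictions") = pred
  );
}

// RMSECV of the PRESS-optimal factor count for each of a list of column
// subsets (used by the SiPLS exhaustive search and the MWPLS window scan).
// `subsets` is a list of 1-based integer index vectors into columns of X.
// Returns, per subset: best factor count and its RMSECV.
// [[Rcpp::export(name = "cpp_subset_rmsecv")]]
Rcpp::List cpp_subset_rmsecv(const arma::mat& X, const arma::vec& y,
                             const Rcpp::List& subsets, int A_max) {
  const int m = subsets.size();
  const uword n = X.n_rows;
  Rcpp::IntegerVector best_a(m);
  Rcpp::NumericVector best_rmsecv(m);
  for (int s = 0; s < m; ++s) {
    uvec cols = Rcpp::as<uvec>(subsets[s]) - 1;
    mat Xs = X.cols(cols);
    // factor cap: min(A_max, variable count - 1, n - 2) guards tiny windows
    int A = std::min(std::min((int)Xs.n_cols - 1, (int)n - 2), A_max);
    if (A < 1) A = 1;
    Rcpp::List lo = cpp_loo_press(Xs, y, A);
    vec press = lo["press"];
    uword ia = press.index_min();
    // ties go to fewer factors: relative 1e-8 band plus an absolute floor
    // at 1e-10 of the response sum of squares
    vec yc = y - mean(y);
    double tie = press(ia) * (1.0 + 1e-8) + 1e-10 * dot(yc, yc);
    for (uword a = 0; a < ia; ++a) {
      if (press(a) <= tie) { ia = a; break; }
    }
    best_a[s] = (int)ia + 1;
    best_rmsecv[s] = std::sqrt(press(ia) / (double)n);
  }
  return Rcpp::List::create(
    Rcpp::Named("n_factors") = best_a,
    Rcpp::Named("rmsecv") = best_rmsecv
  );
}
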
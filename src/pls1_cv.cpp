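// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// PLS1 (univariate-response NIPALS) cross-validation kernel.
// For every response column of Y and every repeat (column of `folds`),
// fits K = max(grid) components on each training fold and predicts the
// held-out samples for every component count in `grid`; returns the
// per-response mean (over repeats) out-of-fold Pearson r per grid entry.
// [[Rcpp::export(name = ".pls1_cv_r_cpp")]]
arma::mat pls1_cv_r_cpp(const arma::mat& X, const arma::mat& Y,
                        const arma::imat& folds, const arma::ivec& grid) {
    const int n = X.n_rows;
    const int kmax = arma::max(grid);
    const int nrep = folds.n_cols;
    const int ng = grid.n_elem;
    arma::mat out(Y.n_cols, ng, arma::fill::zeros);

    for (arma::uword m = 0; m < Y.n_cols; ++m) {
        arma::vec y = Y.col(m);
        arma::mat rsum(1, ng, arma::fill::zeros);
        for (int rep = 0; rep < nrep; ++rep) {
            arma::ivec fold = folds.col(rep);
            int nf = arma::max(fold);
            arma::mat pred(n, ng, arma::fill::zeros);
            for (int f = 1; f <= nf; ++f) {
                arma::uvec test = arma::find(fold == f);
                arma::uvec train = arma::find(fold != f);
                arma::mat Xt = X.rows(train);
                arma::vec yt = y.elem(train);
                arma::rowvec xm = arma::mean(Xt, 0);
                double ym = arma::mean(yt);
                Xt.each_row() -= xm;
                arma::vec yc = yt - ym;
                arma::mat W(X.n_cols, kmax, arma::fill::zeros);
                arma::mat P(X.n_cols, kmax, arma::fill::zeros);
                arma::vec Q(kmax, arma::fill::zeros);
                int kfit = 0;
                for (int a = 0; a < kmax; ++a) {
                    arma::vec w = Xt.t() * yc;
                    double nw = arma::norm(w);
                    if (nw < 1e-12) break;
                    w /= nw;
                    arma::vec t = Xt * w;
                    double tt = arma::dot(t, t);
                    if (tt < 1e-24) break;
                    arma::vec p = Xt.t() * t / tt;
                    double q = arma::dot(yc, t) / tt;
                    Xt -= t * p.t();
                    yc -= q * t;
                    W.col(a) = w; P.col(a) = p; Q(a) = q;
                    ++kfit;
                }
                arma::mat Xtest = X.rows(test);
                Xtest.each_row() -= xm;
                for (int gi = 0; gi < ng; ++gi) {
                    int k = std::min((int)grid(gi), kfit);
                    arma::vec predk(test.n_elem, arma::fill::value(ym));
                    if (k > 0) {
                        arma::mat Wk = W.cols(0, k - 1);
                        arma::mat Pk = P.cols(0, k - 1);
                        arma::vec B = Wk * arma::solve(Pk.t() * Wk,
                                                       Q.subvec(0, k - 1));
                        predk += Xtest * B;
                    }
                    pred.submat(test, arma::uvec{(arma::uword)gi}) = predk;
                }
            }
            for (int gi = 0; gi < ng; ++gi)
                rsum(0, gi) += arma::as_scalar(arma::cor(y, pred.col(gi)));
        }
        out.row(m) = rsum / nrep;
    }
    return out;
}
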
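// EM for the binomial-dosage admixture model:
//   d_il ~ Binomial(v_i, sum_k q_ik f_kl)
// E-step distributes observed alternate/reference allele copies over
// latent cluster origins; M-step re-estimates q and f. Missing dosages
// carry zero weight. The log-likelihood (binomial coefficient dropped)
// is non-decreasing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS_F = 1e-8;

// [[Rcpp::export(name = ".admixEM")]]
Rcpp::List admixEM(const arma::mat& D,     // N x L dosages, 0 where missing
                   const arma::mat& W,     // N x L observation mask (0/1)
                   const arma::vec& v,     // N ploidies
                   arma::mat Q,            // N x K init
                   arma::mat F,            // K x L init
                   int maxIter, double tol) {
    const uword N = D.n_rows, L = D.n_cols;
    mat V = repmat(v, 1, L) % W;           // observed allele copies
    mat Dm = D % W;
    mat Rm = V - Dm;                       // observed reference copies
    std::vector<double> trace;
    trace.reserve(maxIter > 0 ? maxIter : 1);
    double ll = -datum::inf;
    bool conv = false;
    for (int it = 0; it < maxIter; ++it) {
        mat P = clamp(Q * F, EPS_F, 1.0 - EPS_F);
        mat R1 = Dm / P;
        mat R2 = Rm / (1.0 - P);
        mat altNum = Q % (R1 * F.t());     // N x K expected alt copies
        mat refNum = Q % (R2 * (1.0 - F).t());
        mat tot = altNum + refNum;
        Q = tot.each_col() / sum(tot, 1);
        mat fNum = F % (Q.t() * R1);       // K x L
        mat fDen = fNum + (1.0 - F) % (Q.t() * R2);
        F = clamp(fNum / clamp(fDen, 1e-300, datum::inf),
                  EPS_F, 1.0 - EPS_F);
        mat Pn = clamp(Q * F, EPS_F, 1.0 - EPS_F);
        double llNew = accu(Dm % log(Pn) + Rm % log(1.0 - Pn));
        trace.push_back(llNew);
        if (std::isfinite(ll) &&
            std::fabs(llNew - ll) < tol * (std::fabs(ll) + 1e-3)) {
            ll = llNew; conv = true; break;
        }
        ll = llNew;
    }
    return Rcpp::List::create(Rcpp::Named("Q") = Q,
                              Rcpp::Named("F") = F,
                              Rcpp::Named("ll") = ll,
                              Rcpp::Named("conv") = conv,
                              Rcpp::Named("trace") = trace);
}
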
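// Conditional K-group log-rank statistic.
//
// All entry points expect the data pre-sorted by observed time (ascending);
// the R wrappers take care of ordering.  Group codes are 1..K.  The variance
// is the hypergeometric (conditional) form with the ties correction
// d_i (n_i - d_i) / (n_i - 1); risk sets at a tied time include patients
// censored at that time (events precede censorings).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Accumulate O, E (length K) and V (K x K) over the event times.
static void lr_accumulate(const NumericVector& time,
                          const IntegerVector& event,
                          const IntegerVector& group,
                          int K,
                          arma::vec& O, arma::vec& E, arma::mat& V)
{
    const int n = time.size();
    arma::vec atrisk(K, arma::fill::zeros);
    for (int i = 0; i < n; ++i) atrisk[group[i] - 1] += 1.0;

    arma::vec dg(K);
    int i = 0;
    while (i < n) {
        int j = i;
        double d = 0.0;
        dg.zeros();
        const double t = time[i];
        while (j < n && time[j] == t) {
            if (event[j]) {
                d += 1.0;
                dg[group[j] - 1] += 1.0;
            }
            ++j;
        }
        const double ntot = n - i;
        if (d > 0.0) {
            for (int g = 0; g < K; ++g) {
                O[g] += dg[g];
                E[g] += d * atrisk[g] / ntot;
            }
            // term is zero when n_i = 1 (single patient at risk)
            const double c = (ntot > 1.0) ? d * (ntot - d) / (ntot - 1.0) : 0.0;
            if (c > 0.0) {
                for (int g = 0; g < K; ++g) {
                    const double pg = atrisk[g] / ntot;
                    if (pg == 0.0) continue;
                    for (int h = 0; h < K; ++h) {
                        const double ph = atrisk[h] / ntot;
                        V(g, h) += c * pg * ((g == h ? 1.0 : 0.0) - ph);
                    }
                }
            }
        }
        for (int l = i; l < j; ++l) atrisk[group[l] - 1] -= 1.0;
        i = j;
    }
}

// Quadratic form z' Vhat^{-1} z on the first K-1 groups; pseudo-inverse
// when Vhat is singular.  Returns T, the rank of Vhat and a singular flag.
static void lr_quadform(const arma::vec& z, const arma::mat& V, int K,
                        double& T, int& rank, bool& singular)
{
    const int p = K - 1;
    arma::vec z1 = z.head(p);
    arma::mat Vh = V.submat(0, 0, p - 1, p - 1);

    rank = (int) arma::rank(Vh);
    singular = (rank < p);
    if (rank == 0) {            // no variability at all: statistic is zero
        T = 0.0;
        return;
    }
    arma::vec x;
    bool ok = false;
    if (!singular)
        ok = arma::solve(x, Vh, z1, arma::solve_opts::no_approx);
    if (!ok) {
        arma::mat Vinv = arma::pinv(Vh);
        x = Vinv * z1;
        singular = singular || !ok;
    }
    T = arma::dot(z1, x);
    if (T < 0.0) T = 0.0;       // numerical guard
}

// [[Rcpp::export(name = ".lr_stat_cpp")]]
List lr_stat_cpp(NumericVector time, IntegerVector event,
                 IntegerVector group, int K)
{
    arma::vec O(K, arma::fill::zeros), E(K, arma::fill::zeros);
    arma::mat V(K, K, arma::fill::zeros);
    lr_accumulate(time, event, group, K, O, E, V);

    double T;
    int rank;
    bool singular;
    lr_quadform(O - E, V, K, T, rank, singular);

    return List::create(_["observed"] = NumericVector(O.begin(), O.end()),
                        _["expected"] = NumericVector(E.begin(), E.end()),
                        _["var"]      = wrap(V),
                        _["statistic"] = T,
                        _["rank"]     = rank,
                        _["singular"] = singular);
}

// Batched statistic: one column of `labels` per label assignment (already in
// time-sorted patient order).  Used by the permutation and enumeration loops.
// [[Rcpp::export(name = ".lr_stat_batch_cpp")]]
NumericVector lr_stat_batch_cpp(NumericVector time, IntegerVector event,
                                IntegerMatrix labels, int K)
{
    const int B = labels.ncol();
    NumericVector out(B);
    arma::vec O(K), E(K);
    arma::mat V(K, K);
    for (int b = 0; b < B; ++b) {
        O.zeros(); E.zeros(); V.zeros();
        IntegerVector g = labels(_, b);
        lr_accumulate(time, event, g, K, O, E, V);
        double T;
        int rank;
        bool singular;
        lr_quadform(O - E, V, K, T, rank, singular);
        out[b] = T;
    }
    return out;
}
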
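#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mean transition matrix over discrete-gamma rate categories at distance d:
// M(d) = (1/K) * sum_k V diag(exp(lam * r_k * d)) Vinv, entries clamped to a
// tiny positive floor so logs are finite.
static arma::mat trans_avg(double d, const arma::mat& V, const arma::vec& lam,
                           const arma::mat& Vinv, const arma::vec& rates) {
  arma::mat M(20, 20, arma::fill::zeros);
  for (arma::uword k = 0; k < rates.n_elem; ++k) {
    arma::vec ev = arma::exp(lam * (rates[k] * d));
    M += V * arma::diagmat(ev) * Vinv;
  }
  M /= (double)rates.n_elem;
  M.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
  return M;
}

static double pair_nll(double d, const arma::mat& N, const arma::mat& V,
                       const arma::vec& lam, const arma::mat& Vinv,
                       const arma::vec& rates) {
  arma::mat M = trans_avg(d, V, lam, Vinv, rates);
  return -arma::accu(N % arma::log(M));
}

// Golden-section minimisation of the pairwise negative log-likelihood on
// [lo, hi] to absolute tolerance tol.
static double golden_min(const arma::mat& N, const arma::mat& V,
                         const arma::vec& lam, const arma::mat& Vinv,
                         const arma::vec& rates, double lo, double hi,
                         double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a);
  double x2 = a + gr * (b - a);
  double f1 = pair_nll(x1, N, V, lam, Vinv, rates);
  double f2 = pair_nll(x2, N, V, lam, Vinv, rates);
  while (b - a > tol) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = pair_nll(x1, N, V, lam, Vinv, rates);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = pair_nll(x2, N, V, lam, Vinv, rates);
    }
  }
  return 0.5 * (a + b);
}

// 20x20 substitution-pair count table for sequences x, y (codes 0..19; other
// codes = non-comparable site). Returns count of comparable sites in tot.
static arma::mat pair_counts(const IntegerMatrix& codes, int i1, int i2,
                             double& tot) {
  arma::mat N(20, 20, arma::fill::zeros);
  tot = 0.0;
  for (int s = 0; s < codes.ncol(); ++s) {
    int a = codes(i1, s), b = codes(i2, s);
    if (a >= 0 && b >= 0) { N(a, b) += 1.0; tot += 1.0; }
  }
  return N;
}

// Maximum-likelihood pairwise distances under WAG + discrete gamma.
// codes: nseq x nsites integer matrix (0..19, negative = gap/unknown).
// V, lam, Vinv: eigen-decomposition of the scaled rate matrix; rates: the
// discrete-gamma category rates. method 0: per-pair golden-section search to
// tol; method 1: shared log-spaced grid with parabolic refinement (used for
// bootstrap replicates, where topology-grade precision suffices).
// [[Rcpp::export]]
NumericMatrix dist_ml_core(IntegerMatrix codes, NumericMatrix V_,
                           NumericVector lam_, NumericMatrix Vinv_,
                           NumericVector rates_, double lo, double hi,
                           double tol, int method) {
  const int n = codes.nrow();
  arma::mat V(V_.begin(), 20, 20, false);
  arma::mat Vinv(Vinv_.begin(), 20, 20, false);
  arma::vec lam(lam_.begin(), 20, false);
  arma::vec rates(rates_.begin(), rates_.size(), false);
  NumericMatrix D(n, n);

  // shared grid for method 1
  int G = 48;
  std::vector<double> gd(G);
  std::vector<arma::mat> glogM;
  if (method == 1) {
    double llo = std::log(std::max(lo, 1e-4)), lhi = std::log(hi);
    glogM.reserve(G);
    for (int g = 0; g < G; ++g) {
      gd[g] = std::exp(llo + (lhi - llo) * g / (G - 1.0));
      glogM.push_back(arma::log(trans_avg(gd[g], V, lam, Vinv, rates)));
    }
  }

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double tot = 0.0;
      arma::mat N = pair_counts(codes, i, j, tot);
      if (tot < 1.0)
        stop("zero comparable sites between sequences %d and %d", i + 1, j + 1);
      double d;
      if (method == 1) {
        int best = 0; double bf = arma::datum::inf;
        std::vector<double> fg(G);
        for (int g = 0; g < G; ++g) {
          fg[g] = -arma::accu(N % glogM[g]);
          if (fg[g] < bf) { bf = fg[g]; best = g; }
        }
        if (best == 0) d = gd[0];
        else if (best == G - 1) d = gd[G - 1];
        else {
          // parabolic refinement in log-distance
          double x0 = std::log(gd[best - 1]), x1 = std::log(gd[best]),
                 x2 = std::log(gd[best + 1]);
          double f0 = fg[best - 1], f1 = fg[best], f2 = fg[best + 1];
          double denom = (x1 - x0) * (f1 - f2) - (x1 - x2) * (f1 - f0);
          if (std::fabs(denom) < 1e-12) d = gd[best];
          else {
            double xv = x1 - 0.5 * ((x1 - x0) * (x1 - x0) * (f1 - f2) -
                                    (x1 - x2) * (x1 - x2) * (f1 - f0)) / denom;
            if (xv < x0 || xv > x2) d = gd[best];
            else d = std::exp(xv);
          }
        }
      } else {
        d = golden_min(N, V, lam, Vinv, rates, lo, hi, tol);
      }
      if (d > hi) d = hi;
      if (d < lo) d = lo;
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}

// Negative log-likelihood of one aligned pair at distance d (exposed for the
// scalar wag_gamma_distance wrapper and for tests).
// [[Rcpp::export]]
double pair_nll_core(double d, NumericMatrix N_, NumericMatrix V_,
                     NumericVector lam_, NumericMatrix Vinv_,
                     NumericVector rates_) {
  arma::mat N(N_.begin(), 20, 20, false);
  arma::mat V(V_.begin(), 20, 20, false);
  arma::mat Vinv(Vinv_.begin(), 20, 20, false);
  arma::vec lam(lam_.begin(), 20, false);
  arma::vec rates(rates_.begin(), rates_.size(), false);
  return pair_nll(d, N, V, lam, Vinv, rates);
}
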
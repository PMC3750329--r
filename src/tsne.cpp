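// Exact O(n^2) t-SNE internals: per-point precision calibration by binary
// search on the conditional-distribution entropy, and the Student-t
// gradient-descent loop. Kept in C++ because every iteration touches all
// n^2 voxel pairs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Conditional affinities p_{j|i} for one row given precision beta,
// computed on distances shifted by their minimum for stability.
// Returns entropy (nats) and writes the normalized row.
static double row_affinities(const arma::rowvec& dshift, double beta,
                             arma::rowvec& p) {
  p = arma::exp(-beta * dshift);
  double sumP = arma::accu(p);
  double H = std::log(sumP) + beta * arma::accu(dshift % p) / sumP;
  p /= sumP;
  return H;
}

// [[Rcpp::export(name = ".cpp_calibrate")]]
List cpp_calibrate(const arma::mat& D, double perplexity, double tol,
                   int max_iter) {
  const int n = D.n_rows;
  arma::mat Pcond(n, n, arma::fill::zeros);
  arma::vec beta(n, arma::fill::ones);
  arma::vec realized(n);
  const double logU = std::log(perplexity);
  const double tol_nats = tol * std::log(2.0); // tol is on the log2 scale

  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    arma::uvec others = arma::find(all != (unsigned)i);
    arma::rowvec d = arma::conv_to<arma::rowvec>::from(D.row(i)).elem(others).t();
    double dmin = d.min();
    arma::rowvec dshift = d - dmin;
    double b = 1.0, bmin = -arma::datum::inf, bmax = arma::datum::inf;
    arma::rowvec p(n - 1);
    double H = row_affinities(dshift, b, p);
    int it = 0;
    while (std::abs(H - logU) > tol_nats && it < max_iter) {
      if (H > logU) { // entropy too high -> sharpen
        bmin = b;
        b = std::isfinite(bmax) ? 0.5 * (b + bmax) : b * 2.0;
      } else {
        bmax = b;
        b = std::isfinite(bmin) ? 0.5 * (b + bmin) : b * 0.5;
      }
      H = row_affinities(dshift, b, p);
      ++it;
    }
    beta(i) = b;
    realized(i) = std::exp(H); // perplexity = e^{H(nats)} = 2^{H(bits)}
    for (int k = 0; k < n - 1; ++k) Pcond(i, others(k)) = p(k);
  }
  return List::create(_["P_cond"] = Pcond, _["beta"] = beta,
                      _["realized_perplexity"] = realized);
}

// Student-t kernel numerators 1/(1+||yi-yj||^2), zero diagonal.
static arma::mat t_kernel(const arma::mat& Y) {
  arma::vec s = arma::sum(arma::square(Y), 1);
  arma::mat num = -2.0 * (Y * Y.t());
  num.each_col() += s;
  num.each_row() += s.t();
  num = 1.0 / (1.0 + arma::clamp(num, 0.0, arma::datum::inf));
  num.diag().zeros();
  return num;
}

static double kl_divergence(const arma::mat& P, const arma::mat& Q,
                            double floor_q) {
  double c = 0.0;
  const double* p = P.memptr();
  const double* q = Q.memptr();
  const arma::uword nn = P.n_elem;
  for (arma::uword k = 0; k < nn; ++k) {
    if (p[k] > 0.0) c += p[k] * std::log(p[k] / std::max(q[k], floor_q));
  }
  return c;
}

// [[Rcpp::export(name = ".cpp_tsne_grad")]]
List cpp_tsne_grad(const arma::mat& P, const arma::mat& Y, double floor_q,
                   bool want_cost) {
  arma::mat num = t_kernel(Y);
  double Z = arma::accu(num);
  arma::mat Q = num / Z;
  arma::mat PQ = (P - Q) % num;
  arma::vec rs = arma::sum(PQ, 1);
  arma::mat grad = 4.0 * (arma::diagmat(rs) * Y - PQ * Y);
  double cost = want_cost ? kl_divergence(P, Q, floor_q) : NA_REAL;
  return List::create(_["grad"] = grad, _["cost"] = cost);
}

// [[Rcpp::export(name = ".cpp_tsne_loop")]]
List cpp_tsne_loop(const arma::mat& P, const arma::mat& Y0, int n_iter,
                   double eta, double mom_early, double mom_late,
                   int switch_iter, double exag, int exag_iter,
                   double floor_q) {
  // Fused pair-loop over the upper triangle (P and the Student-t kernel are
  // symmetric): pass 1 accumulates the kernel normalizer Z, pass 2 adds each
  // pair's contribution to both endpoints' gradients. No n x n temporaries
  // beyond one triangular kernel buffer, which is what makes the exact
  // method usable at a few thousand voxels.
  const arma::uword n = Y0.n_rows, m = Y0.n_cols;
  arma::mat Y = Y0;
  arma::mat inc(n, m, arma::fill::zeros);
  arma::mat grad(n, m);
  arma::mat gains(n, m, arma::fill::ones); // per-coordinate adaptive rates
  std::vector<double> numbuf(n * (n - 1) / 2);
  for (int it = 1; it <= n_iter; ++it) {
    const double pfac = (it <= exag_iter) ? exag : 1.0;
    double Z = 0.0;
    arma::uword t = 0;
    if (m == 2) { // hot path for map-making
      const double* y0 = Y.colptr(0);
      const double* y1 = Y.colptr(1);
      for (arma::uword j = 1; j < n; ++j) {
        const double yj0 = y0[j], yj1 = y1[j];
        for (arma::uword i = 0; i < j; ++i, ++t) {
          const double d0 = y0[i] - yj0, d1 = y1[i] - yj1;
          const double nu = 1.0 / (1.0 + d0 * d0 + d1 * d1);
          numbuf[t] = nu;
          Z += nu;
        }
      }
    } else {
      for (arma::uword j = 1; j < n; ++j) {
        for (arma::uword i = 0; i < j; ++i, ++t) {
          double d2 = 0.0;
          for (arma::uword c = 0; c < m; ++c) {
            const double dd = Y(i, c) - Y(j, c);
            d2 += dd * dd;
          }
          const double nu = 1.0 / (1.0 + d2);
          numbuf[t] = nu;
          Z += nu;
        }
      }
    }
    Z *= 2.0; // both ordered pairs
    grad.zeros();
    t = 0;
    if (m == 2) {
      const double* y0 = Y.colptr(0);
      const double* y1 = Y.colptr(1);
      double* g0 = grad.colptr(0);
      double* g1 = grad.colptr(1);
      const double invZ = 1.0 / Z;
      for (arma::uword j = 1; j < n; ++j) {
        const double yj0 = y0[j], yj1 = y1[j];
        const double* pj = P.colptr(j);
        double a0 = 0.0, a1 = 0.0; // accumulate column j's contribution
        for (arma::uword i = 0; i < j; ++i, ++t) {
          const double nu = numbuf[t];
          const double g = (pfac * pj[i] - nu * invZ) * nu;
          const double f0 = g * (y0[i] - yj0);
          const double f1 = g * (y1[i] - yj1);
          g0[i] += f0;
          g1[i] += f1;
          a0 -= f0;
          a1 -= f1;
        }
        g0[j] += a0;
        g1[j] += a1;
      }
    } else {
      for (arma::uword j = 1; j < n; ++j) {
        for (arma::uword i = 0; i < j; ++i, ++t) {
          const double nu = numbuf[t];
          const double g = (pfac * P(i, j) - nu / Z) * nu;
          for (arma::uword c = 0; c < m; ++c) {
            const double f = g * (Y(i, c) - Y(j, c));
            grad(i, c) += f;
            grad(j, c) -= f;
          }
        }
      }
    }
    const double mom = (it <= switch_iter) ? mom_early : mom_late;
    // standard adaptive gains: grow when the gradient keeps direction
    // against the velocity, shrink when it flips
    for (arma::uword idx = 0; idx < gains.n_elem; ++idx) {
      const bool same = (grad(idx) > 0.0) == (inc(idx) > 0.0);
      gains(idx) = same ? std::max(gains(idx) * 0.8, 0.01) : gains(idx) + 0.2;
    }
    inc = mom * inc - eta * 4.0 * (gains % grad);
    Y += inc;
    Y.each_row() -= arma::mean(Y, 0); // keep the map centered
  }
  arma::mat num = t_kernel(Y);
  arma::mat Q = num / arma::accu(num);
  double cost = kl_divergence(P, Q, floor_q);
  return List::create(_["Y"] = Y, _["final_cost"] = cost);
}
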
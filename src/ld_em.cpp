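// EM for the haplotype-cluster mixture HMM on unphased diploid genotypes.
//
// Hidden state at marker m is the (unordered) pair of haplotype clusters
// carried by the two chromosomes of an individual; the computation uses the
// ordered-pair product chain (K^2 states), an exact reparameterisation.
// Per-chain transitions are "jump" moves: with probability rho_m the chain
// jumps and re-enters cluster k' with weight alpha_{m,k'}; otherwise it
// stays.  Emissions are Binomial on the cluster allele frequencies theta.
// The rank-one structure of the transition matrix makes every
// forward/backward step O(K^2).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// emission matrix E(k,l) = P(g | theta_mk, theta_ml) into out (K*K)
static inline void emission(int g, const double* th, int K, double* out) {
  if (g < 0) {            // missing
    for (int i = 0; i < K * K; i++) out[i] = 1.0;
    return;
  }
  for (int l = 0; l < K; l++) {
    const double tl = th[l];
    for (int k = 0; k < K; k++) {
      const double tk = th[k];
      double v;
      if (g == 0) v = (1.0 - tk) * (1.0 - tl);
      else if (g == 2) v = tk * tl;
      else v = tk * (1.0 - tl) + (1.0 - tk) * tl;
      out[k + K * l] = v;
    }
  }
}

// y(k',l') = sum_{k,l} x(k,l) T(k,k') T(l,l'),  T = (1-rho) I + rho 1 a'
static inline void fwd_transform(const double* x, double rho,
                                 const double* a, int K, double* y,
                                 double* work) {
  for (int l = 0; l < K; l++) {
    double cs = 0.0;
    const double* xc = x + K * l;
    for (int k = 0; k < K; k++) cs += xc[k];
    double* wc = work + K * l;
    for (int k = 0; k < K; k++)
      wc[k] = (1.0 - rho) * xc[k] + rho * a[k] * cs;
  }
  for (int k = 0; k < K; k++) {
    double rs = 0.0;
    for (int l = 0; l < K; l++) rs += work[k + K * l];
    for (int l = 0; l < K; l++)
      y[k + K * l] = (1.0 - rho) * work[k + K * l] + rho * a[l] * rs;
  }
}

// y(k,l) = sum_{k',l'} T(k,k') T(l,l') g(k',l')   (backward move)
static inline void bwd_transform(const double* g, double rho,
                                 const double* a, int K, double* y,
                                 double* work) {
  for (int l = 0; l < K; l++) {
    double s = 0.0;
    const double* gc = g + K * l;
    for (int k = 0; k < K; k++) s += a[k] * gc[k];
    double* wc = work + K * l;
    for (int k = 0; k < K; k++)
      wc[k] = (1.0 - rho) * gc[k] + rho * s;
  }
  for (int k = 0; k < K; k++) {
    double s = 0.0;
    for (int l = 0; l < K; l++) s += a[l] * work[k + K * l];
    for (int l = 0; l < K; l++)
      y[k + K * l] = (1.0 - rho) * work[k + K * l] + rho * s;
  }
}

// forward pass for one individual over scaled pair states; returns loglik
static double forward_ind(const int* g, int M, int K,
                          const double* theta,   // M x K, column-major
                          const double* alpha,   // M x K
                          const double* rho,
                          double* f,             // M * K * K, out
                          double* c,             // M, out
                          double* E, double* work, double* tmp,
                          double* th, double* a) {
  double ll = 0.0;
  for (int m = 0; m < M; m++) {
    double* fm = f + (size_t)m * K * K;
    for (int k = 0; k < K; k++) th[k] = theta[m + (size_t)M * k];
    emission(g[m], th, K, E);
    if (m == 0) {
      for (int k = 0; k < K; k++) a[k] = alpha[(size_t)M * k];
      for (int l = 0; l < K; l++)
        for (int k = 0; k < K; k++)
          fm[k + K * l] = a[k] * a[l] * E[k + K * l];
    } else {
      const double* fprev = f + (size_t)(m - 1) * K * K;
      for (int k = 0; k < K; k++) a[k] = alpha[m + (size_t)M * k];
      fwd_transform(fprev, rho[m], a, K, tmp, work);
      for (int i = 0; i < K * K; i++) fm[i] = tmp[i] * E[i];
    }
    double cm = 0.0;
    for (int i = 0; i < K * K; i++) cm += fm[i];
    if (!(cm > 0.0) || !std::isfinite(cm))
      stop("non-finite likelihood at marker %d", m + 1);
    for (int i = 0; i < K * K; i++) fm[i] /= cm;
    c[m] = cm;
    ll += std::log(cm);
  }
  return ll;
}

// [[Rcpp::export]]
List ld_em_cpp(IntegerMatrix G, NumericMatrix theta0, NumericMatrix alpha0,
               NumericVector rho0, int max_iter, double tol) {
  const int n = G.nrow(), M = G.ncol();
  const int K = theta0.ncol();
  NumericMatrix theta(clone(theta0)), alpha(clone(alpha0));
  NumericVector rho(clone(rho0));
  std::vector<double> llt;

  std::vector<double> f((size_t)M * K * K), c(M);
  std::vector<double> E(K * K), work(K * K), tmp(K * K), B(K * K), Bn(K * K);
  std::vector<double> gam(K * K), th(K), a(K), r(K), A(K);
  std::vector<int> g(M);

  double prev_ll = -INFINITY;
  for (int iter = 0; iter < max_iter; iter++) {
    std::vector<double> th_num((size_t)M * K, 0.0), th_den((size_t)M * K, 0.0);
    std::vector<double> jump((size_t)M * K, 0.0);
    std::vector<double> a1(K, 0.0);
    double ll = 0.0;

    for (int i = 0; i < n; i++) {
      for (int m = 0; m < M; m++) {
        int v = G(i, m);
        g[m] = (v == NA_INTEGER) ? -1 : v;
      }
      ll += forward_ind(g.data(), M, K, theta.begin(), alpha.begin(),
                        rho.begin(), f.data(), c.data(), E.data(),
                        work.data(), tmp.data(), th.data(), a.data());
      // backward + accumulate
      for (int idx = 0; idx < K * K; idx++) B[idx] = 1.0;
      for (int m = M - 1; m >= 0; m--) {
        const double* fm = f.data() + (size_t)m * K * K;
        for (int k = 0; k < K; k++) th[k] = theta[m + (size_t)M * k];
        emission(g[m], th.data(), K, E.data());
        double gs = 0.0;
        for (int idx = 0; idx < K * K; idx++) {
          gam[idx] = fm[idx] * B[idx];
          gs += gam[idx];
        }
        for (int idx = 0; idx < K * K; idx++) gam[idx] /= gs;
        if (g[m] >= 0) {
          for (int k = 0; k < K; k++) {
            double num = 0.0, den = 0.0;
            for (int l = 0; l < K; l++) {
              const double gkl = gam[k + K * l];
              den += gkl;
              if (g[m] == 2) num += gkl;
              else if (g[m] == 1) {
                const double e = E[k + K * l];
                if (e > 0) num += gkl * (th[k] * (1.0 - th[l]) / e);
              }
            }
            th_num[m + (size_t)M * k] += 2.0 * num;
            th_den[m + (size_t)M * k] += 2.0 * den;
          }
        }
        if (m == 0) {
          for (int k = 0; k < K; k++) {
            double s = 0.0;
            for (int l = 0; l < K; l++) s += gam[k + K * l];
            a1[k] += s;
          }
        } else {
          // expected jump arrivals at interval (m-1, m):
          // J1(k') = rho a(k') sum_{l'} A(l') E(k',l') B(k',l') / Z with
          // A(l') = sum_l r(l) T(l,l'), r = column sums of f_{m-1}, and
          // Z the total pair-transition mass (both chains counted, x2).
          const double* fprev = f.data() + (size_t)(m - 1) * K * K;
          const double rm = rho[m];
          for (int k = 0; k < K; k++) a[k] = alpha[m + (size_t)M * k];
          double rsum = 0.0;
          for (int l = 0; l < K; l++) {
            double s = 0.0;
            for (int k = 0; k < K; k++) s += fprev[k + K * l];
            r[l] = s;
            rsum += s;
          }
          for (int lp = 0; lp < K; lp++)
            A[lp] = (1.0 - rm) * r[lp] + rm * a[lp] * rsum;
          fwd_transform(fprev, rm, a.data(), K, tmp.data(), work.data());
          double Z = 0.0;
          for (int idx = 0; idx < K * K; idx++)
            Z += tmp[idx] * E[idx] * B[idx];
          if (Z > 0) {
            for (int kp = 0; kp < K; kp++) {
              double s = 0.0;
              for (int lp = 0; lp < K; lp++)
                s += A[lp] * E[kp + K * lp] * B[kp + K * lp];
              jump[m + (size_t)M * kp] += 2.0 * rm * a[kp] * s / Z;
            }
          }
          // backward recursion to marker m-1
          for (int idx = 0; idx < K * K; idx++) Bn[idx] = E[idx] * B[idx];
          bwd_transform(Bn.data(), rm, a.data(), K, B.data(), work.data());
          const double cm = c[m];
          for (int idx = 0; idx < K * K; idx++) B[idx] /= cm;
        }
      }
    }

    llt.push_back(ll);
    // M-step (closed form; clipping keeps parameters inside the model,
    // constrained maximization preserves EM monotonicity)
    for (int m = 0; m < M; m++)
      for (int k = 0; k < K; k++) {
        const size_t idx = m + (size_t)M * k;
        if (th_den[idx] > 1e-12) {
          double t = th_num[idx] / th_den[idx];
          theta(m, k) = std::min(1.0 - 1e-6, std::max(1e-6, t));
        }
      }
    double a1s = 0.0;
    for (int k = 0; k < K; k++) a1s += a1[k];
    if (a1s > 0) for (int k = 0; k < K; k++) alpha(0, k) = a1[k] / a1s;
    for (int m = 1; m < M; m++) {
      double tj = 0.0;
      for (int k = 0; k < K; k++) tj += jump[m + (size_t)M * k];
      rho[m] = std::min(0.5, std::max(1e-6, tj / (2.0 * n)));
      if (tj > 1e-12)
        for (int k = 0; k < K; k++) alpha(m, k) = jump[m + (size_t)M * k] / tj;
    }
    if (iter > 0 && ll - prev_ll < tol) { prev_ll = ll; break; }
    prev_ll = ll;
  }

  return List::create(_["theta"] = theta, _["alpha"] = alpha,
                      _["rho"] = rho,
                      _["loglik"] = NumericVector(llt.begin(), llt.end()));
}

// [[Rcpp::export]]
List ld_posterior_cpp(IntegerMatrix G, NumericMatrix theta,
                      NumericMatrix alpha, NumericVector rho) {
  const int n = G.nrow(), M = G.ncol();
  const int K = theta.ncol();
  // counts(i, m, k): expected number of chromosomes of i in cluster k at m
  NumericVector counts(Dimension(n, M, K));
  NumericVector loglik(n);

  std::vector<double> f((size_t)M * K * K), c(M);
  std::vector<double> E(K * K), work(K * K), tmp(K * K), B(K * K), Bn(K * K);
  std::vector<double> gam(K * K), th(K), a(K);
  std::vector<int> g(M);

  for (int i = 0; i < n; i++) {
    for (int m = 0; m < M; m++) {
      int v = G(i, m);
      g[m] = (v == NA_INTEGER) ? -1 : v;
    }
    loglik[i] = forward_ind(g.data(), M, K, theta.begin(), alpha.begin(),
                            rho.begin(), f.data(), c.data(), E.data(),
                            work.data(), tmp.data(), th.data(), a.data());
    for (int idx = 0; idx < K * K; idx++) B[idx] = 1.0;
    for (int m = M - 1; m >= 0; m--) {
      const double* fm = f.data() + (size_t)m * K * K;
      double gs = 0.0;
      for (int idx = 0; idx < K * K; idx++) {
        gam[idx] = fm[idx] * B[idx];
        gs += gam[idx];
      }
      for (int idx = 0; idx < K * K; idx++) gam[idx] /= gs;
      for (int k = 0; k < K; k++) {
        double s = 0.0;
        for (int l = 0; l < K; l++) s += gam[k + K * l] + gam[l + K * k];
        counts[i + (size_t)n * m + (size_t)n * M * k] = s;
      }
      if (m > 0) {
        for (int k = 0; k < K; k++) {
          th[k] = theta[m + (size_t)M * k];
          a[k] = alpha[m + (size_t)M * k];
        }
        emission(g[m], th.data(), K, E.data());
        for (int idx = 0; idx < K * K; idx++) Bn[idx] = E[idx] * B[idx];
        bwd_transform(Bn.data(), rho[m], a.data(), K, B.data(), work.data());
        const double cm = c[m];
        for (int idx = 0; idx < K * K; idx++) B[idx] /= cm;
      }
    }
  }
  return List::create(_["counts"] = counts, _["loglik"] = loglik);
}
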
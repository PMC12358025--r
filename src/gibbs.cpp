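// Gibbs sampler for the admixture model with K ancestral clusters.
//
// Data: n diploid individuals x L unlinked loci; each gene copy carries a
// 0-based allele index (-1 = missing). Latent state: the cluster of origin
// z of every gene copy, cluster allele frequencies P, ancestry proportions
// Q. Under the correlated-frequency (F-) model, cluster frequencies at each
// locus are Dirichlet-distributed around ancestral frequencies pA with
// per-cluster drift F_k; pA and F_k get Metropolis updates. Uses R's RNG so
// set.seed() makes runs reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double runif01() { return R::unif_rand(); }

// Dirichlet draw via gamma variates; clamps away from 0 so that
// log-densities stay finite.
static void rdirichlet(const std::vector<double>& shape, double* out) {
  int J = shape.size();
  double tot = 0.0;
  for (int j = 0; j < J; ++j) {
    double s = shape[j] > 1e-8 ? shape[j] : 1e-8;
    out[j] = R::rgamma(s, 1.0);
    if (out[j] < 1e-12) out[j] = 1e-12;
    tot += out[j];
  }
  for (int j = 0; j < J; ++j) out[j] /= tot;
}

// log Dirichlet(alpha) density at p (both length J)
static double ldirichlet(const double* p, const std::vector<double>& alpha,
                         int J) {
  double asum = 0.0, ld = 0.0;
  for (int j = 0; j < J; ++j) {
    double a = alpha[j] > 1e-8 ? alpha[j] : 1e-8;
    asum += a;
    ld += (a - 1.0) * std::log(p[j]) - R::lgammafn(a);
  }
  return ld + R::lgammafn(asum);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(IntegerMatrix A, IntegerMatrix B, IntegerVector J, int K,
                int burn_in, int n_iter, bool correlated, double alpha,
                bool infer_alpha, double lambda) {
  const int n = A.nrow(), L = A.ncol();
  RNGScope scope;

  // P[l] stored row-major K x J[l]; pA[l] length J[l]
  std::vector<std::vector<double>> P(L), pA(L), cntP(L);
  std::vector<double> F(K, 0.1);
  NumericMatrix Q(n, K);
  for (int l = 0; l < L; ++l) {
    P[l].assign((size_t)K * J[l], 1.0 / J[l]);
    pA[l].assign(J[l], 1.0 / J[l]);
    cntP[l].assign((size_t)K * J[l], 0.0);
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;

  NumericMatrix Qsum(n, K);
  std::vector<std::vector<double>> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l].assign((size_t)K * J[l], 0.0);
  std::vector<double> ll_trace;
  ll_trace.reserve(n_iter);

  std::vector<double> w(K), shape, aprop, cur, cntQ((size_t)n * K);
  const double pa_conc = 50.0;    // Dirichlet proposal concentration for pA
  const double f_step = 0.05;     // RW step for drift F

  int total = burn_in + n_iter;
  for (int sweep = 0; sweep < total; ++sweep) {
    // (a) allele-origin assignment z for every gene copy, accumulating counts
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    for (int l = 0; l < L; ++l)
      std::fill(cntP[l].begin(), cntP[l].end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int alleles[2] = { A(i, l), B(i, l) };
        for (int c = 0; c < 2; ++c) {
          int a = alleles[c];
          if (a < 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[l][(size_t)k * J[l] + a];
            tot += w[k];
          }
          double u = runif01() * tot, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += w[k];
            if (u <= acc) { z = k; break; }
          }
          cntQ[(size_t)i * K + z] += 1.0;
          cntP[l][(size_t)z * J[l] + a] += 1.0;
        }
      }
    }

    // (b) cluster allele frequencies P | z
    for (int l = 0; l < L; ++l) {
      int Jl = J[l];
      shape.resize(Jl);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < Jl; ++j) {
          double prior = correlated ? pA[l][j] * (1.0 - F[k]) / F[k] : lambda;
          shape[j] = prior + cntP[l][(size_t)k * Jl + j];
        }
        rdirichlet(shape, &P[l][(size_t)k * Jl]);
      }
    }

    if (correlated) {
      // (b') ancestral frequencies pA | P, F : Metropolis with Dirichlet
      // proposal centred on the current value (flat Dirichlet prior).
      for (int l = 0; l < L; ++l) {
        int Jl = J[l];
        cur = pA[l];
        shape.resize(Jl);
        for (int j = 0; j < Jl; ++j) shape[j] = pa_conc * cur[j];
        aprop.resize(Jl);
        rdirichlet(shape, aprop.data());
        double lr = 0.0;
        std::vector<double> ap(Jl), ac(Jl);
        for (int k = 0; k < K; ++k) {
          double s = (1.0 - F[k]) / F[k];
          for (int j = 0; j < Jl; ++j) {
            ap[j] = aprop[j] * s;
            ac[j] = cur[j] * s;
          }
          const double* pk = &P[l][(size_t)k * Jl];
          lr += ldirichlet(pk, ap, Jl) - ldirichlet(pk, ac, Jl);
        }
        // proposal asymmetry q(cur | prop) - q(prop | cur)
        std::vector<double> sp(Jl), sc(Jl);
        for (int j = 0; j < Jl; ++j) {
          sp[j] = pa_conc * aprop[j];
          sc[j] = pa_conc * cur[j];
        }
        lr += ldirichlet(cur.data(), sp, Jl) -
              ldirichlet(aprop.data(), sc, Jl);
        if (std::log(runif01()) < lr) pA[l] = aprop;
      }
      // (b'') drift F_k | P, pA : random-walk Metropolis, uniform(0, 0.5)
      for (int k = 0; k < K; ++k) {
        double fp = F[k] + R::norm_rand() * f_step;
        if (fp <= 0.001 || fp >= 0.5) continue;
        double lr = 0.0;
        for (int l = 0; l < L; ++l) {
          int Jl = J[l];
          std::vector<double> ap(Jl), ac(Jl);
          for (int j = 0; j < Jl; ++j) {
            ap[j] = pA[l][j] * (1.0 - fp) / fp;
            ac[j] = pA[l][j] * (1.0 - F[k]) / F[k];
          }
          const double* pk = &P[l][(size_t)k * Jl];
          lr += ldirichlet(pk, ap, Jl) - ldirichlet(pk, ac, Jl);
        }
        if (std::log(runif01()) < lr) F[k] = fp;
      }
    }

    // (c) ancestry proportions Q | z
    for (int i = 0; i < n; ++i) {
      shape.resize(K);
      for (int k = 0; k < K; ++k) shape[k] = alpha + cntQ[(size_t)i * K + k];
      std::vector<double> qrow(K);
      rdirichlet(shape, qrow.data());
      for (int k = 0; k < K; ++k) Q(i, k) = qrow[k];
    }

    // (c') symmetric Dirichlet parameter alpha | Q : random-walk Metropolis
    // with uniform prior on (0, 10)
    if (infer_alpha && K > 1) {
      double ap = alpha + R::norm_rand() * 0.05;
      if (ap > 1e-4 && ap < 10.0) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        double lr = n * (R::lgammafn(K * ap) - K * R::lgammafn(ap))
                  - n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
                  + (ap - alpha) * slq;
        if (std::log(runif01()) < lr) alpha = ap;
      }
    }

    if (sweep >= burn_in) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          int alleles[2] = { A(i, l), B(i, l) };
          for (int c = 0; c < 2; ++c) {
            int a = alleles[c];
            if (a < 0) continue;
            double m = 0.0;
            for (int k = 0; k < K; ++k)
              m += Q(i, k) * P[l][(size_t)k * J[l] + a];
            ll += std::log(m);
          }
        }
      }
      ll_trace.push_back(ll);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (size_t t = 0; t < Psum[l].size(); ++t) Psum[l][t] += P[l][t];
    }
  }

  double inv = 1.0 / n_iter;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) *= inv;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix Pm(K, J[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J[l]; ++j)
        Pm(k, j) = Psum[l][(size_t)k * J[l] + j] * inv;
    Pout[l] = Pm;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout,
                      _["ll_trace"] = NumericVector(ll_trace.begin(),
                                                    ll_trace.end()),
                      _["F"] = NumericVector(F.begin(), F.end()),
                      _["alpha"] = alpha);
}
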
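#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the classic no-admixture-LD, independent-allele-frequency
// admixture model on haploid-coded biallelic genotypes.
//
//   g[i,l] in {0,1,NA}; z[i,l] in 1..K (origin of the single allele copy);
//   p[k,l] ~ Beta(1,1); q[i,] ~ Dirichlet(alpha).
//
// Updates:
//   z | q,p : categorical, P(k) propto q[i,k] * p[k,l]^g * (1-p[k,l])^(1-g)
//   q | z   : Dirichlet(alpha + n_ik)
//   p | z,g : Beta(1 + alt_kl, 1 + ref_kl)
//
// Missing cells are skipped everywhere. The recorded log-likelihood is the
// observed-data mixture likelihood log P(X | p, q).
// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix geno, int K, int n_sweeps, int burnin,
                         int thin, double alpha) {
  int N = geno.nrow(), L = geno.ncol();
  std::vector<int> z(N * L, -1);
  std::vector<double> p(K * L), q(N * K, 1.0 / K);
  std::vector<double> qsum(N * K, 0.0);
  std::vector<int> n_ik(N * K), alt_kl(K * L), tot_kl(K * L);
  std::vector<double> prob(K);
  std::vector<double> ll_trace;

  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      p[k * L + l] = unif_rand();

  int n_rec = 0;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    std::fill(n_ik.begin(), n_ik.end(), 0);
    std::fill(alt_kl.begin(), alt_kl.end(), 0);
    std::fill(tot_kl.begin(), tot_kl.end(), 0);

    // z update + sufficient statistics
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = geno(i, l);
        if (g == NA_INTEGER) continue;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double pk = p[k * L + l];
          double lik = g ? pk : 1.0 - pk;
          prob[k] = q[i * K + k] * lik;
          tot += prob[k];
        }
        double u = unif_rand() * tot, acc = 0.0;
        int pick = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += prob[k];
          if (u <= acc) { pick = k; break; }
        }
        z[i * L + l] = pick;
        n_ik[i * K + pick] += 1;
        tot_kl[pick * L + l] += 1;
        if (g) alt_kl[pick * L + l] += 1;
      }
    }

    // q update (normalized gamma draws)
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = R::rgamma(alpha + n_ik[i * K + k], 1.0);
        q[i * K + k] = d;
        s += d;
      }
      for (int k = 0; k < K; ++k) q[i * K + k] /= s;
    }

    // p update
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int a = alt_kl[k * L + l], t = tot_kl[k * L + l];
        p[k * L + l] = R::rbeta(1.0 + a, 1.0 + (t - a));
      }

    if (sweep > burnin && ((sweep - burnin) % thin == 0)) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i)
        for (int l = 0; l < L; ++l) {
          int g = geno(i, l);
          if (g == NA_INTEGER) continue;
          double m = 0.0;
          for (int k = 0; k < K; ++k) {
            double pk = p[k * L + l];
            m += q[i * K + k] * (g ? pk : 1.0 - pk);
          }
          ll += std::log(m);
        }
      ll_trace.push_back(ll);
      for (int i = 0; i < N * K; ++i) qsum[i] += q[i];
      ++n_rec;
    }
  }

  NumericMatrix Q(N, K);
  if (n_rec > 0) {
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += qsum[i * K + k];
      for (int k = 0; k < K; ++k) Q(i, k) = qsum[i * K + k] / s;
    }
  }
  return List::create(_["Q"] = Q,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["recorded"] = n_rec);
}
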
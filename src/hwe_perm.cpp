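#include <Rcpp.h>
using namespace Rcpp;

// Conditional-probability statistic of a genotype table given allele counts
// (Levene / Guo-Thompson): up to a constant, T = h*log(2) - sum(lgamma(n_ij+1))
// where h is the number of heterozygotes. Larger T = more probable table.
static double table_stat(const std::vector<int> &counts, int k) {
  double t = 0.0;
  for (int i = 0; i < k; ++i) {
    for (int j = i; j < k; ++j) {
      int n = counts[i * k + j];
      if (n > 0) {
        t -= lgamma((double)n + 1.0);
        if (i != j) t += (double)n * M_LN2;
      }
    }
  }
  return t;
}

// Monte-Carlo exact HWE test core: shuffles the 2n alleles into n pairs B
// times and counts permuted tables as or less probable than the observed one.
// a1/a2: 0-based allele codes of the observed genotypes. Uses R's RNG.
// [[Rcpp::export]]
int hwe_perm_count(IntegerVector a1, IntegerVector a2, int k, int B) {
  int n = a1.size();
  std::vector<int> counts((size_t)k * k, 0);
  std::vector<int> pool; pool.reserve(2 * n);
  for (int s = 0; s < n; ++s) {
    int i = a1[s], j = a2[s];
    if (i > j) std::swap(i, j);
    counts[i * k + j] += 1;
    pool.push_back(a1[s]);
    pool.push_back(a2[s]);
  }
  const double t_obs = table_stat(counts, k);
  const double eps = 1e-12;
  int m = 2 * n;
  int n_le = 0;
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates shuffle, then pair consecutive alleles
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(pool[i], pool[j]);
    }
    std::fill(counts.begin(), counts.end(), 0);
    for (int s = 0; s < n; ++s) {
      int i = pool[2 * s], j = pool[2 * s + 1];
      if (i > j) std::swap(i, j);
      counts[i * k + j] += 1;
    }
    if (table_stat(counts, k) <= t_obs + eps) ++n_le;
  }
  return n_le;
}
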
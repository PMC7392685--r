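// Monte Carlo engines for the exact genotype-level tests.
//
// hwe_chain_cpp: random-transposition Markov chain over pairings of the 2n
// allele copies. The conditional (Levene) distribution of a genotype array
// given the allele counts is proportional to the number of pairings that
// realise the array, so a chain that is uniform over pairings induces
// exactly the Levene distribution on arrays. Each step transposes two
// uniformly chosen allele copies (a no-op when both fall in the same
// individual), which keeps the chain aperiodic and reversible.
//
// ld_perm_cpp: permutation null for the two-locus genotypic independence
// G test; one locus' single-locus genotypes are shuffled among individuals.
//
// Both use R's RNG, so results are reproducible via set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int cell(int i, int j, int k) {
  if (i > j) std::swap(i, j);
  return i * k + j;
}

// [[Rcpp::export]]
List hwe_chain_cpp(IntegerVector pairing, int k, double logp_obs, int h_obs,
                   int dememorization, int batches, int iter_per_batch) {
  int twoN = pairing.size();
  std::vector<int> g(pairing.begin(), pairing.end());
  std::vector<int> counts(k * k, 0);
  int H = 0;
  double logp_nf = 0.0; // -sum lgamma(n_ij + 1)
  for (int p = 0; p < twoN; p += 2) {
    counts[cell(g[p], g[p + 1], k)]++;
    if (g[p] != g[p + 1]) H++;
  }
  for (int i = 0; i < k; i++)
    for (int j = i; j < k; j++)
      logp_nf -= lgamma(counts[cell(i, j, k)] + 1.0);
  const double LOG2 = std::log(2.0);
  const double tol = 1e-9;

  NumericVector bp(batches), bex(batches), bdef(batches);
  long step_total = (long)dememorization +
                    (long)batches * (long)iter_per_batch;
  int batch = -1;
  long in_batch = 0;
  double acc_p = 0, acc_ex = 0, acc_def = 0;

  for (long s = 0; s < step_total; s++) {
    int p = (int)(unif_rand() * twoN); if (p == twoN) p--;
    int q = (int)(unif_rand() * twoN); if (q == twoN) q--;
    if (p / 2 != q / 2) {
      int a = g[p], b = g[q];
      int pa = g[p ^ 1], qa = g[q ^ 1];
      // remove (a,pa) and (b,qa); add (b,pa) and (a,qa)
      int c1 = cell(a, pa, k), c2 = cell(b, qa, k);
      int c3 = cell(b, pa, k), c4 = cell(a, qa, k);
      logp_nf += std::log((double)counts[c1]); counts[c1]--;
      logp_nf += std::log((double)counts[c2]); counts[c2]--;
      counts[c3]++; logp_nf -= std::log((double)counts[c3]);
      counts[c4]++; logp_nf -= std::log((double)counts[c4]);
      H += (a != pa ? -1 : 0) + (b != qa ? -1 : 0) +
           (b != pa ? 1 : 0) + (a != qa ? 1 : 0);
      g[p] = b; g[q] = a;
    }
    if (s < dememorization) continue;
    long t = s - dememorization;
    if (t % iter_per_batch == 0) {
      if (batch >= 0) {
        bp[batch] = acc_p / in_batch;
        bex[batch] = acc_ex / in_batch;
        bdef[batch] = acc_def / in_batch;
      }
      batch++; in_batch = 0; acc_p = acc_ex = acc_def = 0;
    }
    double logp = logp_nf + H * LOG2;
    if (logp <= logp_obs + tol) acc_p += 1;
    if (H >= h_obs) acc_ex += 1;
    if (H <= h_obs) acc_def += 1;
    in_batch++;
  }
  if (batch >= 0 && in_batch > 0) {
    bp[batch] = acc_p / in_batch;
    bex[batch] = acc_ex / in_batch;
    bdef[batch] = acc_def / in_batch;
  }
  return List::create(_["batch_p"] = bp, _["batch_excess"] = bex,
                      _["batch_deficit"] = bdef);
}

static double g_stat(const std::vector<int> &tab,
                     const std::vector<int> &rs, const std::vector<int> &cs,
                     int R, int C, int n) {
  double G = 0.0;
  for (int i = 0; i < R; i++) {
    if (rs[i] == 0) continue;
    for (int j = 0; j < C; j++) {
      int o = tab[i * C + j];
      if (o == 0 || cs[j] == 0) continue;
      double e = (double)rs[i] * cs[j] / n;
      G += 2.0 * o * std::log(o / e);
    }
  }
  return G;
}

// [[Rcpp::export]]
List ld_perm_cpp(IntegerVector ga, IntegerVector gb, int R, int C,
                 int batches, int iter_per_batch) {
  int n = ga.size();
  std::vector<int> a(ga.begin(), ga.end()), b(gb.begin(), gb.end());
  std::vector<int> rs(R, 0), cs(C, 0), tab(R * C, 0);
  for (int i = 0; i < n; i++) {
    rs[a[i]]++; cs[b[i]]++; tab[a[i] * C + b[i]]++;
  }
  double g_obs = g_stat(tab, rs, cs, R, C, n);
  NumericVector bmeans(batches);
  for (int bt = 0; bt < batches; bt++) {
    double acc = 0;
    for (int it = 0; it < iter_per_batch; it++) {
      for (int i = n - 1; i > 0; i--) { // Fisher-Yates on locus B
        int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
        std::swap(b[i], b[j]);
      }
      std::fill(tab.begin(), tab.end(), 0);
      for (int i = 0; i < n; i++) tab[a[i] * C + b[i]]++;
      if (g_stat(tab, rs, cs, R, C, n) >= g_obs - 1e-9) acc += 1;
    }
    bmeans[bt] = acc / iter_per_batch;
  }
  return List::create(_["g_obs"] = g_obs, _["batch_means"] = bmeans);
}
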
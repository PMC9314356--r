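#include <Rcpp.h>
using namespace Rcpp;

// Hardy-Weinberg dosage sampler with optional block LD.
//
// Genotypes are built from two haplotypes; within an LD block each
// haplotype's latent normals share a common factor with loading sqrt(r)
// (Gaussian copula), thresholded at qnorm(p) so marginal allele
// frequencies are exact. Uses R's RNG, so draws are reproducible under
// set.seed().
//
// thr: qnorm(effect-allele frequency) per variant
// block: integer block id per variant (consecutive variants share blocks)
// [[Rcpp::export]]
NumericMatrix draw_dosages_cpp(int n, NumericVector thr, IntegerVector block,
                               double r) {
  const int m = thr.size();
  NumericMatrix out(n, m);
  const double a = std::sqrt(r), b = std::sqrt(1.0 - r);
  if (r <= 0.0) {
    for (int j = 0; j < m; ++j) {
      const double p = R::pnorm(thr[j], 0.0, 1.0, 1, 0);
      for (int i = 0; i < n; ++i) {
        out(i, j) = (unif_rand() < p ? 1.0 : 0.0) +
                    (unif_rand() < p ? 1.0 : 0.0);
      }
    }
    return out;
  }
  for (int i = 0; i < n; ++i) {
    for (int h = 0; h < 2; ++h) {
      int cur = -1;
      double u = 0.0;
      for (int j = 0; j < m; ++j) {
        if (block[j] != cur) { cur = block[j]; u = norm_rand(); }
        const double z = a * u + b * norm_rand();
        if (z < thr[j]) out(i, j) += 1.0;
      }
    }
  }
  return out;
}
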
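#include <Rcpp.h>
using namespace Rcpp;

// One generation of two-sex Wright-Fisher transmission on a loci-major
// dosage matrix (L x n_parent; columns 0..n_male-1 are males). Each of the
// n_out offspring draws a uniform father and mother and receives, at every
// locus, one uniformly chosen allele from each parent: a homozygous parent
// transmits its allele deterministically, a heterozygote by coin flip.
// Mutation is applied by the caller. Uses R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix advance_geno(const IntegerMatrix& geno, int n_male,
                           int n_out) {
  const int L = geno.nrow();
  const int n_parent = geno.ncol();
  const int n_female = n_parent - n_male;
  IntegerMatrix out(L, n_out);
  RNGScope scope;
  for (int j = 0; j < n_out; ++j) {
    int f = (int)(unif_rand() * n_male);
    if (f >= n_male) f = n_male - 1;
    int m = n_male + (int)(unif_rand() * n_female);
    if (m >= n_parent) m = n_parent - 1;
    const int* fg = &geno(0, f);
    const int* mg = &geno(0, m);
    int* og = &out(0, j);
    for (int l = 0; l < L; ++l) {
      int pat = (fg[l] == 2) ? 1 : (fg[l] == 1 ? (unif_rand() < 0.5) : 0);
      int mat = (mg[l] == 2) ? 1 : (mg[l] == 1 ? (unif_rand() < 0.5) : 0);
      og[l] = pat + mat;
    }
  }
  return out;
}
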
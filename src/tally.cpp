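#include <Rcpp.h>
using namespace Rcpp;

// Joint residue tallies over motif instances, used to score candidate
// specializations of non-informative positions without re-scanning: a
// specialized pattern's instances are a subset of its base pattern's, so
// counts follow from the joint distribution of instance residues at the
// specialized positions. `mat` holds base codes 1..4 (0 = N, skipped) with
// one row per instance, one column per non-informative position.

// [[Rcpp::export]]
IntegerMatrix tally_pairs_cpp(IntegerMatrix mat, IntegerMatrix pairs) {
  int n = mat.nrow(), np = pairs.nrow();
  IntegerMatrix out(16, np);
  for (int k = 0; k < np; ++k) {
    int p = pairs(k, 0) - 1, q = pairs(k, 1) - 1;
    for (int i = 0; i < n; ++i) {
      int a = mat(i, p), b = mat(i, q);
      if (a && b) out((a - 1) * 4 + (b - 1), k)++;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix tally_triples_cpp(IntegerMatrix mat, IntegerMatrix triples) {
  int n = mat.nrow(), nt = triples.nrow();
  IntegerMatrix out(64, nt);
  for (int k = 0; k < nt; ++k) {
    int p = triples(k, 0) - 1, q = triples(k, 1) - 1, r = triples(k, 2) - 1;
    for (int i = 0; i < n; ++i) {
      int a = mat(i, p), b = mat(i, q), c = mat(i, r);
      if (a && b && c) out((a - 1) * 16 + (b - 1) * 4 + (c - 1), k)++;
    }
  }
  return out;
}
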
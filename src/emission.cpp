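#include <Rcpp.h>
using namespace Rcpp;

// P(observed dosages | inheritance vector) for every vector, by summing
// founder-allele assignment probabilities over the assignments consistent
// with the observed calls. Apat/Amat give, per vector x individual, the
// founder-allele slot (1-based) each individual carries; `patterns` holds
// one row per binary founder-allele assignment (1 = alternate allele) and
// `wp` its prior probability given the marker allele frequency. Individuals
// with missing calls are simply left out of `typed`.
// [[Rcpp::export]]
NumericVector emission_probs_cpp(IntegerMatrix Apat, IntegerMatrix Amat,
                                 IntegerVector typed, IntegerVector obs,
                                 IntegerMatrix patterns, NumericVector wp) {
  const int nv = Apat.nrow();
  const int nt = typed.size();
  const int np = patterns.nrow();
  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) {
    double e = 0.0;
    for (int p = 0; p < np; ++p) {
      bool ok = true;
      for (int t = 0; t < nt; ++t) {
        const int i = typed[t] - 1;
        const int d = patterns(p, Apat(v, i) - 1) + patterns(p, Amat(v, i) - 1);
        if (d != obs[t]) { ok = false; break; }
      }
      if (ok) e += wp[p];
    }
    out[v] = e;
  }
  return out;
}
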
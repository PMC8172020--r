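#include "circbin.h"

using namespace Rcpp;

// Apply i.i.d. substitution errors to reads using R's RNG (deterministic
// under set.seed); each erroneous base is replaced by one of the three
// other bases, uniformly.
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double err_rate) {
  if (err_rate <= 0) return seqs;
  RNGScope scope;
  CharacterVector out(seqs.size());
  const char *bases = "ACGT";
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < err_rate) {
        int cur;
        switch (s[p]) {
        case 'A': cur = 0; break;
        case 'C': cur = 1; break;
        case 'G': cur = 2; break;
        case 'T': cur = 3; break;
        default: continue; // leave N alone
        }
        int pick = (int)(unif_rand() * 3.0);
        if (pick > 2) pick = 2;
        if (pick >= cur) ++pick;
        s[p] = bases[pick];
      }
    }
    out[i] = s;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}
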
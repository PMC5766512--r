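#include <Rcpp.h>
#include <string>
#include <climits>

using namespace Rcpp;

// Minimal Hamming distance of each tag over all ungapped substring
// placements within `ref` (sense strand, no indels). Distances above
// `max_mm` are reported as NA. Case-sensitive on purpose: callers
// normalize to uppercase DNA.
// [[Rcpp::export(name = ".c_min_hamming")]]
IntegerVector c_min_hamming(CharacterVector tags, std::string ref,
                            int max_mm) {
  int n = tags.size();
  int R = (int) ref.size();
  IntegerVector out(n, NA_INTEGER);
  for (int t = 0; t < n; ++t) {
    const char *tag = CHAR(STRING_ELT(tags, t));
    int L = (int) LENGTH(STRING_ELT(tags, t));
    if (L > R) continue;
    int best = INT_MAX;
    for (int o = 0; o + L <= R; ++o) {
      int mm = 0;
      for (int i = 0; i < L; ++i) {
        if (tag[i] != ref[o + i]) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm && mm < best) {
        best = mm;
        if (best == 0) break;
      }
    }
    if (best <= max_mm) out[t] = best;
  }
  return out;
}
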
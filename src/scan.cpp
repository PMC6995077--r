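#include <Rcpp.h>
using namespace Rcpp;

// Mismatch-bounded protospacer scan over one encoded strand.
// enc: contig encoded A=1,C=2,G=3,T=4,N=0; sp: encoded 20-mer spacer.
// A site is reported when the 3-bp PAM immediately 3' of the 20-mer is
// NGG or NAG and the mismatch count (N always mismatches) is <= max_mm.
// Returns 0-based protospacer start offsets and mismatch counts.
// [[Rcpp::export(name = ".scan_strand_cpp")]]
List scan_strand_cpp(IntegerVector enc, IntegerVector sp, int max_mm) {
  int L = enc.size();
  int n_pos = L - 22;
  std::vector<int> pos;
  std::vector<int> mm_out;
  if (n_pos > 0) {
    for (int i = 0; i < n_pos; ++i) {
      int p3 = enc[i + 22];
      if (p3 != 3) continue;              // PAM position 3 must be G
      int p2 = enc[i + 21];
      if (p2 != 3 && p2 != 1) continue;   // NGG or NAG
      int mm = 0;
      for (int k = 0; k < 20; ++k) {
        int b = enc[i + k];
        if (b == 0 || b != sp[k]) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        pos.push_back(i);
        mm_out.push_back(mm);
      }
    }
  }
  return List::create(_["pos"] = wrap(pos), _["mm"] = wrap(mm_out));
}
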
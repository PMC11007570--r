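#include "seq_util.h"
using namespace Rcpp;

// Paired-end fragment simulator for one template sequence. Fragment starts
// are uniform on the circle (or on valid linear positions), insert sizes
// uniform in [ins_min, ins_max], fragment strand random, and per-base
// substitution errors applied at rate `err`. Uses R's RNG so set.seed()
// controls the output. Returns mate sequences plus the fragment truth
// (1-based start on the forward strand, insert, strand).
// [[Rcpp::export]]
List cpp_simulate_pairs(std::string genome, bool circular, int n_pairs,
                        int read_len, int ins_min, int ins_max, double err) {
  int L = (int)genome.size();
  if (ins_max > L) stop("insert exceeds template length (%d > %d)", ins_max, L);
  if (read_len > ins_min) stop("read length exceeds minimum insert");
  CharacterVector s1(n_pairs), s2(n_pairs);
  IntegerVector start(n_pairs), insert(n_pairs), strand(n_pairs);
  std::string frag;
  for (int i = 0; i < n_pairs; ++i) {
    int ins = ins_min + (int)std::floor(unif_rand() * (ins_max - ins_min + 1));
    if (ins > ins_max) ins = ins_max;
    int maxstart = circular ? L : (L - ins + 1);
    int st = (int)std::floor(unif_rand() * maxstart);
    if (st >= maxstart) st = maxstart - 1;
    frag.resize(ins);
    for (int j = 0; j < ins; ++j) frag[j] = genome[circular ? (st + j) % L : st + j];
    bool fwd = unif_rand() < 0.5;
    if (!fwd) frag = revcomp_str(frag);
    std::string r1 = frag.substr(0, read_len);
    std::string r2 = revcomp_str(frag.substr(ins - read_len));
    if (err > 0) {
      for (auto* r : {&r1, &r2}) {
        for (auto& c : *r) {
          if (unif_rand() < err) {
            int b = base2bits(c);
            int nb = (int)std::floor(unif_rand() * 3);
            if (nb > 2) nb = 2;
            c = bits2base((b + 1 + nb) % 4);
          }
        }
      }
    }
    s1[i] = r1; s2[i] = r2;
    start[i] = st + 1; insert[i] = ins; strand[i] = fwd ? 1 : -1;
  }
  return List::create(_["seq1"] = s1, _["seq2"] = s2, _["start"] = start,
                      _["insert"] = insert, _["strand"] = strand);
}
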
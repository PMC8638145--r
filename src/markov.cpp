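#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-2 Markov nucleotide sequence of length n.
// trans: 16 x 4 row-stochastic matrix, rows indexed by the previous
// dinucleotide (4 * prev1 + prev2, A=0 C=1 G=2 T=3), columns by next base.
// Uses the R RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
std::string cpp_markov2_sample(NumericMatrix trans, int n, int start_state) {
  static const char bases[] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');
  if (n == 0) return out;
  int p1 = start_state / 4, p2 = start_state % 4;
  out[0] = bases[p1];
  if (n > 1) out[1] = bases[p2];
  for (int i = 2; i < n; ++i) {
    int row = 4 * p1 + p2;
    double u = R::unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(row, j);
      if (u <= acc) { b = j; break; }
    }
    out[i] = bases[b];
    p1 = p2; p2 = b;
  }
  return out;
}
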
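#include <Rcpp.h>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N and friends: neutral (zero) contribution
  }
}

// Maximum log-odds window score over both strands for each sequence.
// lo is 4 x W (rows A,C,G,T). Reverse-strand windows are scored in place via
// base complementation; ties prefer the forward strand, then the smallest
// forward-coordinate window start. Positions are 0-based.
// [[Rcpp::export]]
List scan_pwm_cpp(CharacterVector seqs, NumericMatrix lo) {
  const int W = lo.ncol();
  const int n = seqs.size();
  NumericVector best(n);
  IntegerVector pos(n);
  CharacterVector strand(n);

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    if (L < W) stop("sequence %d is shorter than the motif width (%d < %d)",
                    i + 1, L, W);
    std::vector<int> code(L);
    for (int k = 0; k < L; ++k) code[k] = base_code(s[k]);

    double b = R_NegInf;
    int bp = 0;
    int bs = 0;  // 0 = forward, 1 = reverse
    for (int p = 0; p <= L - W; ++p) {           // forward strand first
      double sc = 0.0;
      for (int j = 0; j < W; ++j) {
        int c = code[p + j];
        if (c < 4) sc += lo(c, j);
      }
      if (sc > b) { b = sc; bp = p; bs = 0; }
    }
    for (int p = 0; p <= L - W; ++p) {           // reverse complement
      double sc = 0.0;
      for (int j = 0; j < W; ++j) {
        int c = code[p + W - 1 - j];
        if (c < 4) sc += lo(3 - c, j);
      }
      if (sc > b) { b = sc; bp = p; bs = 1; }
    }
    best[i] = b;
    pos[i] = bp;
    strand[i] = bs == 0 ? "+" : "-";
  }
  return List::create(_["score"] = best, _["position"] = pos,
                      _["strand"] = strand);
}
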
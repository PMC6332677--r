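#include <Rcpp.h>
using namespace Rcpp;

// Per-pair ordering counts between two gene blocks sharing the same
// samples: gt(i, j) = #samples with xi(i, s) > xj(j, s), lt(i, j) the
// reverse.  Ties contribute to neither count.
// [[Rcpp::export(name = ".pair_order_counts")]]
List pair_order_counts(NumericMatrix xi, NumericMatrix xj) {
  const int gi = xi.nrow(), gj = xj.nrow(), S = xi.ncol();
  if (xj.ncol() != S) stop("blocks must share the same samples");
  IntegerMatrix gt(gi, gj), lt(gi, gj);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < gj; ++j) {
      const double vj = xj(j, s);
      for (int i = 0; i < gi; ++i) {
        const double vi = xi(i, s);
        if (vi > vj) ++gt(i, j);
        else if (vi < vj) ++lt(i, j);
      }
    }
  }
  return List::create(_["gt"] = gt, _["lt"] = lt);
}
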
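#include <Rcpp.h>
using namespace Rcpp;

// Pairwise strict less-than counts per class over samples:
// poor(i,j) = #{samples s in poor class : X(i,s) < X(j,s)}, likewise good.
// Ties count for neither direction ("not less than").
// [[Rcpp::export(name = ".pair_lt_counts")]]
List pair_lt_counts(NumericMatrix X, LogicalVector poor) {
  const int P = X.nrow(), n = X.ncol();
  IntegerMatrix cp(P, P), cg(P, P);
  std::vector<double> col(P);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < P; ++i) col[i] = X(i, s);
    IntegerMatrix &C = poor[s] ? cp : cg;
    for (int i = 0; i < P; ++i) {
      const double xi = col[i];
      for (int j = i + 1; j < P; ++j) {
        if (xi < col[j]) ++C(i, j);
        else if (col[j] < xi) ++C(j, i);
      }
    }
  }
  return List::create(_["poor"] = cp, _["good"] = cg);
}
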
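// Harrell's concordance over all comparable pairs.
// A pair (i, j) is comparable when the earlier time is an event; the pair
// is concordant when the subject with the earlier event has the higher
// linear predictor; predictor ties count one half. Tied event times are
// not comparable.

#include <Rcpp.h>

// [[Rcpp::export(name = ".c_index_pairs")]]
Rcpp::List c_index_pairs(Rcpp::NumericVector lp, Rcpp::NumericVector time,
                         Rcpp::IntegerVector event) {
  const int n = lp.size();
  if (time.size() != n || event.size() != n)
    Rcpp::stop("lp, time and event must have equal length");
  double concordant = 0.0;
  long long comparable = 0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      // i is the earlier event; j survived past time[i]
      bool cmp = time[j] > time[i] || (time[j] == time[i] && event[j] == 0);
      if (!cmp) continue;
      ++comparable;
      if (lp[i] > lp[j]) concordant += 1.0;
      else if (lp[i] == lp[j]) concordant += 0.5;
    }
  }
  return Rcpp::List::create(Rcpp::Named("concordant") = concordant,
                            Rcpp::Named("comparable") = (double)comparable);
}
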
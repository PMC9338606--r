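#include <Rcpp.h>
using namespace Rcpp;

// Gradient/hessian/count histograms for one tree node.
// bins: n x p integer matrix, entries in 0..nbins (0 = missing).
// rows: 1-based row indices belonging to the node.
// Returns a numeric vector laid out as [feature][bin][g,h,count],
// i.e. dim c(3, nbins + 1, p) after array().
// [[Rcpp::export]]
NumericVector gbt_node_hist(IntegerMatrix bins, IntegerVector rows,
                            NumericVector g, NumericVector h, int nbins) {
  const int p = bins.ncol();
  const int stride = (nbins + 1) * 3;
  NumericVector out(p * stride);
  double *o = REAL(out);
  const int nr = rows.size();
  for (int j = 0; j < p; ++j) {
    double *base = o + j * stride;
    for (int k = 0; k < nr; ++k) {
      const int i = rows[k] - 1;
      const int b = bins(i, j);
      base[b * 3 + 0] += g[i];
      base[b * 3 + 1] += h[i];
      base[b * 3 + 2] += 1.0;
    }
  }
  return out;
}

// Partition node rows by a binned split: left iff bin <= split_bin,
// missing (bin 0) goes to the side given by miss_left.
// [[Rcpp::export]]
List gbt_partition(IntegerMatrix bins, IntegerVector rows, int feature,
                   int split_bin, bool miss_left) {
  const int nr = rows.size();
  std::vector<int> left, right;
  left.reserve(nr); right.reserve(nr);
  for (int k = 0; k < nr; ++k) {
    const int i = rows[k] - 1;
    const int b = bins(i, feature - 1);
    bool go_left = (b == 0) ? miss_left : (b <= split_bin);
    if (go_left) left.push_back(rows[k]); else right.push_back(rows[k]);
  }
  return List::create(_["left"] = wrap(left), _["right"] = wrap(right));
}
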
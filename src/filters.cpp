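#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Connected-component labeling by breadth-first flood fill.
// `mask` is a logical array with dim attribute (2 or 3 dims);
// `offsets` is an n_neigh x ndim integer matrix of neighbor steps.
// Labels are assigned 1..N in order of each component's first voxel
// in the array's linear (column-major) order, so labeling is
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   IntegerMatrix offsets) {
  const int nd = dim.size();
  const R_xlen_t n = mask.size();
  std::vector<R_xlen_t> stride(nd);
  stride[0] = 1;
  for (int d = 1; d < nd; ++d) stride[d] = stride[d - 1] * dim[d - 1];

  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;
  std::vector<R_xlen_t> queue;
  std::vector<int> coord(nd), ncoord(nd);
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      R_xlen_t rem = cur;
      for (int d = nd - 1; d >= 0; --d) {
        coord[d] = (int)(rem / stride[d]);
        rem -= (R_xlen_t)coord[d] * stride[d];
      }
      for (int k = 0; k < offsets.nrow(); ++k) {
        bool ok = true;
        for (int d = 0; d < nd; ++d) {
          ncoord[d] = coord[d] + offsets(k, d);
          if (ncoord[d] < 0 || ncoord[d] >= dim[d]) { ok = false; break; }
        }
        if (!ok) continue;
        R_xlen_t j = 0;
        for (int d = 0; d < nd; ++d) j += (R_xlen_t)ncoord[d] * stride[d];
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          queue.push_back(j);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// Median rank filter over an arbitrary pixel neighborhood with
// reflected (mirror, no edge repeat beyond bounds) border handling.
// `img` is a numeric matrix; `offsets` is n_off x 2 (row, col) steps.
// [[Rcpp::export]]
NumericMatrix cpp_rank_filter_median(NumericMatrix img, IntegerMatrix offsets) {
  const int nr = img.nrow(), nc = img.ncol(), no = offsets.nrow();
  NumericMatrix out(nr, nc);
  std::vector<double> vals(no);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int k = 0; k < no; ++k) {
        int rr = r + offsets(k, 0);
        int cc = c + offsets(k, 1);
        // reflect about the border pixel (a b c | b a)
        if (rr < 0) rr = -rr;
        if (rr >= nr) rr = 2 * nr - 2 - rr;
        if (cc < 0) cc = -cc;
        if (cc >= nc) cc = 2 * nc - 2 - cc;
        vals[k] = img(rr, cc);
      }
      std::nth_element(vals.begin(), vals.begin() + no / 2, vals.end());
      double med = vals[no / 2];
      if (no % 2 == 0) {
        double lo = *std::max_element(vals.begin(), vals.begin() + no / 2);
        med = 0.5 * (med + lo);
      }
      out(r, c) = med;
    }
  }
  return out;
}
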
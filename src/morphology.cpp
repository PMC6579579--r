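#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 3D morphology primitives for the segmentation pipeline.
// Arrays are passed as flat vectors with dims (d1, d2, d3) in R's
// column-major layout: index = i + d1*(j + d2*k).

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + (long long)d2 * k);
}

// Connected-component labelling of a logical mask, 26-neighbourhood.
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int k0 = 0; k0 < d3; ++k0)
    for (int j0 = 0; j0 < d2; ++j0)
      for (int i0 = 0; i0 < d1; ++i0) {
        const int p0 = idx3(i0, j0, k0, d1, d2);
        if (!mask[p0] || lab[p0]) continue;
        ++next;
        stack.clear();
        stack.push_back(p0);
        lab[p0] = next;
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int i = p % d1, j = (p / d1) % d2, k = p / (d1 * d2);
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                const int ii = i + di, jj = j + dj, kk = k + dk;
                if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 ||
                    kk < 0 || kk >= d3) continue;
                const int q = idx3(ii, jj, kk, d1, d2);
                if (mask[q] && !lab[q]) {
                  lab[q] = next;
                  stack.push_back(q);
                }
              }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

struct PQItem {
  double elev;
  long long order;
  int pos;
};
struct PQCompare {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-based watershed by priority flooding (Meyer). Markers > 0 are
// seed labels; flooding proceeds uphill on `elev` with 6-connectivity,
// restricted to voxels where `allowed` is true (marker voxels are
// always allowed). Every voxel ends up with the label of the marker
// whose basin reaches it first (lowest elevation path).
// [[Rcpp::export(name = ".watershed_3d")]]
IntegerVector watershed_3d(NumericVector elev, IntegerVector markers,
                           IntegerVector dims, LogicalVector allowed) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerVector lab(clone(markers));
  std::priority_queue<PQItem, std::vector<PQItem>, PQCompare> pq;
  long long order = 0;
  const int di6[6] = {1, -1, 0, 0, 0, 0};
  const int dj6[6] = {0, 0, 1, -1, 0, 0};
  const int dk6[6] = {0, 0, 0, 0, 1, -1};
  for (int p = 0; p < lab.size(); ++p)
    if (lab[p] > 0) pq.push({elev[p], order++, p});
  while (!pq.empty()) {
    const PQItem it = pq.top();
    pq.pop();
    const int p = it.pos;
    const int i = p % d1, j = (p / d1) % d2, k = p / (d1 * d2);
    for (int n = 0; n < 6; ++n) {
      const int ii = i + di6[n], jj = j + dj6[n], kk = k + dk6[n];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 ||
          kk < 0 || kk >= d3) continue;
      const int q = idx3(ii, jj, kk, d1, d2);
      if (lab[q] == 0 && allowed[q]) {
        lab[q] = lab[p];
        pq.push({std::max(elev[q], it.elev), order++, q});
      }
    }
  }
  return lab;
}

// Separable 1D convolution along the first array dimension with a
// symmetric kernel, replicate padding at the edges. Smoothing along the
// other dimensions is done in R by permuting the array.
// [[Rcpp::export(name = ".conv_dim1")]]
NumericVector conv_dim1(NumericVector x, IntegerVector dims,
                        NumericVector kernel) {
  const int d1 = dims[0];
  const long long ncol = (long long)dims[1] * dims[2];
  const int kh = (kernel.size() - 1) / 2;
  NumericVector out(x.size());
  for (long long c = 0; c < ncol; ++c) {
    const long long off = c * d1;
    for (int i = 0; i < d1; ++i) {
      double acc = 0.0;
      for (int t = -kh; t <= kh; ++t) {
        int s = i + t;
        if (s < 0) s = 0;
        if (s >= d1) s = d1 - 1;
        acc += kernel[t + kh] * x[off + s];
      }
      out[off + i] = acc;
    }
  }
  return out;
}
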
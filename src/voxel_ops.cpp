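// Voxel-grid kernels: separable 1-D convolution (replicate padding) and
// 26-connected component labeling.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Convolve along `axis` (0,1,2) with a symmetric kernel, replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size(), r = kl / 2;
  NumericVector out(vol.size());
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {sx, sy, sz};
  const int na = n[axis];
  const size_t sa = stride[axis];

  // iterate over all lines along `axis`
  int b1 = axis == 0 ? 1 : 0;
  int b2 = axis == 2 ? 1 : 2;
  std::vector<double> line(na);
  for (int j2 = 0; j2 < n[b2]; ++j2)
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      size_t base = (size_t)j1 * stride[b1] + (size_t)j2 * stride[b2];
      for (int i = 0; i < na; ++i) line[i] = vol[base + (size_t)i * sa];
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int src = i + t;
          if (src < 0) src = 0;
          if (src >= na) src = na - 1;
          acc += line[src] * kernel[t + r];
        }
        out[base + (size_t)i * sa] = acc;
      }
    }
  return out;
}

// 26-connected labeling of a logical mask.
// Returns labels (0 = background), component sizes, and the minimum linear
// index (1-based) of each component, for deterministic tie-breaking.
// [[Rcpp::export]]
List cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t ntot = (size_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);
  std::vector<int> sizes, minidx;
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    sizes.push_back(0);
    minidx.push_back((int)s + 1);
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front();
      q.pop();
      sizes[next - 1]++;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t s2 = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[s2] && labels[s2] == 0) {
              labels[s2] = next;
              q.push(s2);
            }
          }
    }
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes),
                      _["min_index"] = wrap(minidx));
}
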
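#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labelling of a 3D logical array (6 or 26 connectivity).
// Labels are assigned in raster-scan order of the first voxel encountered.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector lab(mask.size(), 0);
  std::vector<int> offs;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
      }
  auto lin = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
  };
  int next = 0;
  std::queue<long long> q;
  for (long long s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      long long c = q.front(); q.pop();
      int ci = (int)(c % nx), cj = (int)((c / nx) % ny), ck = (int)(c / ((long long)nx*ny));
      for (size_t o = 0; o < offs.size(); o += 3) {
        int i = ci + offs[o], j = cj + offs[o+1], k = ck + offs[o+2];
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        long long t = lin(i, j, k);
        if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
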
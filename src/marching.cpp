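#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra over a scalar field sampled on a regular grid.
//
// Each grid cell is split into six tetrahedra that all share the cell's main
// diagonal (corner 0 -> corner 6).  The decomposition is mirror-consistent
// across cell faces (the face diagonals 0-2 / 4-6 / 1-6 / 0-7 / 3-6 / 0-5
// match up between neighbouring cells), so welding interpolated vertices by
// the global index pair of their supporting edge yields a watertight,
// 2-manifold mesh: every interior tet face is emitted zero times, every
// iso-crossing tet is triangulated identically on both sides of a shared
// face.  No ambiguous configurations exist (a tetrahedron has none), which
// makes the extraction fully deterministic.

static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
};

struct VKey {
  long long a, b;
  bool operator==(const VKey& o) const { return a == o.a && b == o.b; }
};
struct VKeyHash {
  std::size_t operator()(const VKey& k) const {
    return std::hash<long long>()(k.a * 73856093LL ^ k.b * 19349663LL);
  }
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double iso,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* f = field.begin();
  auto lin = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
  };

  std::unordered_map<VKey, int, VKeyHash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  // world coordinate of grid node (i,j,k)
  auto wx = [&](double i) { return origin[0] + i * spacing[0]; };
  auto wy = [&](double j) { return origin[1] + j * spacing[1]; };
  auto wz = [&](double k) { return origin[2] + k * spacing[2]; };

  // vertex on edge between global corners ga (value va) and gb (value vb)
  auto edge_vertex = [&](long long ga, long long gb, double va, double vb,
                         const double pa[3], const double pb[3]) -> int {
    VKey key = ga < gb ? VKey{ga, gb} : VKey{gb, ga};
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    // canonical orientation: always interpolate from the lower-index corner
    // so both cells sharing the edge produce the bit-identical vertex
    double ca[3], cb[3], fva = va, fvb = vb;
    if (ga < gb) {
      for (int d = 0; d < 3; d++) { ca[d] = pa[d]; cb[d] = pb[d]; }
    } else {
      for (int d = 0; d < 3; d++) { ca[d] = pb[d]; cb[d] = pa[d]; }
      fva = vb; fvb = va;
    }
    double t = (iso - fva) / (fvb - fva);
    int id = (int)vx.size();
    vx.push_back(ca[0] + t * (cb[0] - ca[0]));
    vy.push_back(ca[1] + t * (cb[1] - ca[1]));
    vz.push_back(ca[2] + t * (cb[2] - ca[2]));
    vmap.emplace(key, id);
    return id;
  };

  double cv[8];
  long long gl[8];
  double cp[8][3];

  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        double cmin = 1e300, cmax = -1e300;
        for (int c = 0; c < 8; c++) {
          int ci = i + CORNER[c][0], cj = j + CORNER[c][1], ck = k + CORNER[c][2];
          cv[c] = f[lin(ci, cj, ck)];
          gl[c] = lin(ci, cj, ck);
          cp[c][0] = wx(ci); cp[c][1] = wy(cj); cp[c][2] = wz(ck);
          if (cv[c] < cmin) cmin = cv[c];
          if (cv[c] > cmax) cmax = cv[c];
        }
        if (cmax <= iso || cmin > iso) continue;

        for (int t = 0; t < 6; t++) {
          int ins[4], out[4], ni = 0, no = 0;
          for (int q = 0; q < 4; q++) {
            int c = TETS[t][q];
            if (cv[c] > iso) ins[ni++] = c; else out[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;

          // emit triangle(s); orient so the normal points from inside to
          // outside (outward for a field that is high inside the object)
          if (ni == 1) {
            int a = ins[0];
            int p0 = edge_vertex(gl[a], gl[out[0]], cv[a], cv[out[0]], cp[a], cp[out[0]]);
            int p1 = edge_vertex(gl[a], gl[out[1]], cv[a], cv[out[1]], cp[a], cp[out[1]]);
            int p2 = edge_vertex(gl[a], gl[out[2]], cv[a], cv[out[2]], cp[a], cp[out[2]]);
            double u[3], v[3], n[3], d[3];
            u[0] = vx[p1]-vx[p0]; u[1] = vy[p1]-vy[p0]; u[2] = vz[p1]-vz[p0];
            v[0] = vx[p2]-vx[p0]; v[1] = vy[p2]-vy[p0]; v[2] = vz[p2]-vz[p0];
            n[0] = u[1]*v[2]-u[2]*v[1]; n[1] = u[2]*v[0]-u[0]*v[2]; n[2] = u[0]*v[1]-u[1]*v[0];
            d[0] = vx[p0]-cp[a][0]; d[1] = vy[p0]-cp[a][1]; d[2] = vz[p0]-cp[a][2];
            if (n[0]*d[0]+n[1]*d[1]+n[2]*d[2] >= 0) { fa.push_back(p0); fb.push_back(p1); fc.push_back(p2); }
            else { fa.push_back(p0); fb.push_back(p2); fc.push_back(p1); }
          } else if (ni == 3) {
            int a = out[0];
            int p0 = edge_vertex(gl[ins[0]], gl[a], cv[ins[0]], cv[a], cp[ins[0]], cp[a]);
            int p1 = edge_vertex(gl[ins[1]], gl[a], cv[ins[1]], cv[a], cp[ins[1]], cp[a]);
            int p2 = edge_vertex(gl[ins[2]], gl[a], cv[ins[2]], cv[a], cp[ins[2]], cp[a]);
            double u[3], v[3], n[3], d[3];
            u[0] = vx[p1]-vx[p0]; u[1] = vy[p1]-vy[p0]; u[2] = vz[p1]-vz[p0];
            v[0] = vx[p2]-vx[p0]; v[1] = vy[p2]-vy[p0]; v[2] = vz[p2]-vz[p0];
            n[0] = u[1]*v[2]-u[2]*v[1]; n[1] = u[2]*v[0]-u[0]*v[2]; n[2] = u[0]*v[1]-u[1]*v[0];
            d[0] = cp[a][0]-vx[p0]; d[1] = cp[a][1]-vy[p0]; d[2] = cp[a][2]-vz[p0];
            if (n[0]*d[0]+n[1]*d[1]+n[2]*d[2] >= 0) { fa.push_back(p0); fb.push_back(p1); fc.push_back(p2); }
            else { fa.push_back(p0); fb.push_back(p2); fc.push_back(p1); }
          } else { // ni == 2: quad split into two triangles
            int a = ins[0], b = ins[1], c = out[0], d0 = out[1];
            int pac = edge_vertex(gl[a], gl[c], cv[a], cv[c], cp[a], cp[c]);
            int pad = edge_vertex(gl[a], gl[d0], cv[a], cv[d0], cp[a], cp[d0]);
            int pbc = edge_vertex(gl[b], gl[c], cv[b], cv[c], cp[b], cp[c]);
            int pbd = edge_vertex(gl[b], gl[d0], cv[b], cv[d0], cp[b], cp[d0]);
            double ctr[3] = { (cp[a][0]+cp[b][0])/2, (cp[a][1]+cp[b][1])/2, (cp[a][2]+cp[b][2])/2 };
            int quads[2][3] = { {pac, pad, pbd}, {pac, pbd, pbc} };
            for (int qq = 0; qq < 2; qq++) {
              int p0 = quads[qq][0], p1 = quads[qq][1], p2 = quads[qq][2];
              double u[3], v[3], n[3], d[3];
              u[0] = vx[p1]-vx[p0]; u[1] = vy[p1]-vy[p0]; u[2] = vz[p1]-vz[p0];
              v[0] = vx[p2]-vx[p0]; v[1] = vy[p2]-vy[p0]; v[2] = vz[p2]-vz[p0];
              n[0] = u[1]*v[2]-u[2]*v[1]; n[1] = u[2]*v[0]-u[0]*v[2]; n[2] = u[0]*v[1]-u[1]*v[0];
              d[0] = vx[p0]-ctr[0]; d[1] = vy[p0]-ctr[1]; d[2] = vz[p0]-ctr[2];
              if (n[0]*d[0]+n[1]*d[1]+n[2]*d[2] >= 0) { fa.push_back(p0); fb.push_back(p1); fc.push_back(p2); }
              else { fa.push_back(p0); fb.push_back(p2); fc.push_back(p1); }
            }
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; i++) { F(i,0) = fa[i]+1; F(i,1) = fb[i]+1; F(i,2) = fc[i]+1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Separable Gaussian smoothing of a 3D field (reflected boundaries).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector field, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> w(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; i++) { w[i+rad] = std::exp(-0.5*i*i/(sigma*sigma)); s += w[i+rad]; }
  for (auto& x : w) x /= s;

  NumericVector a = clone(field), b(field.size());
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2*n - i - 1; }
    return i;
  };
  auto lin = [&](int i, int j, int k) { return i + nx * (j + ny * k); };

  for (int pass = 0; pass < 3; pass++) {
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          double acc = 0;
          for (int o = -rad; o <= rad; o++) {
            int ii = i, jj = j, kk = k;
            if (pass == 0) ii = reflect(i + o, nx);
            else if (pass == 1) jj = reflect(j + o, ny);
            else kk = reflect(k + o, nz);
            acc += w[o+rad] * a[lin(ii, jj, kk)];
          }
          b[lin(i, j, k)] = acc;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dims;
  return a;
}
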
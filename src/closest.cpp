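#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Closest point from query points to a triangle soup, plus signed distance
// via angle-weighted pseudonormals (robust sign on edges and vertices).

struct V3 { double x, y, z; };
static inline V3 sub(const V3&a, const V3&b){ return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 add(const V3&a, const V3&b){ return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline V3 mul(const V3&a, double s){ return {a.x*s, a.y*s, a.z*s}; }
static inline double dot(const V3&a, const V3&b){ return a.x*b.x+a.y*b.y+a.z*b.z; }
static inline V3 cross(const V3&a, const V3&b){
  return {a.y*b.z-a.z*b.y, a.z*b.x-a.x*b.z, a.x*b.y-a.y*b.x};
}
static inline double norm(const V3&a){ return std::sqrt(dot(a,a)); }

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection
// style Voronoi-region case analysis).  region: 0 face, 1/2/3 vertex a/b/c,
// 4 edge ab, 5 edge bc, 6 edge ca.
static V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c,
                         int& region) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { region = 1; return a; }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { region = 2; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    region = 4; double v = d1 / (d1 - d3); return add(a, mul(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { region = 3; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    region = 6; double w = d2 / (d2 - d6); return add(a, mul(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    region = 5; double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, mul(sub(c, b), w));
  }
  region = 0;
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(mul(ab, v), mul(ac, w)));
}

struct EKey {
  int a, b;
  bool operator==(const EKey& o) const { return a == o.a && b == o.b; }
};
struct EKeyHash {
  std::size_t operator()(const EKey& k) const {
    return std::hash<long long>()(((long long)k.a << 32) ^ (long long)k.b);
  }
};

// [[Rcpp::export]]
List cpp_closest_signed(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                        bool want_sign) {
  const int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  std::vector<V3> vert(nv);
  for (int i = 0; i < nv; i++) vert[i] = {V(i,0), V(i,1), V(i,2)};

  // face normals (unnormalised = 2*area weighted) and unit normals
  std::vector<V3> fn(nf), fnu(nf);
  for (int t = 0; t < nf; t++) {
    V3 a = vert[F(t,0)-1], b = vert[F(t,1)-1], c = vert[F(t,2)-1];
    V3 n = cross(sub(b,a), sub(c,a));
    fn[t] = n;
    double l = norm(n);
    fnu[t] = l > 0 ? mul(n, 1.0/l) : V3{0,0,0};
  }

  std::vector<V3> vn;                       // angle-weighted vertex normals
  std::unordered_map<EKey, V3, EKeyHash> en; // edge normals (sum of faces)
  if (want_sign) {
    vn.assign(nv, {0,0,0});
    for (int t = 0; t < nf; t++) {
      int ia = F(t,0)-1, ib = F(t,1)-1, ic = F(t,2)-1;
      const V3 &a = vert[ia], &b = vert[ib], &c = vert[ic];
      // incident angle at each corner
      auto ang = [](const V3& u, const V3& v) {
        double cu = norm(u), cv = norm(v);
        if (cu == 0 || cv == 0) return 0.0;
        double ct = dot(u, v) / (cu * cv);
        ct = std::max(-1.0, std::min(1.0, ct));
        return std::acos(ct);
      };
      vn[ia] = add(vn[ia], mul(fnu[t], ang(sub(b,a), sub(c,a))));
      vn[ib] = add(vn[ib], mul(fnu[t], ang(sub(a,b), sub(c,b))));
      vn[ic] = add(vn[ic], mul(fnu[t], ang(sub(a,c), sub(b,c))));
      int e[3][2] = {{ia,ib},{ib,ic},{ic,ia}};
      for (int q = 0; q < 3; q++) {
        EKey k = e[q][0] < e[q][1] ? EKey{e[q][0], e[q][1]} : EKey{e[q][1], e[q][0]};
        auto it = en.find(k);
        if (it == en.end()) en.emplace(k, fnu[t]);
        else it->second = add(it->second, fnu[t]);
      }
    }
  }

  NumericVector dist(np);
  NumericMatrix CP(np, 3);
  IntegerVector face(np);
  for (int i = 0; i < np; i++) {
    V3 p = {P(i,0), P(i,1), P(i,2)};
    double best = R_PosInf; V3 bcp = {0,0,0}; int bt = -1, breg = 0;
    for (int t = 0; t < nf; t++) {
      int reg;
      V3 cp = closest_on_tri(p, vert[F(t,0)-1], vert[F(t,1)-1], vert[F(t,2)-1], reg);
      double d = norm(sub(p, cp));
      if (d < best) { best = d; bcp = cp; bt = t; breg = reg; }
    }
    double sgn = 1.0;
    if (want_sign && bt >= 0) {
      V3 n;
      int ia = F(bt,0)-1, ib = F(bt,1)-1, ic = F(bt,2)-1;
      switch (breg) {
        case 0: n = fnu[bt]; break;
        case 1: n = vn[ia]; break;
        case 2: n = vn[ib]; break;
        case 3: n = vn[ic]; break;
        case 4: n = en[ia < ib ? EKey{ia,ib} : EKey{ib,ia}]; break;
        case 5: n = en[ib < ic ? EKey{ib,ic} : EKey{ic,ib}]; break;
        default: n = en[ic < ia ? EKey{ic,ia} : EKey{ia,ic}]; break;
      }
      sgn = dot(sub(p, bcp), n) >= 0 ? 1.0 : -1.0;
    }
    dist[i] = sgn * best;
    CP(i,0) = bcp.x; CP(i,1) = bcp.y; CP(i,2) = bcp.z;
    face[i] = bt + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = CP, _["face"] = face);
}
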
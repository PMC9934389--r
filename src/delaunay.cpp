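#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// 3-D Delaunay tessellation by incremental Bowyer-Watson insertion into a
// large enclosing super-tetrahedron.  Point sets here are protein heavy atoms
// (hundreds to a few thousand), so the simple O(n * T) bad-tetra scan per
// insertion is fast enough and avoids the bookkeeping of a walk structure.
//
// Degeneracies (coplanar/cospherical atoms are common in idealised fixtures)
// are broken by a deterministic jitter of at most 1e-6 Angstrom drawn from a
// fixed-seed LCG, applied to every coordinate before tessellating.  1e-6 is
// far below both PDB precision (1e-3) and any contact cutoff of interest.

namespace {

struct Tet {
  int v[4];
  bool alive;
};

// deterministic LCG (Numerical Recipes constants), seed fixed at 0
struct Lcg {
  uint64_t s;
  explicit Lcg(uint64_t seed) : s(seed) {}
  double unif() {  // in [0,1)
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    return (double)(s >> 11) / 9007199254740992.0;
  }
};

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

// orientation of tetra (a,b,c,d): positive if d below plane abc (right-handed)
inline double orient3d(const double* p, int a, int b, int c, int d) {
  double adx = p[3*a] - p[3*d],   ady = p[3*a+1] - p[3*d+1], adz = p[3*a+2] - p[3*d+2];
  double bdx = p[3*b] - p[3*d],   bdy = p[3*b+1] - p[3*d+1], bdz = p[3*b+2] - p[3*d+2];
  double cdx = p[3*c] - p[3*d],   cdy = p[3*c+1] - p[3*d+1], cdz = p[3*c+2] - p[3*d+2];
  return det3(adx, ady, adz, bdx, bdy, bdz, cdx, cdy, cdz);
}

// insphere: > 0 iff point e is strictly inside circumsphere of positively
// oriented tetra (a,b,c,d)
inline double insphere(const double* p, int a, int b, int c, int d, int e) {
  double aex = p[3*a] - p[3*e], aey = p[3*a+1] - p[3*e+1], aez = p[3*a+2] - p[3*e+2];
  double bex = p[3*b] - p[3*e], bey = p[3*b+1] - p[3*e+1], bez = p[3*b+2] - p[3*e+2];
  double cex = p[3*c] - p[3*e], cey = p[3*c+1] - p[3*e+1], cez = p[3*c+2] - p[3*e+2];
  double dex = p[3*d] - p[3*e], dey = p[3*d+1] - p[3*e+1], dez = p[3*d+2] - p[3*e+2];
  double alift = aex*aex + aey*aey + aez*aez;
  double blift = bex*bex + bey*bey + bez*bez;
  double clift = cex*cex + cey*cey + cez*cez;
  double dlift = dex*dex + dey*dey + dez*dez;
  // 4x4 determinant expansion along the lift column
  double ab = aex*bey - bex*aey, ac = aex*cey - cex*aey, ad = aex*dey - dex*aey;
  double bc = bex*cey - cex*bey, bd = bex*dey - dex*bey, cd = cex*dey - dex*cey;
  double abc = aez*bc - bez*ac + cez*ab;
  double abd = aez*bd - bez*ad + dez*ab;
  double acd = aez*cd - cez*ad + dez*ac;
  double bcd = bez*cd - cez*bd + dez*bc;
  return dlift*abc - clift*abd + blift*acd - alift*bcd;
}

struct Face {
  int a, b, c;  // sorted
  Face(int x, int y, int z) {
    if (x > y) std::swap(x, y);
    if (y > z) std::swap(y, z);
    if (x > y) std::swap(x, y);
    a = x; b = y; c = z;
  }
  bool operator<(const Face& o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix coords) {
  int n = coords.nrow();
  if (n < 2) return IntegerMatrix(0, 2);
  if (n <= 4) {
    // tessellation degenerate; every pair is trivially a neighbour
    std::vector<int> ea, eb;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) { ea.push_back(i + 1); eb.push_back(j + 1); }
    IntegerMatrix out(ea.size(), 2);
    for (size_t k = 0; k < ea.size(); ++k) { out(k, 0) = ea[k]; out(k, 1) = eb[k]; }
    return out;
  }

  std::vector<double> p(3 * (n + 4));
  Lcg rng(0);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = coords(i, k) + (rng.unif() * 2.0 - 1.0) * 1e-6;
      p[3*i + k] = v;
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double cx = (lo[0] + hi[0]) / 2, cy = (lo[1] + hi[1]) / 2, cz = (lo[2] + hi[2]) / 2;
  double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0});
  double R = 1e4 * span;
  // super-tetrahedron vertices n..n+3
  double sv[4][3] = {{cx, cy, cz + 3*R},
                     {cx - 2*R, cy - R, cz - R},
                     {cx + 2*R, cy - R, cz - R},
                     {cx, cy + 2*R, cz - R}};
  for (int i = 0; i < 4; ++i)
    for (int k = 0; k < 3; ++k) p[3*(n+i) + k] = sv[i][k];

  std::vector<Tet> tets;
  {
    Tet t; t.v[0] = n; t.v[1] = n+1; t.v[2] = n+2; t.v[3] = n+3; t.alive = true;
    if (orient3d(p.data(), t.v[0], t.v[1], t.v[2], t.v[3]) < 0) std::swap(t.v[0], t.v[1]);
    tets.push_back(t);
  }

  std::vector<int> bad;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      const int* v = tets[t].v;
      if (insphere(p.data(), v[0], v[1], v[2], v[3], i) > 0) bad.push_back((int)t);
    }
    // boundary faces of the cavity = faces belonging to exactly one bad tetra
    std::map<Face, int> fc;
    for (int bt : bad) {
      const int* v = tets[bt].v;
      fc[Face(v[0], v[1], v[2])]++;
      fc[Face(v[0], v[1], v[3])]++;
      fc[Face(v[0], v[2], v[3])]++;
      fc[Face(v[1], v[2], v[3])]++;
      tets[bt].alive = false;
    }
    for (std::map<Face, int>::iterator it = fc.begin(); it != fc.end(); ++it) {
      if (it->second != 1) continue;
      Tet t;
      t.v[0] = it->first.a; t.v[1] = it->first.b; t.v[2] = it->first.c; t.v[3] = i;
      t.alive = true;
      if (orient3d(p.data(), t.v[0], t.v[1], t.v[2], t.v[3]) < 0) std::swap(t.v[0], t.v[1]);
      tets.push_back(t);
    }
    // periodically compact to keep the scan short
    if (tets.size() > 8u * (size_t)std::max(n, 64)) {
      std::vector<Tet> keep;
      keep.reserve(tets.size() / 2);
      for (size_t t = 0; t < tets.size(); ++t)
        if (tets[t].alive) keep.push_back(tets[t]);
      tets.swap(keep);
    }
  }

  std::map<std::pair<int,int>, bool> edges;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    const int* v = tets[t].v;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int i = v[a], j = v[b];
        if (i >= n || j >= n) continue;
        if (i > j) std::swap(i, j);
        edges[std::make_pair(i, j)] = true;
      }
  }
  IntegerMatrix out((int)edges.size(), 2);
  int r = 0;
  for (std::map<std::pair<int,int>, bool>::iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first.first + 1;
    out(r, 1) = it->first.second + 1;
  }
  return out;
}
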
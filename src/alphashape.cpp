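// 3D Delaunay tetrahedralization (incremental Bowyer-Watson) for alpha-shape
// volume estimation of the mouth-cavity endocast.
//
// Scope: point clouds of a few thousand landmarks per frame; an O(n * T)
// cavity search per insertion is fast enough and avoids walk-based locate
// bookkeeping.
//
// Robustness: input is rescaled to the unit box and deterministically
// jittered (~1e-6 of the cloud extent) so cospherical and coplanar
// degeneracies (common in grid-like landmark sets) break consistently. The
// four bootstrap vertices are treated as points at infinity: every predicate
// involving them is evaluated symbolically as a polynomial in the bootstrap
// scale K and decided by its leading coefficient (the K -> infinity limit),
// so the finite part of the triangulation is the true Delaunay
// tetrahedralization of the data. Finite-only tests use a cached
// double-precision circumcenter with a guard band and fall back to a
// long-double insphere determinant near ties. Volumes and circumradii
// reported to R are computed from the original, unjittered coordinates.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

typedef long double ld;

// ---- polynomial-in-K arithmetic (degree <= 5 arises; length 8 is safe) ----
const int PDEG = 8;
struct Poly {
  ld c[PDEG];
  Poly() { for (int i = 0; i < PDEG; ++i) c[i] = 0.0L; }
};

inline Poly pconst(ld v) { Poly p; p.c[0] = v; return p; }
inline Poly plin(ld v0, ld v1) { Poly p; p.c[0] = v0; p.c[1] = v1; return p; }
inline Poly padd(const Poly& a, const Poly& b) {
  Poly r; for (int i = 0; i < PDEG; ++i) r.c[i] = a.c[i] + b.c[i]; return r;
}
inline Poly psub(const Poly& a, const Poly& b) {
  Poly r; for (int i = 0; i < PDEG; ++i) r.c[i] = a.c[i] - b.c[i]; return r;
}
inline Poly pmul(const Poly& a, const Poly& b) {
  Poly r;
  for (int i = 0; i < PDEG; ++i) {
    if (a.c[i] == 0.0L) continue;
    for (int j = 0; j + i < PDEG; ++j)
      if (b.c[j] != 0.0L) r.c[i + j] += a.c[i] * b.c[j];
  }
  return r;
}
inline int psign(const Poly& p, ld tiny = 1e-24L) {
  for (int i = PDEG - 1; i >= 0; --i) {
    if (p.c[i] > tiny) return 1;
    if (p.c[i] < -tiny) return -1;
  }
  return 0;
}
inline Poly pdet3(const Poly m[3][3]) {
  return psub(padd(pmul(m[0][0], psub(pmul(m[1][1], m[2][2]), pmul(m[1][2], m[2][1]))),
                   pmul(m[0][2], psub(pmul(m[1][0], m[2][1]), pmul(m[1][1], m[2][0])))),
              pmul(m[0][1], psub(pmul(m[1][0], m[2][2]), pmul(m[1][2], m[2][0]))));
}

// ---- plain long-double helpers for all-finite configurations ----
inline ld det3l(ld a1, ld a2, ld a3, ld b1, ld b2, ld b3, ld c1, ld c2, ld c3) {
  return a1 * (b2 * c3 - b3 * c2)
       - a2 * (b1 * c3 - b3 * c1)
       + a3 * (b1 * c2 - b2 * c1);
}

inline ld orient3d_fin(const double* a, const double* b,
                       const double* c, const double* d) {
  return det3l((ld)b[0] - a[0], (ld)b[1] - a[1], (ld)b[2] - a[2],
               (ld)c[0] - a[0], (ld)c[1] - a[1], (ld)c[2] - a[2],
               (ld)d[0] - a[0], (ld)d[1] - a[1], (ld)d[2] - a[2]);
}

// insphere determinant (rows q_i - p with lifted coordinate); for a
// positively oriented finite tet, p is strictly inside iff value < 0
inline ld insphere_fin(const double* a, const double* b, const double* c,
                       const double* d, const double* p) {
  ld m[4][4];
  const double* q[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    ld dx = (ld)q[i][0] - p[0];
    ld dy = (ld)q[i][1] - p[1];
    ld dz = (ld)q[i][2] - p[2];
    m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
    m[i][3] = dx * dx + dy * dy + dz * dz;
  }
  ld det = 0.0L;
  for (int i = 0; i < 4; ++i) {
    int rows[3], k = 0;
    for (int r = 0; r < 4; ++r) if (r != i) rows[k++] = r;
    ld minor = det3l(m[rows[0]][0], m[rows[0]][1], m[rows[0]][2],
                     m[rows[1]][0], m[rows[1]][1], m[rows[1]][2],
                     m[rows[2]][0], m[rows[2]][1], m[rows[2]][2]);
    det += m[i][3] * (((i + 3) % 2 == 0) ? minor : -minor);
  }
  return det;
}

bool circumsphere(const double* a, const double* b, const double* c,
                  const double* d, double* cc, double& r2) {
  // long double throughout so the cached center is accurate enough for a
  // tight guard band even on moderately flat tets
  ld M[3][3], rhs[3];
  const double* pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    ld s = 0.0L;
    for (int k = 0; k < 3; ++k) {
      ld dk = (ld)pts[i][k] - a[k];
      M[i][k] = 2.0L * dk;
      s += dk * ((ld)pts[i][k] + a[k]);
    }
    rhs[i] = s;
  }
  ld det = det3l(M[0][0], M[0][1], M[0][2],
                 M[1][0], M[1][1], M[1][2],
                 M[2][0], M[2][1], M[2][2]);
  if (std::fabs((double)det) < 1e-9) return false;  // sliver: exact path only
  for (int k = 0; k < 3; ++k) {
    ld Mk[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Mk[i][j] = (j == k) ? rhs[i] : M[i][j];
    cc[k] = (double)(det3l(Mk[0][0], Mk[0][1], Mk[0][2],
                           Mk[1][0], Mk[1][1], Mk[1][2],
                           Mk[2][0], Mk[2][1], Mk[2][2]) / det);
  }
  double dx = cc[0] - a[0], dy = cc[1] - a[1], dz = cc[2] - a[2];
  r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

inline double hash_unit(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  return (double)(x >> 11) / 9007199254740992.0 - 0.5;
}

struct Tet {
  int v[4];
  double cc[3];
  double r2;
  int n_inf;     // number of bootstrap (infinite) vertices (0..4)
  int inf_idx;   // index (0..3) of the infinite vertex when n_inf == 1
  bool inf;      // n_inf > 0
  bool degen;    // finite but circumcenter unreliable
  bool alive;
};

struct Mesh {
  std::vector<std::array<double,3> > P;  // 4 bootstrap slots then data points
  // bootstrap vertices at infinity: direction per vertex, nominal center
  double dir[4][3];
  double ctr[3];
  std::vector<Tet> tets;

  bool is_inf(int v) const { return v < 4; }

  // polynomial rows (in K) for a vertex, optionally offset by finite p
  void vertex_poly(int v, const double* p, Poly out[3]) const {
    if (is_inf(v)) {
      for (int k = 0; k < 3; ++k)
        out[k] = plin((ld)ctr[k] - (p ? p[k] : 0.0), dir[v][k]);
    } else {
      for (int k = 0; k < 3; ++k)
        out[k] = pconst((ld)P[v][k] - (p ? p[k] : 0.0));
    }
  }

  int orient_sym(const int vv[4]) const {
    bool anyinf = is_inf(vv[0]) || is_inf(vv[1]) || is_inf(vv[2]) || is_inf(vv[3]);
    if (!anyinf)
      return (orient3d_fin(P[vv[0]].data(), P[vv[1]].data(),
                           P[vv[2]].data(), P[vv[3]].data()) > 0.0L) ? 1 : -1;
    Poly a[3], rows[3][3];
    vertex_poly(vv[0], NULL, a);
    for (int i = 0; i < 3; ++i) {
      Poly b[3];
      vertex_poly(vv[i + 1], NULL, b);
      for (int k = 0; k < 3; ++k) rows[i][k] = psub(b[k], a[k]);
    }
    return psign(pdet3(rows));
  }

  // conflict test: is p inside the (possibly limiting) circumsphere?
  bool conflict(const Tet& t, const double* p) const {
    if (!t.inf && !t.degen) {
      double dx = p[0] - t.cc[0], dy = p[1] - t.cc[1], dz = p[2] - t.cc[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double margin = t.r2 - d2;
      double band = 1e-8 * (t.r2 + 1.0);
      if (margin > band) return true;
      if (margin < -band) return false;
      return insphere_fin(P[t.v[0]].data(), P[t.v[1]].data(),
                          P[t.v[2]].data(), P[t.v[3]].data(), p) < 0.0L;
    }
    if (!t.inf)
      return insphere_fin(P[t.v[0]].data(), P[t.v[1]].data(),
                          P[t.v[2]].data(), P[t.v[3]].data(), p) < 0.0L;
    if (t.n_inf == 1) {
      // leading K^2 coefficient of the symbolic determinant: |d|^2 times
      // the signed cofactor of the infinite row's lifted entry, i.e. an
      // orientation test of p against the finite face; ties fall through
      // to the full polynomial
      int i = t.inf_idx;
      ld rows[3][3];
      int k = 0;
      for (int r = 0; r < 4; ++r) {
        if (r == i) continue;
        for (int c2 = 0; c2 < 3; ++c2)
          rows[k][c2] = (ld)P[t.v[r]][c2] - p[c2];
        ++k;
      }
      ld det = det3l(rows[0][0], rows[0][1], rows[0][2],
                     rows[1][0], rows[1][1], rows[1][2],
                     rows[2][0], rows[2][1], rows[2][2]);
      ld lead = (((i + 3) % 2 == 0) ? det : -det) * 3.0L;  // |d|^2 = 3
      if (lead < -1e-12L) return true;
      if (lead > 1e-12L) return false;
    }
    // symbolic: det of rows (v_i - p, |v_i - p|^2) as polynomial in K;
    // tet is stored positively oriented (in the symbolic sense), so
    // conflict iff leading sign < 0; ties count as conflict to keep the
    // cavity closed
    Poly m[4][4];
    for (int i = 0; i < 4; ++i) {
      Poly row[3];
      vertex_poly(t.v[i], p, row);
      Poly w = pconst(0.0L);
      for (int k = 0; k < 3; ++k) {
        m[i][k] = row[k];
        w = padd(w, pmul(row[k], row[k]));
      }
      m[i][3] = w;
    }
    Poly det = pconst(0.0L);
    for (int i = 0; i < 4; ++i) {
      int rows[3], k = 0;
      for (int r = 0; r < 4; ++r) if (r != i) rows[k++] = r;
      Poly sub[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          sub[a][b] = m[rows[a]][b];
      Poly term = pmul(m[i][3], pdet3(sub));
      if ((i + 3) % 2 == 0) det = padd(det, term);
      else det = psub(det, term);
    }
    return psign(det) <= 0;
  }

  void make_tet(int i0, int i1, int i2, int i3) {
    Tet t;
    t.v[0] = i0; t.v[1] = i1; t.v[2] = i2; t.v[3] = i3;
    int s = orient_sym(t.v);
    if (s < 0) std::swap(t.v[2], t.v[3]);
    t.n_inf = 0; t.inf_idx = -1;
    for (int i = 0; i < 4; ++i)
      if (is_inf(t.v[i])) { ++t.n_inf; t.inf_idx = i; }
    if (t.n_inf != 1) t.inf_idx = -1;
    t.inf = t.n_inf > 0;
    t.degen = false;
    if (!t.inf) {
      t.degen = !circumsphere(P[t.v[0]].data(), P[t.v[1]].data(),
                              P[t.v[2]].data(), P[t.v[3]].data(), t.cc, t.r2);
      if (t.degen) { t.cc[0] = t.cc[1] = t.cc[2] = 0.0; t.r2 = 0.0; }
    } else {
      t.cc[0] = t.cc[1] = t.cc[2] = 0.0; t.r2 = 0.0;
    }
    t.alive = true;
    tets.push_back(t);
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D Delaunay tetrahedralization");
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");

  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = pts(i, k);
      if (!R_finite(v)) stop("non-finite coordinate at row %d", i + 1);
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  if (scale <= 0.0) scale = 1.0;

  Mesh M;
  M.P.resize(4 + n);
  M.ctr[0] = M.ctr[1] = M.ctr[2] = 0.5;
  double sgn[4][3] = {{1,1,1}, {1,-1,-1}, {-1,1,-1}, {-1,-1,1}};
  for (int s = 0; s < 4; ++s)
    for (int k = 0; k < 3; ++k) {
      M.dir[s][k] = sgn[s][k];
      M.P[s][k] = 0.0;  // placeholder; bootstrap vertices are symbolic
    }
  const double jit = 1e-6;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      M.P[4 + i][k] = (pts(i, k) - lo[k]) / scale
                    + jit * hash_unit((uint64_t)i * 3u + (uint64_t)k);

  M.tets.reserve(16 * (size_t)n);
  M.make_tet(0, 1, 2, 3);
  size_t n_dead = 0;

  static const int fidx[4][3] = {{1,2,3}, {0,3,2}, {0,1,3}, {0,2,1}};
  typedef std::array<int,3> FaceKey;
  std::vector<int> bad;

  for (int ip = 0; ip < n; ++ip) {
    const double* p = M.P[4 + ip].data();
    bad.clear();
    for (size_t t = 0; t < M.tets.size(); ++t) {
      if (!M.tets[t].alive) continue;
      if (M.conflict(M.tets[t], p)) bad.push_back((int)t);
    }
    if (bad.empty())
      stop("internal error: inserted point conflicts with no tetrahedron");

    std::map<FaceKey, std::pair<int, std::array<int,3> > > faces;
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tet& t = M.tets[bad[b]];
      for (int f = 0; f < 4; ++f) {
        std::array<int,3> tri = {t.v[fidx[f][0]], t.v[fidx[f][1]], t.v[fidx[f][2]]};
        FaceKey key = tri;
        std::sort(key.begin(), key.end());
        std::map<FaceKey, std::pair<int, std::array<int,3> > >::iterator it = faces.find(key);
        if (it == faces.end()) faces[key] = std::make_pair(1, tri);
        else it->second.first += 1;
      }
    }
    for (size_t b = 0; b < bad.size(); ++b) M.tets[bad[b]].alive = false;
    n_dead += bad.size();
    for (std::map<FaceKey, std::pair<int, std::array<int,3> > >::iterator it = faces.begin();
         it != faces.end(); ++it) {
      if (it->second.first != 1) continue;
      const std::array<int,3>& tri = it->second.second;
      M.make_tet(4 + ip, tri[0], tri[1], tri[2]);
    }

    if (n_dead > 512) {
      std::vector<Tet> live;
      live.reserve(M.tets.size());
      for (size_t t = 0; t < M.tets.size(); ++t)
        if (M.tets[t].alive) live.push_back(M.tets[t]);
      M.tets.swap(live);
      n_dead = 0;
    }
  }

  std::vector<std::array<int,4> > keep;
  for (size_t t = 0; t < M.tets.size(); ++t) {
    if (!M.tets[t].alive || M.tets[t].inf) continue;
    const Tet& tt = M.tets[t];
    std::array<int,4> ids = {tt.v[0] - 4, tt.v[1] - 4, tt.v[2] - 4, tt.v[3] - 4};
    keep.push_back(ids);
  }

  const int m = (int)keep.size();
  IntegerMatrix out_t(m, 4);
  NumericVector out_vol(m), out_r(m);
  for (int i = 0; i < m; ++i) {
    double q[4][3];
    for (int j = 0; j < 4; ++j) {
      out_t(i, j) = keep[i][j] + 1;  // 1-based for R
      for (int k = 0; k < 3; ++k) q[j][k] = pts(keep[i][j], k);
    }
    out_vol[i] = std::fabs((double)orient3d_fin(q[0], q[1], q[2], q[3])) / 6.0;
    double cc[3], r2;
    if (circumsphere(q[0], q[1], q[2], q[3], cc, r2))
      out_r[i] = std::sqrt(r2);
    else
      out_r[i] = R_PosInf;
  }

  return List::create(_["tets"] = out_t,
                      _["volume"] = out_vol,
                      _["circumradius"] = out_r);
}
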
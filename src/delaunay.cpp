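// Incremental 3D Delaunay tessellation (Bowyer-Watson).
//
// Backbone of the Voronoi probe-sphere construction (circumcenters of the
// Delaunay tetrahedra are the Voronoi vertices; tetrahedra sharing a facet
// correspond to Voronoi-edge-connected vertices) and of the alpha complex
// used for void surface reconstruction (tetrahedra filtered by circumradius).
//
// Robustness strategy: callers deterministically jitter degenerate inputs;
// the in-sphere test is conservative (near-cospherical points are treated as
// outside) so the cavity stays star-shaped and the mesh stays valid.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];     // vertex ids (0-based; >= n_input means super-vertex)
  int nb[4];    // nb[i] = tet opposite vertex v[i]; -1 = none
  double cc[3]; // circumcenter
  double r2;    // squared circumradius
  bool alive;
};

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

inline double orient3d(const double* a, const double* b,
                       const double* c, const double* d) {
  // > 0 when d is on the positive side of plane (a,b,c) (right-hand rule)
  return det3(b[0] - a[0], b[1] - a[1], b[2] - a[2],
              c[0] - a[0], c[1] - a[1], c[2] - a[2],
              d[0] - a[0], d[1] - a[1], d[2] - a[2]);
}

// circumcenter of tetrahedron; returns false when degenerate (flat)
bool circumsphere(const double* a, const double* b, const double* c,
                  const double* d, double* cc, double& r2) {
  double ba[3], ca[3], da[3];
  for (int k = 0; k < 3; ++k) {
    ba[k] = b[k] - a[k];
    ca[k] = c[k] - a[k];
    da[k] = d[k] - a[k];
  }
  double nb2 = ba[0]*ba[0] + ba[1]*ba[1] + ba[2]*ba[2];
  double nc2 = ca[0]*ca[0] + ca[1]*ca[1] + ca[2]*ca[2];
  double nd2 = da[0]*da[0] + da[1]*da[1] + da[2]*da[2];
  double D = 2.0 * det3(ba[0], ba[1], ba[2],
                        ca[0], ca[1], ca[2],
                        da[0], da[1], da[2]);
  if (std::fabs(D) < 1e-30) return false;
  double ux = det3(nb2, ba[1], ba[2], nc2, ca[1], ca[2], nd2, da[1], da[2]) / D;
  double uy = det3(ba[0], nb2, ba[2], ca[0], nc2, ca[2], da[0], nd2, da[2]) / D;
  double uz = det3(ba[0], ba[1], nb2, ca[0], ca[1], nc2, da[0], da[1], nd2) / D;
  cc[0] = a[0] + ux; cc[1] = a[1] + uy; cc[2] = a[2] + uz;
  r2 = ux*ux + uy*uy + uz*uz;
  return true;
}

// in-sphere predicate via the lifted 4x4 determinant in extended precision;
// the cached-circumcenter test is ill-conditioned for sliver tetrahedra and
// corrupts the incremental construction on cospherical inputs.
// For a positively oriented tet (a,b,c,d): det > 0 <=> p strictly inside
// the circumsphere.
inline long double insphere_det(const double* a, const double* b,
                                const double* c, const double* d,
                                const double* p) {
  long double m[4][4];
  const double* v[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    long double dx = (long double)v[i][0] - p[0];
    long double dy = (long double)v[i][1] - p[1];
    long double dz = (long double)v[i][2] - p[2];
    m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
    m[i][3] = dx * dx + dy * dy + dz * dz;
  }
  // expansion along the lifted (4th) column, minors over ascending rows
  static const int rows[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
  long double det = 0.0L;
  for (int i = 0; i < 4; ++i) {
    const int* r = rows[i];
    long double minor =
      m[r[0]][0] * (m[r[1]][1] * m[r[2]][2] - m[r[1]][2] * m[r[2]][1]) -
      m[r[0]][1] * (m[r[1]][0] * m[r[2]][2] - m[r[1]][2] * m[r[2]][0]) +
      m[r[0]][2] * (m[r[1]][0] * m[r[2]][1] - m[r[1]][1] * m[r[2]][0]);
    long double sign = (i % 2 == 0) ? -1.0L : 1.0L; // (-1)^(i+3)
    det += sign * m[i][3] * minor;
  }
  return det;
}

struct FaceKey {
  int a, b, c; // sorted vertex ids
  bool operator==(const FaceKey& o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};

struct FaceKeyHash {
  std::size_t operator()(const FaceKey& k) const {
    std::size_t h = (std::size_t)k.a;
    h = h * 1000003u ^ (std::size_t)k.b;
    h = h * 1000003u ^ (std::size_t)k.c;
    return h;
  }
};

inline FaceKey make_face(int a, int b, int c) {
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  FaceKey k; k.a = a; k.b = b; k.c = c;
  return k;
}

class Delaunay3 {
public:
  std::vector<double> pts; // 3 * (n + 4)
  std::vector<Tet> tets;
  int n;
  int forced = 0;
  int guard_exhausted = 0;

  const double* P(int i) const { return &pts[3 * i]; }

  explicit Delaunay3(const NumericMatrix& X) {
    n = X.nrow();
    pts.resize(3 * (n + 4));
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double v = X(i, k);
        pts[3 * i + k] = v;
        if (v < lo[k]) lo[k] = v;
        if (v > hi[k]) hi[k] = v;
      }
    double cx = 0.5 * (lo[0] + hi[0]), cy = 0.5 * (lo[1] + hi[1]),
           cz = 0.5 * (lo[2] + hi[2]);
    double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0});
    double R = 50.0 * span;
    // regular super-tetrahedron around the bounding box
    double sv[4][3] = {
      { cx,          cy,           cz + 3.0 * R },
      { cx,          cy + 2.828 * R, cz - R },
      { cx - 2.449 * R, cy - 1.414 * R, cz - R },
      { cx + 2.449 * R, cy - 1.414 * R, cz - R }
    };
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 3; ++k) pts[3 * (n + j) + k] = sv[j][k];

    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    // enforce positive orientation
    if (orient3d(P(t0.v[0]), P(t0.v[1]), P(t0.v[2]), P(t0.v[3])) < 0)
      std::swap(t0.v[0], t0.v[1]);
    for (int j = 0; j < 4; ++j) t0.nb[j] = -1;
    circumsphere(P(t0.v[0]), P(t0.v[1]), P(t0.v[2]), P(t0.v[3]), t0.cc, t0.r2);
    t0.alive = true;
    tets.push_back(t0);
  }

  // exact-ish in-sphere: lifted determinant (tets stored positively
  // oriented), conservative on near-cospherical configurations
  bool in_sphere(const Tet& t, const double* p) const {
    const double* a = P(t.v[0]);
    const double* b = P(t.v[1]);
    const double* c = P(t.v[2]);
    const double* d = P(t.v[3]);
    long double det = insphere_det(a, b, c, d, p);
    long double lift = 0.0L;
    for (int k = 0; k < 3; ++k) {
      long double da = a[k] - p[k], db = b[k] - p[k], dc = c[k] - p[k],
                  dd = d[k] - p[k];
      lift += da*da + db*db + dc*dc + dd*dd;
    }
    long double tol = 1e-13L * lift * lift * sqrtl(lift);
    return det < -tol; // positively oriented tet: negative det <=> inside
  }

  // orientation in extended precision; mag returns the term magnitude for
  // scale-aware degeneracy decisions
  static long double orient3d_ld(const double* a, const double* b,
                                 const double* c, const double* d,
                                 long double& mag) {
    long double bx = (long double)b[0] - a[0], by = (long double)b[1] - a[1],
                bz = (long double)b[2] - a[2];
    long double cx = (long double)c[0] - a[0], cy = (long double)c[1] - a[1],
                cz = (long double)c[2] - a[2];
    long double dx = (long double)d[0] - a[0], dy = (long double)d[1] - a[1],
                dz = (long double)d[2] - a[2];
    long double t1 = bx * (cy * dz - cz * dy);
    long double t2 = by * (cx * dz - cz * dx);
    long double t3 = bz * (cx * dy - cy * dx);
    mag = fabsl(t1) + fabsl(t2) + fabsl(t3);
    return t1 - t2 + t3;
  }

  // walk from tet `start` to a tet containing p; the qualifying face is
  // picked in pseudo-random order (stochastic walk) so the traversal cannot
  // cycle on the conservative, not-exactly-Delaunay structure
  int locate(int start, const double* p) const {
    int cur = start;
    int prev = -1;
    unsigned rng = 0x9e3779b9u ^ (unsigned)start;
    int guard = 16 * (int)tets.size() + 64;
    while (guard-- > 0) {
      const Tet& t = tets[cur];
      int next = -1;
      rng = rng * 1664525u + 1013904223u;
      for (int jj = 0; jj < 4; ++jj) {
        int j = (int)((jj + (rng >> 16)) & 3);
        int a = t.v[(j + 1) & 3], b = t.v[(j + 2) & 3], c = t.v[(j + 3) & 3];
        long double mag_p;
        long double op = orient3d_ld(P(a), P(b), P(c), p, mag_p);
        // tets are stored positively oriented, so the side of face j that
        // contains the opposite vertex is fixed by index parity; this stays
        // valid inside sliver tets where an orientation test on the
        // opposite vertex itself would be degenerate
        bool sd = (j % 2) == 1;
        bool sp = op > 0;
        if (sd != sp && fabsl(op) > 1e-14L * mag_p) {
          int nb = t.nb[j];
          if (nb >= 0 && nb != prev && tets[nb].alive) { next = nb; break; }
          if (nb >= 0 && tets[nb].alive) { next = nb; } // allow going back
        }
      }
      if (next < 0) return cur;
      prev = cur; cur = next;
    }
    const_cast<Delaunay3*>(this)->guard_exhausted++;
    return cur; // guard exhausted; jittered inputs should never get here
  }

  // does tet t contain p (boundary counts as inside)?
  bool contains(const Tet& t, const double* p) const {
    for (int j = 0; j < 4; ++j) {
      int a = t.v[(j + 1) & 3], b = t.v[(j + 2) & 3], c = t.v[(j + 3) & 3];
      long double mag;
      long double op = orient3d_ld(P(a), P(b), P(c), p, mag);
      bool sd = (j % 2) == 1;
      if ((op > 0) != sd && fabsl(op) > 1e-14L * mag) return false;
    }
    return true;
  }

  void insert(int ip, int& hint) {
    const double* p = P(ip);
    int t0 = locate(hint, p);
    if (!contains(tets[t0], p)) {
      // walk failed (cycled out); exhaustive containment scan is sound
      for (size_t ti = 0; ti < tets.size(); ++ti)
        if (tets[ti].alive && contains(tets[ti], p)) { t0 = (int)ti; break; }
    }
    // grow cavity of tets whose circumsphere contains p
    std::vector<int> cav;
    std::vector<char> incav(tets.size(), 0);
    std::vector<int> stack;
    // the containing tet is always part of the cavity: p lies inside its
    // circumsphere geometrically even when the conservative predicate
    // declines to say so (sliver case)
    int seed = t0;
    if (!in_sphere(tets[t0], p)) ++forced;
    stack.push_back(seed); incav[seed] = 1;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      cav.push_back(ti);
      for (int j = 0; j < 4; ++j) {
        int nb = tets[ti].nb[j];
        if (nb >= 0 && tets[nb].alive && !incav[nb] && in_sphere(tets[nb], p)) {
          incav[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces of the cavity -> new tets
    std::unordered_map<FaceKey, std::pair<int,int>, FaceKeyHash> open_face;
    std::vector<int> fresh;
    for (size_t ci = 0; ci < cav.size(); ++ci) {
      int ti = cav[ci];
      Tet t = tets[ti]; // by value: push_back below may reallocate `tets`
      for (int j = 0; j < 4; ++j) {
        int nb = t.nb[j];
        if (nb >= 0 && incav[nb]) continue; // internal face
        int a = t.v[(j + 1) & 3], b = t.v[(j + 2) & 3], c = t.v[(j + 3) & 3];
        // orient the new tet (a,b,c,p) positively
        long double mag;
        if (orient3d_ld(P(a), P(b), P(c), p, mag) < 0) std::swap(b, c);
        Tet nt;
        nt.v[0] = a; nt.v[1] = b; nt.v[2] = c; nt.v[3] = ip;
        nt.nb[3] = nb; // face (a,b,c) opposite p borders the outside tet
        nt.nb[0] = nt.nb[1] = nt.nb[2] = -1;
        if (!circumsphere(P(nt.v[0]), P(nt.v[1]), P(nt.v[2]), P(nt.v[3]),
                          nt.cc, nt.r2)) {
          // flat sliver: circumcenter undefined; infinite circumradius keeps
          // it out of any alpha complex (jittered inputs rarely get here)
          nt.cc[0] = p[0]; nt.cc[1] = p[1]; nt.cc[2] = p[2];
          nt.r2 = R_PosInf;
        }
        nt.alive = true;
        int nid = (int)tets.size();
        tets.push_back(nt);
        fresh.push_back(nid);
        // fix outside neighbor's back-pointer
        if (nb >= 0) {
          Tet& out = tets[nb];
          for (int k = 0; k < 4; ++k) if (out.nb[k] == ti) { out.nb[k] = nid; break; }
        }
      }
    }
    // kill cavity tets
    for (size_t ci = 0; ci < cav.size(); ++ci) tets[cav[ci]].alive = false;
    // stitch new tets to each other across faces containing p
    for (size_t fi = 0; fi < fresh.size(); ++fi) {
      int nid = fresh[fi];
      Tet& t = tets[nid];
      for (int j = 0; j < 3; ++j) { // faces incident to p (opposite v[0..2])
        int a = t.v[(j + 1) & 3], b = t.v[(j + 2) & 3], c = t.v[(j + 3) & 3];
        // replace index arithmetic: face opposite vertex j among {0,1,2}
        int f[3]; int m = 0;
        for (int k = 0; k < 4; ++k) if (k != j) f[m++] = t.v[k];
        FaceKey key = make_face(f[0], f[1], f[2]);
        (void)a; (void)b; (void)c;
        auto it = open_face.find(key);
        if (it == open_face.end()) {
          open_face[key] = std::make_pair(nid, j);
        } else {
          int oid = it->second.first, oj = it->second.second;
          t.nb[j] = oid;
          tets[oid].nb[oj] = nid;
          open_face.erase(it);
        }
      }
    }
    if (!fresh.empty()) hint = fresh.back();
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix X) {
  int n = X.nrow();
  if (n < 4) stop("need at least 4 points for a 3D tessellation");
  Delaunay3 D(X);
  int hint = 0;
  for (int i = 0; i < n; ++i) D.insert(i, hint);

  // collect finite tets (no super-vertex)
  std::vector<int> keep;
  std::vector<int> newid(D.tets.size(), -1);
  for (size_t t = 0; t < D.tets.size(); ++t) {
    if (!D.tets[t].alive) continue;
    bool finite = true;
    for (int j = 0; j < 4; ++j) if (D.tets[t].v[j] >= n) { finite = false; break; }
    if (finite) { newid[t] = (int)keep.size(); keep.push_back((int)t); }
  }
  int m = (int)keep.size();
  IntegerMatrix tets(m, 4), nbrs(m, 4);
  NumericMatrix cc(m, 3);
  NumericVector cr(m);
  for (int i = 0; i < m; ++i) {
    const Tet& t = D.tets[keep[i]];
    for (int j = 0; j < 4; ++j) {
      tets(i, j) = t.v[j] + 1;
      int nb = t.nb[j];
      nbrs(i, j) = (nb >= 0 && newid[nb] >= 0) ? newid[nb] + 1 : 0;
    }
    cc(i, 0) = t.cc[0]; cc(i, 1) = t.cc[1]; cc(i, 2) = t.cc[2];
    cr[i] = std::sqrt(t.r2);
  }
  return List::create(_["tets"] = tets, _["neighbors"] = nbrs,
                      _["circumcenter"] = cc, _["circumradius"] = cr,
                      _["forced"] = D.forced,
                      _["guard_exhausted"] = D.guard_exhausted);
}
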
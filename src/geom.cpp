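// Distance-field and lattice kernels shared by the void-extraction and
// synthetic-data modules.  All lengths in Angstrom; boxes are orthorhombic
// and periodic distances use the minimum-image convention.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

static inline double mi(double d, double L) {
  if (L <= 0) return d;
  d -= L * std::round(d / L);
  return d;
}

// signed distance from each point to the nearest atom *sphere surface*:
// min_a (|x - c_a| - r_a).  box of length 0 (or negative) disables PBC.
// [[Rcpp::export(name = ".min_dist_to_spheres_cpp")]]
NumericVector min_dist_to_spheres_cpp(NumericMatrix pts, NumericMatrix centers,
                                      NumericVector radii, NumericVector box) {
  int m = pts.nrow(), n = centers.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int a = 0; a < n; ++a) {
      double dx = mi(px - centers(a, 0), Lx);
      double dy = mi(py - centers(a, 1), Ly);
      double dz = mi(pz - centers(a, 2), Lz);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz) - radii[a];
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// index of nearest atom center to each point (plain Euclidean, no radii)
// [[Rcpp::export(name = ".nearest_center_cpp")]]
IntegerVector nearest_center_cpp(NumericMatrix pts, NumericMatrix centers) {
  int m = pts.nrow(), n = centers.nrow();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf; int bi = 0;
    for (int a = 0; a < n; ++a) {
      double dx = pts(i, 0) - centers(a, 0);
      double dy = pts(i, 1) - centers(a, 1);
      double dz = pts(i, 2) - centers(a, 2);
      double d = dx*dx + dy*dy + dz*dz;
      if (d < best) { best = d; bi = a; }
    }
    out[i] = bi + 1;
  }
  return out;
}

// random sequential addition of hard-core centers in a periodic box,
// driven by R's RNG so that set.seed() controls the stream.
// [[Rcpp::export(name = ".rsa_insert_cpp")]]
NumericMatrix rsa_insert_cpp(NumericVector box, int n_target, double hardcore,
                             int max_attempts) {
  RNGScope scope;
  double Lx = box[0], Ly = box[1], Lz = box[2];
  double cell = std::max(hardcore, 1e-6);
  int nx = std::max(1, (int)std::floor(Lx / cell));
  int ny = std::max(1, (int)std::floor(Ly / cell));
  int nz = std::max(1, (int)std::floor(Lz / cell));
  double hx = Lx / nx, hy = Ly / ny, hz = Lz / nz;
  std::vector< std::vector<int> > cells((size_t)nx * ny * nz);
  std::vector<double> X, Y, Z;
  double hc2 = hardcore * hardcore;
  int placed = 0, attempts = 0;
  while (placed < n_target && attempts < max_attempts) {
    ++attempts;
    double x = unif_rand() * Lx, y = unif_rand() * Ly, z = unif_rand() * Lz;
    int cx = std::min((int)(x / hx), nx - 1);
    int cy = std::min((int)(y / hy), ny - 1);
    int cz = std::min((int)(z / hz), nz - 1);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          int ix = (cx + dx + nx) % nx, iy = (cy + dy + ny) % ny,
              iz = (cz + dz + nz) % nz;
          const std::vector<int>& bucket = cells[(size_t)(ix * ny + iy) * nz + iz];
          for (size_t b = 0; b < bucket.size(); ++b) {
            int j = bucket[b];
            double ddx = mi(x - X[j], Lx), ddy = mi(y - Y[j], Ly),
                   ddz = mi(z - Z[j], Lz);
            if (ddx*ddx + ddy*ddy + ddz*ddz < hc2) { ok = false; break; }
          }
        }
    if (!ok) continue;
    X.push_back(x); Y.push_back(y); Z.push_back(z);
    cells[(size_t)(cx * ny + cy) * nz + cz].push_back(placed);
    ++placed;
  }
  NumericMatrix out(placed, 3);
  for (int i = 0; i < placed; ++i) {
    out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i];
  }
  return out;
}

// Grid cavity oracle.  Marks cell centers whose distance to every atom
// sphere surface is >= probe (the probe-center accessible region), labels
// its 26-connected components (periodic wrap), then dilates each component
// by the probe radius to obtain the volume swept by admissible probe
// spheres.  Returns eroded/dilated cell counts per component plus the two
// label arrays (0 = unassigned), in x-fastest order.
// [[Rcpp::export(name = ".grid_cavity_cpp")]]
List grid_cavity_cpp(NumericMatrix centers, NumericVector radii,
                     NumericVector box, double probe, double cell,
                     bool periodic) {
  double Lx = box[0], Ly = box[1], Lz = box[2];
  int nx = std::max(1, (int)std::round(Lx / cell));
  int ny = std::max(1, (int)std::round(Ly / cell));
  int nz = std::max(1, (int)std::round(Lz / cell));
  double hx = Lx / nx, hy = Ly / ny, hz = Lz / nz;
  size_t ncell = (size_t)nx * ny * nz;
  int natom = centers.nrow();

  // atom cell list (bucket by cell index of wrapped center)
  double maxr = 0.0;
  for (int a = 0; a < natom; ++a) if (radii[a] > maxr) maxr = radii[a];
  double reach = maxr + probe;
  int sx = (int)std::ceil(reach / hx) + 1;
  int sy = (int)std::ceil(reach / hy) + 1;
  int sz = (int)std::ceil(reach / hz) + 1;
  std::vector< std::vector<int> > buckets(ncell);
  for (int a = 0; a < natom; ++a) {
    double x = centers(a, 0), y = centers(a, 1), z = centers(a, 2);
    if (periodic) {
      x -= Lx * std::floor(x / Lx);
      y -= Ly * std::floor(y / Ly);
      z -= Lz * std::floor(z / Lz);
    }
    int cx = std::min(std::max((int)(x / hx), 0), nx - 1);
    int cy = std::min(std::max((int)(y / hy), 0), ny - 1);
    int cz = std::min(std::max((int)(z / hz), 0), nz - 1);
    buckets[((size_t)cx * ny + cy) * nz + cz].push_back(a);
  }

  std::vector<char> marked(ncell, 1);
  // a cell is accessible iff no atom with |x - c_a| < r_a + probe
  for (size_t ci = 0; ci < ncell; ++ci) {
    int cx = (int)(ci / ((size_t)ny * nz));
    int cy = (int)((ci / nz) % ny);
    int cz = (int)(ci % nz);
    double px = (cx + 0.5) * hx, py = (cy + 0.5) * hy, pz = (cz + 0.5) * hz;
    bool ok = true;
    for (int dx = -sx; dx <= sx && ok; ++dx)
      for (int dy = -sy; dy <= sy && ok; ++dy)
        for (int dz = -sz; dz <= sz && ok; ++dz) {
          int ix = cx + dx, iy = cy + dy, iz = cz + dz;
          if (periodic) {
            ix = (ix % nx + nx) % nx; iy = (iy % ny + ny) % ny;
            iz = (iz % nz + nz) % nz;
          } else if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny ||
                     iz >= nz) {
            continue;
          }
          const std::vector<int>& bk = buckets[((size_t)ix * ny + iy) * nz + iz];
          for (size_t b = 0; b < bk.size(); ++b) {
            int a = bk[b];
            double ddx = px - centers(a, 0), ddy = py - centers(a, 1),
                   ddz = pz - centers(a, 2);
            if (periodic) { ddx = mi(ddx, Lx); ddy = mi(ddy, Ly); ddz = mi(ddz, Lz); }
            double lim = radii[a] + probe;
            if (ddx*ddx + ddy*ddy + ddz*ddz < lim * lim) { ok = false; break; }
          }
        }
    if (!ok) marked[ci] = 0;
  }

  // 26-connected flood fill
  std::vector<int> label(ncell, 0);
  int ncomp = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < ncell; ++start) {
    if (!marked[start] || label[start]) continue;
    ++ncomp;
    stack.clear();
    stack.push_back(start);
    label[start] = ncomp;
    while (!stack.empty()) {
      size_t ci = stack.back(); stack.pop_back();
      int cx = (int)(ci / ((size_t)ny * nz));
      int cy = (int)((ci / nz) % ny);
      int cz = (int)(ci % nz);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int ix = cx + dx, iy = cy + dy, iz = cz + dz;
            if (periodic) {
              ix = (ix + nx) % nx; iy = (iy + ny) % ny; iz = (iz + nz) % nz;
            } else if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny ||
                       iz >= nz) {
              continue;
            }
            size_t cj = ((size_t)ix * ny + iy) * nz + iz;
            if (marked[cj] && !label[cj]) {
              label[cj] = ncomp;
              stack.push_back(cj);
            }
          }
    }
  }

  // dilate: a point belongs to the void swept by probe spheres when it lies
  // within `probe` of an accessible cell center.  Cells are resolved with a
  // 2x2x2 subcell sample so partially covered boundary cells contribute
  // fractionally (reduces quantization bias).
  std::vector<int> dlabel(label);
  NumericVector ecount(ncomp), dcount(ncomp);
  int rx = (int)std::ceil(probe / hx) + 1, ry = (int)std::ceil(probe / hy) + 1,
      rz = (int)std::ceil(probe / hz) + 1;
  double probe2 = probe * probe;
  for (size_t ci = 0; ci < ncell; ++ci) {
    if (label[ci]) { dcount[label[ci] - 1] += 1.0; continue; }
    int cx = (int)(ci / ((size_t)ny * nz));
    int cy = (int)((ci / nz) % ny);
    int cz = (int)(ci % nz);
    // sub-sample points at cell-center +- h/4
    int hit = 0, bl = 0;
    double bestd = R_PosInf;
    for (int s = 0; s < 8; ++s) {
      double ox = ((s & 1) ? 0.25 : -0.25) * hx;
      double oy = ((s & 2) ? 0.25 : -0.25) * hy;
      double oz = ((s & 4) ? 0.25 : -0.25) * hz;
      bool covered = false;
      for (int dx = -rx; dx <= rx && !covered; ++dx)
        for (int dy = -ry; dy <= ry && !covered; ++dy)
          for (int dz = -rz; dz <= rz && !covered; ++dz) {
            int ix = cx + dx, iy = cy + dy, iz = cz + dz;
            if (periodic) {
              ix = (ix % nx + nx) % nx; iy = (iy % ny + ny) % ny;
              iz = (iz % nz + nz) % nz;
            } else if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny ||
                       iz >= nz) {
              continue;
            }
            size_t cj = ((size_t)ix * ny + iy) * nz + iz;
            if (!label[cj]) continue;
            double ddx = dx * hx - ox, ddy = dy * hy - oy, ddz = dz * hz - oz;
            double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (d2 <= probe2) {
              covered = true;
              if (d2 < bestd) { bestd = d2; bl = label[cj]; }
            }
          }
      if (covered) ++hit;
    }
    if (hit > 0) {
      dlabel[ci] = bl;
      dcount[bl - 1] += hit / 8.0;
    }
  }

  for (size_t ci = 0; ci < ncell; ++ci)
    if (label[ci]) ecount[label[ci] - 1] += 1.0;
  double vcell = hx * hy * hz;
  IntegerVector lab(ncell), dlab(ncell);
  for (size_t ci = 0; ci < ncell; ++ci) { lab[ci] = label[ci]; dlab[ci] = dlabel[ci]; }
  return List::create(
    _["n_components"] = ncomp,
    _["eroded_volume"] = ecount * vcell,
    _["dilated_volume"] = dcount * vcell,
    _["dims"] = IntegerVector::create(nx, ny, nz),
    _["cell_size"] = NumericVector::create(hx, hy, hz),
    _["label"] = lab,
    _["dilated_label"] = dlab);
}
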
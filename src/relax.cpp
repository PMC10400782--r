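// Zero-temperature quench of a soft-sphere packing: single-particle
// displacement moves accepted when they do not increase the harmonic
// overlap energy sum_{r<sigma} (sigma - r)^2.  Homogenizes a random
// sequential packing toward liquid-like first-shell structure at fixed
// density.  Driven by R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double mi(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

// [[Rcpp::export(name = ".relax_quench_cpp")]]
NumericMatrix relax_quench_cpp(NumericMatrix pos, NumericVector box,
                               double sigma, double step, int sweeps) {
  RNGScope scope;
  int n = pos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = pos(i,0); Y[i] = pos(i,1); Z[i] = pos(i,2); }

  double cell = sigma;
  int nx = std::max(1, (int)std::floor(Lx / cell));
  int ny = std::max(1, (int)std::floor(Ly / cell));
  int nz = std::max(1, (int)std::floor(Lz / cell));
  double hx = Lx / nx, hy = Ly / ny, hz = Lz / nz;

  std::vector< std::vector<int> > cells;
  std::vector<int> mycell(n);
  auto cell_of = [&](double x, double y, double z) {
    x -= Lx * std::floor(x / Lx); y -= Ly * std::floor(y / Ly);
    z -= Lz * std::floor(z / Lz);
    int cx = std::min((int)(x / hx), nx - 1);
    int cy = std::min((int)(y / hy), ny - 1);
    int cz = std::min((int)(z / hz), nz - 1);
    return ((size_t)cx * ny + cy) * nz + cz;
  };
  auto rebuild = [&]() {
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      size_t c = cell_of(X[i], Y[i], Z[i]);
      mycell[i] = (int)c;
      cells[c].push_back(i);
    }
  };
  auto local_energy = [&](int i, double x, double y, double z) {
    double e = 0.0;
    size_t c = cell_of(x, y, z);
    int cx = (int)(c / ((size_t)ny * nz));
    int cy = (int)((c / nz) % ny);
    int cz = (int)(c % nz);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int ix = (cx + dx + nx) % nx, iy = (cy + dy + ny) % ny,
              iz = (cz + dz + nz) % nz;
          const std::vector<int>& bk = cells[((size_t)ix * ny + iy) * nz + iz];
          for (size_t b = 0; b < bk.size(); ++b) {
            int j = bk[b];
            if (j == i) continue;
            double ddx = mi(x - X[j], Lx), ddy = mi(y - Y[j], Ly),
                   ddz = mi(z - Z[j], Lz);
            double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (r2 < sigma * sigma) {
              double r = std::sqrt(r2);
              e += (sigma - r) * (sigma - r);
            }
          }
        }
    return e;
  };

  rebuild();
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double x = X[i] + (unif_rand() * 2.0 - 1.0) * step;
      double y = Y[i] + (unif_rand() * 2.0 - 1.0) * step;
      double z = Z[i] + (unif_rand() * 2.0 - 1.0) * step;
      double e0 = local_energy(i, X[i], Y[i], Z[i]);
      double e1 = local_energy(i, x, y, z);
      if (e1 <= e0) {
        x -= Lx * std::floor(x / Lx);
        y -= Ly * std::floor(y / Ly);
        z -= Lz * std::floor(z / Lz);
        size_t c = cell_of(x, y, z);
        if ((int)c != mycell[i]) {
          std::vector<int>& old = cells[mycell[i]];
          for (size_t b = 0; b < old.size(); ++b)
            if (old[b] == i) { old.erase(old.begin() + b); break; }
          cells[c].push_back(i);
          mycell[i] = (int)c;
        }
        X[i] = x; Y[i] = y; Z[i] = z;
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=X[i]; out(i,1)=Y[i]; out(i,2)=Z[i]; }
  return out;
}

// distance from a point to the phantom region boundary (negative inside):
// sphere of core_radius at center, optionally united with capsule tendrils
// whose axes run from the center to reach*dir (cap radius trad).
static double region_dist(double x, double y, double z,
                          const double* center, double core_radius,
                          const Rcpp::NumericMatrix& dirs, double reach,
                          double trad, double Lx, double Ly, double Lz) {
  double dx = mi(x - center[0], Lx), dy = mi(y - center[1], Ly),
         dz = mi(z - center[2], Lz);
  double d = std::sqrt(dx*dx + dy*dy + dz*dz) - core_radius;
  for (int k = 0; k < dirs.nrow(); ++k) {
    double ux = dirs(k,0), uy = dirs(k,1), uz = dirs(k,2);
    double t = dx*ux + dy*uy + dz*uz;
    if (t < 0) t = 0;
    if (t > reach) t = reach;
    double ex = dx - t*ux, ey = dy - t*uy, ez = dz - t*uz;
    double dk = std::sqrt(ex*ex + ey*ey + ez*ez) - trad;
    if (dk < d) d = dk;
  }
  return d;
}

// rigid-molecule quench against a phantom-region wall.  opos: oxygen
// positions; h1/h2: fixed H offsets from O.  Pair term: harmonic O-O
// overlap at sigma; wall term: harmonic penetration of any atom sphere
// into the region (weight wall_w).  Accepts non-increasing moves only.
// [[Rcpp::export(name = ".relax_wall_cpp")]]
NumericMatrix relax_wall_cpp(NumericMatrix opos, NumericMatrix h1,
                             NumericMatrix h2, NumericVector box,
                             double sigma, double step, int sweeps,
                             NumericVector center, double core_radius,
                             NumericMatrix dirs, double reach, double trad,
                             double rO, double rH, double wall_w,
                             double att_w, double att_range) {
  RNGScope scope;
  int n = opos.nrow();
  double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i]=opos(i,0); Y[i]=opos(i,1); Z[i]=opos(i,2); }

  double cell = sigma;
  int nx = std::max(1, (int)std::floor(Lx / cell));
  int ny = std::max(1, (int)std::floor(Ly / cell));
  int nz = std::max(1, (int)std::floor(Lz / cell));
  double hx = Lx / nx, hy = Ly / ny, hz = Lz / nz;
  std::vector< std::vector<int> > cells;
  std::vector<int> mycell(n);
  auto cell_of = [&](double x, double y, double z) {
    x -= Lx * std::floor(x / Lx); y -= Ly * std::floor(y / Ly);
    z -= Lz * std::floor(z / Lz);
    int cx = std::min((int)(x / hx), nx - 1);
    int cy = std::min((int)(y / hy), ny - 1);
    int cz = std::min((int)(z / hz), nz - 1);
    return ((size_t)cx * ny + cy) * nz + cz;
  };
  auto rebuild = [&]() {
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      size_t c = cell_of(X[i], Y[i], Z[i]);
      mycell[i] = (int)c;
      cells[c].push_back(i);
    }
  };
  auto energy = [&](int i, double x, double y, double z) {
    double e = 0.0;
    size_t c = cell_of(x, y, z);
    int cx = (int)(c / ((size_t)ny * nz));
    int cy = (int)((c / nz) % ny);
    int cz = (int)(c % nz);
    for (int ddx = -1; ddx <= 1; ++ddx)
      for (int ddy = -1; ddy <= 1; ++ddy)
        for (int ddz = -1; ddz <= 1; ++ddz) {
          int ix = (cx + ddx + nx) % nx, iy = (cy + ddy + ny) % ny,
              iz = (cz + ddz + nz) % nz;
          const std::vector<int>& bk = cells[((size_t)ix * ny + iy) * nz + iz];
          for (size_t b = 0; b < bk.size(); ++b) {
            int j = bk[b];
            if (j == i) continue;
            double ax = mi(x - X[j], Lx), ay = mi(y - Y[j], Ly),
                   az = mi(z - Z[j], Lz);
            double r2 = ax*ax + ay*ay + az*az;
            if (r2 < sigma * sigma) {
              double r = std::sqrt(r2);
              e += (sigma - r) * (sigma - r);
            }
          }
        }
    // wall: O plus the two rigid H sites
    double axs[3] = {x, x + h1(i,0), x + h2(i,0)};
    double ays[3] = {y, y + h1(i,1), y + h2(i,1)};
    double azs[3] = {z, z + h1(i,2), z + h2(i,2)};
    double rad[3] = {rO, rH, rH};
    for (int a = 0; a < 3; ++a) {
      double d = region_dist(axs[a], ays[a], azs[a], &center[0], core_radius,
                             dirs, reach, trad, Lx, Ly, Lz);
      if (d < rad[a]) {
        double pen = rad[a] - d;
        e += wall_w * pen * pen;
      } else if (d < rad[a] + att_range) {
        // short-range wall attraction: reproduces the contact-density
        // enhancement a fluid shows at a hard wall
        double gap = d - rad[a];
        e += att_w * gap * gap;
      } else {
        e += att_w * att_range * att_range;
      }
    }
    return e;
  };

  rebuild();
  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double x = X[i] + (unif_rand() * 2.0 - 1.0) * step;
      double y = Y[i] + (unif_rand() * 2.0 - 1.0) * step;
      double z = Z[i] + (unif_rand() * 2.0 - 1.0) * step;
      if (energy(i, x, y, z) <= energy(i, X[i], Y[i], Z[i])) {
        x -= Lx * std::floor(x / Lx);
        y -= Ly * std::floor(y / Ly);
        z -= Lz * std::floor(z / Lz);
        size_t c = cell_of(x, y, z);
        if ((int)c != mycell[i]) {
          std::vector<int>& old = cells[mycell[i]];
          for (size_t b = 0; b < old.size(); ++b)
            if (old[b] == i) { old.erase(old.begin() + b); break; }
          cells[c].push_back(i);
          mycell[i] = (int)c;
        }
        X[i] = x; Y[i] = y; Z[i] = z;
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=X[i]; out(i,1)=Y[i]; out(i,2)=Z[i]; }
  return out;
}
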
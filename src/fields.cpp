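#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid layout contract: values are stored x-fastest, then y, then z;
// point (ix,iy,iz) sits at origin + spacing*(ix,iy,iz); linear index
// ix + nx*(iy + ny*iz).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Mark grid points inside the closed van der Waals sphere of any atom.
static void occupancy_mask(const NumericMatrix& coords,
                           const NumericVector& radii,
                           const NumericVector& origin,
                           double spacing,
                           const IntegerVector& dims,
                           std::vector<char>& inside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  inside.assign((size_t)nx * ny * nz, 0);
  const int natom = coords.nrow();
  for (int a = 0; a < natom; ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double r = radii[a];
    const double r2 = r * r + 1e-12;  // closed sphere: boundary is inside
    int ixlo = clampi((int)std::ceil ((cx - r - origin[0]) / spacing - 1e-9), 0, nx - 1);
    int ixhi = clampi((int)std::floor((cx + r - origin[0]) / spacing + 1e-9), 0, nx - 1);
    int iylo = clampi((int)std::ceil ((cy - r - origin[1]) / spacing - 1e-9), 0, ny - 1);
    int iyhi = clampi((int)std::floor((cy + r - origin[1]) / spacing + 1e-9), 0, ny - 1);
    int izlo = clampi((int)std::ceil ((cz - r - origin[2]) / spacing - 1e-9), 0, nz - 1);
    int izhi = clampi((int)std::floor((cz + r - origin[2]) / spacing + 1e-9), 0, nz - 1);
    for (int iz = izlo; iz <= izhi; ++iz) {
      const double dz = origin[2] + spacing * iz - cz;
      for (int iy = iylo; iy <= iyhi; ++iy) {
        const double dy = origin[1] + spacing * iy - cy;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        const size_t base = (size_t)nx * (iy + (size_t)ny * iz);
        for (int ix = ixlo; ix <= ixhi; ++ix) {
          const double dx = origin[0] + spacing * ix - cx;
          if (dx * dx + dyz2 <= r2) inside[base + ix] = 1;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_shape_field(NumericMatrix coords, NumericVector radii,
                              NumericVector origin, double spacing,
                              IntegerVector dims) {
  std::vector<char> inside;
  occupancy_mask(coords, radii, origin, spacing, dims, inside);
  NumericVector out(inside.size());
  for (size_t i = 0; i < inside.size(); ++i) out[i] = inside[i] ? 1.0 : 0.0;
  return out;
}

// Coulomb energy of a unit positive probe in a distance-dependent
// dielectric (eps = 4r): E = sum_i K q_i / (4 d_i^2). Points inside the
// molecule's own vdW surface are zeroed; clamp = NA disables truncation.
// [[Rcpp::export]]
NumericVector cpp_elec_field(NumericMatrix coords, NumericVector charges,
                             NumericVector radii, NumericVector origin,
                             double spacing, IntegerVector dims,
                             double coulomb_k, double clamp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = coords.nrow();
  std::vector<char> inside;
  occupancy_mask(coords, radii, origin, spacing, dims, inside);
  NumericVector out((size_t)nx * ny * nz);
  const bool do_clamp = !NumericVector::is_na(clamp);
  size_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double pz = origin[2] + spacing * iz;
    for (int iy = 0; iy < ny; ++iy) {
      const double py = origin[1] + spacing * iy;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        if (inside[idx]) { out[idx] = 0.0; continue; }
        const double px = origin[0] + spacing * ix;
        double e = 0.0;
        for (int a = 0; a < natom; ++a) {
          const double dx = px - coords(a, 0);
          const double dy = py - coords(a, 1);
          const double dz = pz - coords(a, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          e += coulomb_k * charges[a] / (4.0 * d2);
        }
        if (do_clamp) {
          if (e > clamp) e = clamp; else if (e < -clamp) e = -clamp;
        }
        out[idx] = e;
      }
    }
  }
  return out;
}
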
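#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Uniform grid over atom centers for nearest-surface queries. Clearance of a
// point is min over atoms of (distance - vdW radius); the ring search stops
// once no unvisited cell can beat the current best by more than the largest
// radius present.
namespace {

struct AtomGrid {
  double x0, y0, z0, cell;
  int nx, ny, nz;
  double rmax;
  const double *ax, *ay, *az, *rad;
  int n;
  std::vector<std::vector<int> > cells;

  AtomGrid(const NumericMatrix &atoms, const NumericVector &radii, double cell_size)
      : cell(cell_size) {
    n = atoms.nrow();
    ax = &atoms(0, 0);
    ay = &atoms(0, 1);
    az = &atoms(0, 2);
    rad = &radii[0];
    double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf, zmax = R_NegInf;
    rmax = 0.0;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, ax[i]); xmax = std::max(xmax, ax[i]);
      ymin = std::min(ymin, ay[i]); ymax = std::max(ymax, ay[i]);
      zmin = std::min(zmin, az[i]); zmax = std::max(zmax, az[i]);
      rmax = std::max(rmax, rad[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    nz = std::max(1, (int)std::floor((zmax - z0) / cell) + 1);
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((ax[i] - x0) / cell);
      int cy = (int)std::floor((ay[i] - y0) / cell);
      int cz = (int)std::floor((az[i] - z0) / cell);
      cx = std::min(std::max(cx, 0), nx - 1);
      cy = std::min(std::max(cy, 0), ny - 1);
      cz = std::min(std::max(cz, 0), nz - 1);
      cells[(size_t)(cx * ny + cy) * nz + cz].push_back(i);
    }
  }

  inline void scan_cell(int cx, int cy, int cz, double px, double py, double pz,
                        double &best) const {
    if (cx < 0 || cy < 0 || cz < 0 || cx >= nx || cy >= ny || cz >= nz) return;
    const std::vector<int> &v = cells[(size_t)(cx * ny + cy) * nz + cz];
    for (size_t k = 0; k < v.size(); ++k) {
      int i = v[k];
      double dx = px - ax[i], dy = py - ay[i], dz = pz - az[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[i];
      if (d < best) best = d;
    }
  }

  // scan only the shell at Chebyshev ring k around (cx,cy,cz), with loop
  // ranges clipped to the grid, so far-outside queries skip empty rings fast
  inline void scan_ring(int cx, int cy, int cz, int k, double px, double py,
                        double pz, double &best) const {
    if (k == 0) { scan_cell(cx, cy, cz, px, py, pz, best); return; }
    int xlo = std::max(cx - k, 0), xhi = std::min(cx + k, nx - 1);
    int ylo = std::max(cy - k, 0), yhi = std::min(cy + k, ny - 1);
    int zlo = std::max(cz - k, 0), zhi = std::min(cz + k, nz - 1);
    if (xlo > xhi || ylo > yhi || zlo > zhi) return;
    for (int s = -1; s <= 1; s += 2) { // x faces
      int ix = cx + s * k;
      if (ix < 0 || ix >= nx) continue;
      for (int iy = ylo; iy <= yhi; ++iy)
        for (int iz = zlo; iz <= zhi; ++iz)
          scan_cell(ix, iy, iz, px, py, pz, best);
    }
    int xin_lo = std::max(cx - k + 1, 0), xin_hi = std::min(cx + k - 1, nx - 1);
    for (int s = -1; s <= 1; s += 2) { // y faces
      int iy = cy + s * k;
      if (iy < 0 || iy >= ny) continue;
      for (int ix = xin_lo; ix <= xin_hi; ++ix)
        for (int iz = zlo; iz <= zhi; ++iz)
          scan_cell(ix, iy, iz, px, py, pz, best);
    }
    int yin_lo = std::max(cy - k + 1, 0), yin_hi = std::min(cy + k - 1, ny - 1);
    for (int s = -1; s <= 1; s += 2) { // z faces
      int iz = cz + s * k;
      if (iz < 0 || iz >= nz) continue;
      for (int ix = xin_lo; ix <= xin_hi; ++ix)
        for (int iy = yin_lo; iy <= yin_hi; ++iy)
          scan_cell(ix, iy, iz, px, py, pz, best);
    }
  }

  double clearance(double px, double py, double pz) const {
    int cx = (int)std::floor((px - x0) / cell);
    int cy = (int)std::floor((py - y0) / cell);
    int cz = (int)std::floor((pz - z0) / cell);
    int kmax = 0;
    kmax = std::max(kmax, std::max(std::abs(cx - 0), std::abs(cx - (nx - 1))));
    kmax = std::max(kmax, std::max(std::abs(cy - 0), std::abs(cy - (ny - 1))));
    kmax = std::max(kmax, std::max(std::abs(cz - 0), std::abs(cz - (nz - 1))));
    double best = std::numeric_limits<double>::infinity();
    // fast-forward over rings that cannot intersect the grid (queries far
    // outside the atom bounding box)
    int k0 = 0;
    if (cx < 0) k0 = std::max(k0, -cx);
    if (cx >= nx) k0 = std::max(k0, cx - (nx - 1));
    if (cy < 0) k0 = std::max(k0, -cy);
    if (cy >= ny) k0 = std::max(k0, cy - (ny - 1));
    if (cz < 0) k0 = std::max(k0, -cz);
    if (cz >= nz) k0 = std::max(k0, cz - (nz - 1));
    for (int k = k0; k <= kmax; ++k) {
      // any atom in a ring-k cell is at distance >= (k-1)*cell
      if (k > 1 && (double)(k - 1) * cell - rmax > best) break;
      scan_ring(cx, cy, cz, k, px, py, pz, best);
    }
    return best;
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_point_clearance(NumericMatrix points, NumericMatrix atoms,
                                  NumericVector radii) {
  if (atoms.nrow() == 0) stop("empty structure");
  AtomGrid g(atoms, radii, 3.0);
  int np = points.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = g.clearance(points(i, 0), points(i, 1), points(i, 2));
  return out;
}

// Minimum clearance along each segment, sampled every `step` angstroms with
// both endpoints included.
// [[Rcpp::export]]
NumericVector cpp_segment_clearance(NumericMatrix p0, NumericMatrix p1,
                                    double step, NumericMatrix atoms,
                                    NumericVector radii) {
  if (atoms.nrow() == 0) stop("empty structure");
  AtomGrid g(atoms, radii, 3.0);
  int ns = p0.nrow();
  NumericVector out(ns);
  for (int i = 0; i < ns; ++i) {
    double dx = p1(i, 0) - p0(i, 0);
    double dy = p1(i, 1) - p0(i, 1);
    double dz = p1(i, 2) - p0(i, 2);
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    // clamp: degenerate sliver circumcenters can produce absurdly long
    // edges; sampling density only matters for traversable (short) edges
    int m = std::max(1, (int)std::ceil(len / step));
    if (m > 80) m = 80;
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j <= m; ++j) {
      double t = (double)j / (double)m;
      double c = g.clearance(p0(i, 0) + t * dx, p0(i, 1) + t * dy,
                             p0(i, 2) + t * dz);
      if (c < best) best = c;
    }
    out[i] = best;
  }
  return out;
}

// Shrake-Rupley solvent-accessible surface area per atom, deterministic
// golden-spiral sphere points.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix atoms, NumericVector radii, double probe,
                       int n_points) {
  int n = atoms.nrow();
  if (n == 0) stop("empty structure");
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double y = 1.0 - 2.0 * ((double)i + 0.5) / (double)n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - y * y));
    double th = golden * (double)i;
    sx[i] = r * std::cos(th);
    sy[i] = y;
    sz[i] = r * std::sin(th);
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  AtomGrid g(atoms, radii, 3.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    double reach = Ri + rmax + probe; // neighbour can occlude only within this
    // collect neighbour candidates by ring scan
    std::vector<int> nb;
    int cx = (int)std::floor((atoms(i, 0) - g.x0) / g.cell);
    int cy = (int)std::floor((atoms(i, 1) - g.y0) / g.cell);
    int cz = (int)std::floor((atoms(i, 2) - g.z0) / g.cell);
    int kr = (int)std::ceil(reach / g.cell) + 1;
    for (int ix = cx - kr; ix <= cx + kr; ++ix)
      for (int iy = cy - kr; iy <= cy + kr; ++iy)
        for (int iz = cz - kr; iz <= cz + kr; ++iz) {
          if (ix < 0 || iy < 0 || iz < 0 || ix >= g.nx || iy >= g.ny || iz >= g.nz)
            continue;
          const std::vector<int> &v = g.cells[(size_t)(ix * g.ny + iy) * g.nz + iz];
          for (size_t k = 0; k < v.size(); ++k) {
            int j = v[k];
            if (j == i) continue;
            double dx = atoms(i, 0) - atoms(j, 0);
            double dy = atoms(i, 1) - atoms(j, 1);
            double dz = atoms(i, 2) - atoms(j, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            double lim = Ri + radii[j] + probe;
            if (d2 < lim * lim) nb.push_back(j);
          }
        }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = atoms(i, 0) + Ri * sx[p];
      double py = atoms(i, 1) + Ri * sy[p];
      double pz = atoms(i, 2) + Ri * sz[p];
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double dx = px - atoms(j, 0);
        double dy = py - atoms(j, 1);
        double dz = pz - atoms(j, 2);
        double Rj = radii[j] + probe;
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return out;
}
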
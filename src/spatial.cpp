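#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Cell-grid spatial index. Lateral cell size = r; axial cell size = rz.
// 3D distances use the ellipsoidal scaled norm sqrt(dx^2 + dy^2 + (dz*r/rz)^2),
// so a "radius r" neighbourhood is an ellipsoid with axial semi-axis rz.

namespace {

struct Grid {
  double cell, cellz, x0, y0, z0;
  bool has_z;
  std::unordered_map<long long, std::vector<int>> cells;

  static long long key(int ix, int iy, int iz) {
    return (static_cast<long long>(ix) << 42) ^
           (static_cast<long long>(iy) << 21) ^ static_cast<long long>(iz);
  }

  Grid(const NumericVector& x, const NumericVector& y,
       const NumericVector& z, bool use_z, double cs, double csz)
      : cell(cs), cellz(csz), has_z(use_z) {
    x0 = *std::min_element(x.begin(), x.end());
    y0 = *std::min_element(y.begin(), y.end());
    z0 = use_z ? *std::min_element(z.begin(), z.end()) : 0.0;
    int n = x.size();
    cells.reserve(n * 2);
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((x[i] - x0) / cell));
      int iy = static_cast<int>(std::floor((y[i] - y0) / cell));
      int iz = has_z ? static_cast<int>(std::floor((z[i] - z0) / cellz)) : 0;
      cells[key(ix, iy, iz)].push_back(i);
    }
  }

  void cell_of(double xi, double yi, double zi, int& ix, int& iy, int& iz) const {
    ix = static_cast<int>(std::floor((xi - x0) / cell));
    iy = static_cast<int>(std::floor((yi - y0) / cell));
    iz = has_z ? static_cast<int>(std::floor((zi - z0) / cellz)) : 0;
  }

  const std::vector<int>* at(int ix, int iy, int iz) const {
    auto it = cells.find(key(ix, iy, iz));
    return it == cells.end() ? nullptr : &it->second;
  }
};

inline double sq(double v) { return v * v; }

// scaled squared distance (z term scaled by r/rz so threshold is r^2)
inline double sdist2(const NumericVector& x, const NumericVector& y,
                     const NumericVector& z, bool has_z, double zscale,
                     int i, int j) {
  double d = sq(x[i] - x[j]) + sq(y[i] - y[j]);
  if (has_z) d += sq((z[i] - z[j]) * zscale);
  return d;
}

// collect indices of all points within scaled radius r of point i (excluding i)
void neighbours_of(const Grid& g, const NumericVector& x, const NumericVector& y,
                   const NumericVector& z, bool has_z, double r, double rz,
                   int i, std::vector<int>& out) {
  out.clear();
  double zscale = has_z ? r / rz : 1.0;
  double r2 = r * r;
  int ix, iy, iz;
  g.cell_of(x[i], y[i], has_z ? z[i] : 0.0, ix, iy, iz);
  int zspan = has_z ? 1 : 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -zspan; dz <= zspan; ++dz) {
        const std::vector<int>* c = g.at(ix + dx, iy + dy, iz + dz);
        if (!c) continue;
        for (int j : *c) {
          if (j == i) continue;
          if (sdist2(x, y, z, has_z, zscale, i, j) <= r2) out.push_back(j);
        }
      }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_neighbor_counts(NumericVector x, NumericVector y,
                                  NumericVector z, bool has_z,
                                  double r, double rz) {
  int n = x.size();
  Grid g(x, y, z, has_z, r, has_z ? rz : r);
  IntegerVector counts(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    neighbours_of(g, x, y, z, has_z, r, rz, i, nb);
    counts[i] = static_cast<int>(nb.size());
  }
  return counts;
}

// A point is a local maximum iff every neighbour within r has a strictly
// smaller count, or an equal count and a larger index (lowest-index tie-break).
// Returns 1-based indices, ascending.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector x, NumericVector y,
                               NumericVector z, bool has_z,
                               double r, double rz, IntegerVector counts) {
  int n = x.size();
  Grid g(x, y, z, has_z, r, has_z ? rz : r);
  std::vector<int> maxima, nb;
  for (int i = 0; i < n; ++i) {
    neighbours_of(g, x, y, z, has_z, r, rz, i, nb);
    bool is_max = true;
    for (int j : nb) {
      if (counts[j] > counts[i] || (counts[j] == counts[i] && j < i)) {
        is_max = false;
        break;
      }
    }
    if (is_max) maxima.push_back(i + 1);
  }
  return wrap(maxima);
}

// Assign localizations to maxima processed in decreasing neighbour-count
// order (ties by ascending index): each unassigned point within r of the
// maximum joins its cluster. Returns 0 for unassigned, else cluster id
// numbered by processing order (1, 2, ...).
// [[Rcpp::export]]
IntegerVector cpp_assign_clusters(NumericVector x, NumericVector y,
                                  NumericVector z, bool has_z,
                                  double r, double rz,
                                  IntegerVector counts, IntegerVector maxima) {
  int n = x.size();
  Grid g(x, y, z, has_z, r, has_z ? rz : r);
  std::vector<int> order(maxima.begin(), maxima.end());
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return counts[a - 1] > counts[b - 1] || (counts[a - 1] == counts[b - 1] && a < b);
  });
  IntegerVector assign(n, 0);
  std::vector<int> nb;
  int id = 0;
  for (int m1 : order) {
    int m = m1 - 1;
    if (assign[m] != 0) continue;  // maximum swallowed by a denser cluster
    ++id;
    assign[m] = id;
    neighbours_of(g, x, y, z, has_z, r, rz, m, nb);
    for (int j : nb)
      if (assign[j] == 0) assign[j] = id;
  }
  return assign;
}

namespace {

// dense cell grid (CSR layout) for fast 2D k-NN queries
struct DenseGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<int> start, idx;

  DenseGrid(const NumericVector& x, const NumericVector& y, double cs)
      : cell(cs) {
    int n = x.size();
    x0 = *std::min_element(x.begin(), x.end());
    y0 = *std::min_element(y.begin(), y.end());
    double xmax = *std::max_element(x.begin(), x.end());
    double ymax = *std::max_element(y.begin(), y.end());
    // cap the grid at ~sqrt(n) cells per axis: degenerate extents (e.g.
    // collinear points) would otherwise explode the cell count and make
    // the ring search quadratic
    double max_dim = std::ceil(std::sqrt(static_cast<double>(n))) + 1.0;
    double min_cell = std::max((xmax - x0) / max_dim, (ymax - y0) / max_dim);
    if (cell < min_cell) cell = min_cell;
    if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
    nx = static_cast<int>(std::floor((xmax - x0) / cell)) + 1;
    ny = static_cast<int>(std::floor((ymax - y0) / cell)) + 1;
    std::vector<int> cix(n);
    start.assign(static_cast<size_t>(nx) * ny + 1, 0);
    for (int i = 0; i < n; ++i) {
      int ix = static_cast<int>(std::floor((x[i] - x0) / cell));
      int iy = static_cast<int>(std::floor((y[i] - y0) / cell));
      cix[i] = ix * ny + iy;
      ++start[cix[i] + 1];
    }
    for (size_t c = 1; c < start.size(); ++c) start[c] += start[c - 1];
    idx.resize(n);
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) idx[cur[cix[i]]++] = i;
  }
};

void knn_query(const DenseGrid& g, const NumericVector& x,
               const NumericVector& y, int i, int k, int max_ring,
               std::vector<double>& best, double dmax2 = 0.0) {
  best.clear();  // max-heap of squared distances, size <= k
  int ix = static_cast<int>(std::floor((x[i] - g.x0) / g.cell));
  int iy = static_cast<int>(std::floor((y[i] - g.y0) / g.cell));
  for (int ring = 0; ring <= max_ring; ++ring) {
    // capped search: distances beyond sqrt(dmax2) may be reported inexactly
    if (dmax2 > 0 && ring > 1 && sq((ring - 1) * g.cell) > dmax2) break;
    int xlo = std::max(ix - ring, 0), xhi = std::min(ix + ring, g.nx - 1);
    int ylo = std::max(iy - ring, 0), yhi = std::min(iy + ring, g.ny - 1);
    for (int cx = xlo; cx <= xhi; ++cx) {
      bool edge_col = (cx == ix - ring || cx == ix + ring);
      for (int cy = ylo; cy <= yhi; ++cy) {
        if (!edge_col && cy != iy - ring && cy != iy + ring) continue;
        int c = cx * g.ny + cy;
        for (int p = g.start[c]; p < g.start[c + 1]; ++p) {
          int j = g.idx[p];
          if (j == i) continue;
          double d2 = sq(x[i] - x[j]) + sq(y[i] - y[j]);
          if (static_cast<int>(best.size()) < k) {
            best.push_back(d2);
            std::push_heap(best.begin(), best.end());
          } else if (d2 < best.front()) {
            std::pop_heap(best.begin(), best.end());
            best.back() = d2;
            std::push_heap(best.begin(), best.end());
          }
        }
      }
    }
    // cells beyond this ring are at least ring*cell from the query point
    if (static_cast<int>(best.size()) == k && best.front() <= sq(ring * g.cell))
      break;
  }
  std::sort_heap(best.begin(), best.end());
  // pad with sentinel beyond-cap distances if the capped search found < k
  while (static_cast<int>(best.size()) < k)
    best.push_back(dmax2 > 0 ? 4.0 * dmax2 : R_PosInf);
}

}  // namespace

// k nearest-neighbour Euclidean distances (2D), exact, via ring expansion on
// a dense cell grid. Returns an n x k matrix, column j = distance to j-th NN.
// [[Rcpp::export]]
NumericMatrix cpp_knn(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (n <= k) stop("need more than k points");
  double xspan = *std::max_element(x.begin(), x.end()) -
                 *std::min_element(x.begin(), x.end());
  double yspan = *std::max_element(y.begin(), y.end()) -
                 *std::min_element(y.begin(), y.end());
  double area = std::max(xspan * yspan, 1e-12);
  double cell = std::sqrt(area * (k + 1) / n);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  DenseGrid g(x, y, cell);
  int max_ring = std::max(g.nx, g.ny);

  NumericMatrix out(n, k);
  std::vector<double> best;
  for (int i = 0; i < n; ++i) {
    knn_query(g, x, y, i, k, max_ring, best);
    for (int j = 0; j < k; ++j) out(i, j) = std::sqrt(best[j]);
  }
  return out;
}

// as cpp_knn, but distances are reported only for points inside the closed
// rectangle [rx0, rx1] x [ry0, ry1]; all points act as candidate neighbours.
// Rows keep the original relative order of the inside points. With dmax > 0
// the search stops at distance dmax and unfound neighbours are reported as
// 2*dmax (callers binning distances below dmax are unaffected).
// [[Rcpp::export]]
NumericMatrix cpp_knn_rect(NumericVector x, NumericVector y, int k,
                           double rx0, double ry0, double rx1, double ry1,
                           double dmax = 0.0) {
  int n = x.size();
  if (n <= k) stop("need more than k points");
  std::vector<int> inside;
  inside.reserve(n);
  for (int i = 0; i < n; ++i)
    if (x[i] >= rx0 && x[i] <= rx1 && y[i] >= ry0 && y[i] <= ry1)
      inside.push_back(i);
  double xspan = *std::max_element(x.begin(), x.end()) -
                 *std::min_element(x.begin(), x.end());
  double yspan = *std::max_element(y.begin(), y.end()) -
                 *std::min_element(y.begin(), y.end());
  double area = std::max(xspan * yspan, 1e-12);
  double cell = std::sqrt(area * (k + 1) / n);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  DenseGrid g(x, y, cell);
  int max_ring = std::max(g.nx, g.ny);

  NumericMatrix out(inside.size(), k);
  std::vector<double> best;
  double dmax2 = dmax > 0 ? dmax * dmax : 0.0;
  for (size_t q = 0; q < inside.size(); ++q) {
    knn_query(g, x, y, inside[q], k, max_ring, best, dmax2);
    for (int j = 0; j < k; ++j) out(q, j) = std::sqrt(best[j]);
  }
  return out;
}

namespace {

// Monomer/dimer mixture generator core (positions in nm), sharing R's RNG
// stream. Monomer count ~ Poisson(lam_mono), dimer-pair count ~
// Poisson(lam_dim), centres/monomers uniform on [lo, hi]^2, pair members at
// +/- D/2 along a uniform random orientation, every molecule perturbed by
// N(0, sigma^2) per axis, then thinned with probability eff (monomers are
// thinned before the perturbation draw, which is distributionally
// equivalent and skips discarded work).
void gen_mixture(double lam_mono, double lam_dim, double lo, double hi,
                 double D, double sigma, double eff,
                 std::vector<double>& kx, std::vector<double>& ky) {
  int n_mono = static_cast<int>(R::rpois(lam_mono));
  int n_dim = static_cast<int>(R::rpois(lam_dim));
  int n_mono_kept = eff >= 1.0 ? n_mono
                               : static_cast<int>(R::rbinom(n_mono, eff));
  double span = hi - lo;
  kx.clear();
  ky.clear();
  kx.reserve(n_mono_kept + 2 * n_dim);
  ky.reserve(n_mono_kept + 2 * n_dim);
  for (int i = 0; i < n_mono_kept; ++i) {
    double xi = lo + span * unif_rand(), yi = lo + span * unif_rand();
    if (sigma > 0) {
      xi += sigma * norm_rand();
      yi += sigma * norm_rand();
    }
    kx.push_back(xi);
    ky.push_back(yi);
  }
  for (int i = 0; i < n_dim; ++i) {
    double cx = lo + span * unif_rand(), cy = lo + span * unif_rand();
    double th = 2.0 * M_PI * unif_rand();
    double ox = 0.5 * D * std::cos(th), oy = 0.5 * D * std::sin(th);
    for (int s = -1; s <= 1; s += 2) {
      if (eff < 1.0 && unif_rand() >= eff) continue;
      double xi = cx + s * ox, yi = cy + s * oy;
      if (sigma > 0) {
        xi += sigma * norm_rand();
        yi += sigma * norm_rand();
      }
      kx.push_back(xi);
      ky.push_back(yi);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sim_mixture(double lam_mono, double lam_dim, double lo,
                              double hi, double D, double sigma, double eff) {
  std::vector<double> kx, ky;
  gen_mixture(lam_mono, lam_dim, lo, hi, D, sigma, eff, kx, ky);
  NumericMatrix out(kx.size(), 2);
  for (size_t i = 0; i < kx.size(); ++i) {
    out(i, 0) = kx[i];
    out(i, 1) = ky[i];
  }
  return out;
}

// Fused objective path: simulate a mixture, compute first-NND (capped at
// the last bin edge) for points inside [0, side]^2 with the full pattern as
// candidate neighbours, and return the probability histogram on `edges`
// (mass normalized by the number of inside points). One R call per
// least-squares evaluation.
// [[Rcpp::export]]
NumericVector cpp_mixture_nnd_hist(double lam_mono, double lam_dim,
                                   double lo, double hi, double D,
                                   double sigma, double eff, double side,
                                   NumericVector edges) {
  std::vector<double> kx, ky;
  gen_mixture(lam_mono, lam_dim, lo, hi, D, sigma, eff, kx, ky);
  int nb = edges.size() - 1;
  NumericVector hist(nb);
  int n = kx.size();
  if (n < 2) return hist;
  double dmax = edges[edges.size() - 1];
  double dmax2 = dmax * dmax;

  // dense grid sized to the expected first-NND scale
  double cell = (hi - lo) * std::sqrt(2.0 / n);
  if (!(cell > 0) || !std::isfinite(cell)) cell = 1.0;
  int nxc = static_cast<int>(std::floor((hi - lo) / cell)) + 1;
  std::vector<int> start(static_cast<size_t>(nxc) * nxc + 1, 0), cix(n);
  for (int i = 0; i < n; ++i) {
    int ix = static_cast<int>(std::floor((kx[i] - lo) / cell));
    int iy = static_cast<int>(std::floor((ky[i] - lo) / cell));
    ix = std::min(std::max(ix, 0), nxc - 1);
    iy = std::min(std::max(iy, 0), nxc - 1);
    cix[i] = ix * nxc + iy;
    ++start[cix[i] + 1];
  }
  for (size_t c = 1; c < start.size(); ++c) start[c] += start[c - 1];
  std::vector<int> idx(n), cur(start.begin(), start.end() - 1);
  for (int i = 0; i < n; ++i) idx[cur[cix[i]]++] = i;

  int n_inside = 0;
  for (int i = 0; i < n; ++i) {
    if (kx[i] < 0 || kx[i] > side || ky[i] < 0 || ky[i] > side) continue;
    ++n_inside;
    double best = R_PosInf;
    int ix = cix[i] / nxc, iy = cix[i] % nxc;
    for (int ring = 0; ; ++ring) {
      if (ring > 1 && sq((ring - 1) * cell) > std::min(best, dmax2)) break;
      int xlo = std::max(ix - ring, 0), xhi = std::min(ix + ring, nxc - 1);
      int ylo = std::max(iy - ring, 0), yhi = std::min(iy + ring, nxc - 1);
      if (ix - ring < 0 && ix + ring > nxc - 1 &&
          iy - ring < 0 && iy + ring > nxc - 1 && ring > nxc)
        break;  // whole grid scanned
      for (int cx = xlo; cx <= xhi; ++cx) {
        bool edge_col = (cx == ix - ring || cx == ix + ring);
        for (int cy = ylo; cy <= yhi; ++cy) {
          if (!edge_col && cy != iy - ring && cy != iy + ring) continue;
          int c = cx * nxc + cy;
          for (int p = start[c]; p < start[c + 1]; ++p) {
            int j = idx[p];
            if (j == i) continue;
            double d2 = sq(kx[i] - kx[j]) + sq(ky[i] - ky[j]);
            if (d2 < best) best = d2;
          }
        }
      }
    }
    if (best < dmax2) {
      double d = std::sqrt(best);
      // edges assumed sorted; linear scan is fine for ~100 bins
      int b = static_cast<int>(std::upper_bound(edges.begin(), edges.end(), d) -
                               edges.begin()) - 1;
      if (b >= 0 && b < nb) ++hist[b];
    }
  }
  if (n_inside > 0)
    for (int b = 0; b < nb; ++b) hist[b] /= n_inside;
  return hist;
}
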
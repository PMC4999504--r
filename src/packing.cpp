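// Hard-sphere rejection packing: greedy acceptance of candidate points that
// keep a minimum-image exclusion distance from fixed atoms and from each
// other. Cell-list accelerated; orthorhombic boxes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellGrid {
  int nx, ny, nz;
  double bx, by, bz;
  std::vector<std::vector<int>> cells;
  std::vector<double> px, py, pz;

  CellGrid(double bx_, double by_, double bz_, double excl)
      : bx(bx_), by(by_), bz(bz_) {
    nx = std::max(3, (int)std::floor(bx / excl));
    ny = std::max(3, (int)std::floor(by / excl));
    nz = std::max(3, (int)std::floor(bz / excl));
    cells.assign((size_t)nx * ny * nz, {});
  }

  static double wrap(double v, double b) {
    v -= b * std::floor(v / b);
    if (v >= b) v = 0.0;
    return v;
  }

  int cell_of(double x, double y, double z) const {
    int i = std::min(nx - 1, (int)(wrap(x, bx) / bx * nx));
    int j = std::min(ny - 1, (int)(wrap(y, by) / by * ny));
    int k = std::min(nz - 1, (int)(wrap(z, bz) / bz * nz));
    return i + nx * (j + ny * k);
  }

  void add(double x, double y, double z) {
    int idx = (int)px.size();
    px.push_back(x); py.push_back(y); pz.push_back(z);
    cells[cell_of(x, y, z)].push_back(idx);
  }

  static double mind(double d, double b) {
    d -= b * std::ceil(d / b - 0.5);
    return d;
  }

  bool clear(double x, double y, double z, double excl2) const {
    int ci = std::min(nx - 1, (int)(wrap(x, bx) / bx * nx));
    int cj = std::min(ny - 1, (int)(wrap(y, by) / by * ny));
    int ck = std::min(nz - 1, (int)(wrap(z, bz) / bz * nz));
    for (int di = -1; di <= 1; ++di) {
      int i = (ci + di + nx) % nx;
      for (int dj = -1; dj <= 1; ++dj) {
        int j = (cj + dj + ny) % ny;
        for (int dk = -1; dk <= 1; ++dk) {
          int k = (ck + dk + nz) % nz;
          for (int idx : cells[(size_t)i + nx * ((size_t)j + (size_t)ny * k)]) {
            double ddx = mind(x - px[idx], bx);
            double ddy = mind(y - py[idx], by);
            double ddz = mind(z - pz[idx], bz);
            if (ddx * ddx + ddy * ddy + ddz * ddz < excl2) return false;
          }
        }
      }
    }
    return true;
  }
};

}  // namespace

// Greedily accept candidates (rows of `cand`) that stay at least `excl`
// (minimum image) from every fixed point and every previously accepted
// candidate; stop after `n_needed` acceptances. Returns 1-based row indices
// of the accepted candidates, in acceptance order.
// [[Rcpp::export(name = ".accept_excluded")]]
IntegerVector accept_excluded(NumericMatrix cand, NumericMatrix fixed,
                              NumericVector box, double excl, int n_needed) {
  CellGrid grid(box[0], box[1], box[2], excl);
  for (int r = 0; r < fixed.nrow(); ++r) {
    grid.add(fixed(r, 0), fixed(r, 1), fixed(r, 2));
  }
  double excl2 = excl * excl;
  IntegerVector out;
  for (int r = 0; r < cand.nrow() && out.size() < n_needed; ++r) {
    double x = cand(r, 0), y = cand(r, 1), z = cand(r, 2);
    if (grid.clear(x, y, z, excl2)) {
      grid.add(x, y, z);
      out.push_back(r + 1);
    }
  }
  return out;
}
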
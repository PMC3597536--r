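// Center-based rigid-sphere mechanics: uniform-grid neighbour search,
// pairwise overlap projection, gravitational aggregation, and the
// overdamped spring step used by the growing-aggregate model.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  double h;
  double ox, oy, oz;
  std::unordered_map<long long, std::vector<int>> cells;

  static long long key(int ix, int iy, int iz) {
    // pack three 21-bit signed indices
    const long long B = 1 << 20;
    return (((long long)(ix + B)) << 42) | (((long long)(iy + B)) << 21) |
           ((long long)(iz + B));
  }

  void build(const NumericMatrix &pos, double cell_size) {
    h = cell_size;
    cells.clear();
    int n = pos.nrow();
    ox = oy = oz = 0.0;
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(pos(i, 0) / h);
      int iy = (int)std::floor(pos(i, 1) / h);
      int iz = (int)std::floor(pos(i, 2) / h);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }

  // visit all unordered candidate pairs (i < j) within one grid cell of
  // each other; fn returns nothing
  template <class F> void pairs(const NumericMatrix &pos, F fn) const {
    int n = pos.nrow();
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(pos(i, 0) / h);
      int iy = (int)std::floor(pos(i, 1) / h);
      int iz = (int)std::floor(pos(i, 2) / h);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
            if (it == cells.end()) continue;
            for (int j : it->second)
              if (j > i) fn(i, j);
          }
    }
  }
};

double dist3(const NumericMatrix &pos, int i, int j) {
  double dx = pos(i, 0) - pos(j, 0);
  double dy = pos(i, 1) - pos(j, 1);
  double dz = pos(i, 2) - pos(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

double grid_cell_size(const NumericVector &radii, double slack) {
  double rmax = 0.0;
  for (double r : radii) rmax = std::max(rmax, r);
  return 2.0 * rmax * (1.0 + slack) + 1e-9;
}

// one randomized sweep of symmetric pairwise overlap projection; returns
// the maximum overlap found ON ENTRY as a fraction of the smaller
// radius (a return value <= tol therefore certifies the pre-sweep
// configuration)
double overlap_sweep(NumericMatrix &pos, const NumericVector &radii,
                     bool randomize, double push_tol) {
  Grid g;
  g.build(pos, grid_cell_size(radii, 0.0));
  std::vector<std::pair<int, int>> prs;
  double worst = 0.0;
  g.pairs(pos, [&](int i, int j) {
    double d = dist3(pos, i, j);
    double ov = (radii[i] + radii[j] - d) / std::min(radii[i], radii[j]);
    if (ov > worst) worst = ov;
    if (ov > push_tol) prs.emplace_back(i, j);
  });
  if (randomize && prs.size() > 1) {
    // Fisher-Yates with R's RNG so sweeps are reproducible under set.seed
    for (int k = (int)prs.size() - 1; k > 0; --k) {
      int m = (int)std::floor(unif_rand() * (k + 1));
      if (m > k) m = k;
      std::swap(prs[k], prs[m]);
    }
  }
  for (auto &p : prs) {
    int i = p.first, j = p.second;
    double d = dist3(pos, i, j);
    double target = radii[i] + radii[j];
    if (d >= target) continue;
    double ux, uy, uz;
    if (d < 1e-12) { // coincident centers: random push direction
      double th = 2.0 * M_PI * unif_rand(), z = 2.0 * unif_rand() - 1.0;
      double s = std::sqrt(std::max(0.0, 1.0 - z * z));
      ux = s * std::cos(th); uy = s * std::sin(th); uz = z;
      d = 0.0;
    } else {
      ux = (pos(i, 0) - pos(j, 0)) / d;
      uy = (pos(i, 1) - pos(j, 1)) / d;
      uz = (pos(i, 2) - pos(j, 2)) / d;
    }
    double half = 0.5 * (target - d);
    pos(i, 0) += half * ux; pos(i, 1) += half * uy; pos(i, 2) += half * uz;
    pos(j, 0) -= half * ux; pos(j, 1) -= half * uy; pos(j, 2) -= half * uz;
  }
  return worst;
}

} // namespace

// [[Rcpp::export]]
List cpp_contact_pairs(NumericMatrix pos, NumericVector radii, double slack) {
  Grid g;
  g.build(pos, grid_cell_size(radii, slack));
  std::vector<int> ii, jj;
  std::vector<double> dd;
  g.pairs(pos, [&](int i, int j) {
    double d = dist3(pos, i, j);
    if (d <= (radii[i] + radii[j]) * (1.0 + slack)) {
      ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d);
    }
  });
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["length"] = wrap(dd));
}

// [[Rcpp::export]]
List cpp_resolve_overlaps(NumericMatrix pos, NumericVector radii,
                          double tol_frac, int max_sweeps) {
  NumericMatrix out = clone(pos);
  double worst = R_PosInf;
  int s = 0;
  for (; s < max_sweeps; ++s) {
    worst = overlap_sweep(out, radii, true, tol_frac);
    if (worst <= tol_frac) break;
  }
  return List::create(_["pos"] = out, _["sweeps"] = s + 1,
                      _["max_overlap"] = worst);
}

// Gravitational aggregation: every iteration each sphere advances
// step µm toward the attractor, then overlaps are projected out.  The
// step is halved whenever net displacement stalls, so the scheme settles
// into a jammed packing and terminates.
// [[Rcpp::export]]
List cpp_aggregate(NumericMatrix pos0, NumericVector radii,
                   NumericVector attractor, double step0,
                   double conv_disp, int max_iter, double tol_frac,
                   int settle_sweeps) {
  NumericMatrix pos = clone(pos0);
  int n = pos.nrow();
  double step = step0;
  double max_disp = R_PosInf;
  double window_best = R_PosInf, prev_window_best = R_PosInf;
  bool converged = false;
  int it = 0;
  std::vector<double> oldx(n), oldy(n), oldz(n);
  for (it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      oldx[i] = pos(i, 0); oldy[i] = pos(i, 1); oldz[i] = pos(i, 2);
      double dx = attractor[0] - pos(i, 0);
      double dy = attractor[1] - pos(i, 1);
      double dz = attractor[2] - pos(i, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double adv = std::min(step, d);
      if (d > 1e-12) {
        pos(i, 0) += adv * dx / d;
        pos(i, 1) += adv * dy / d;
        pos(i, 2) += adv * dz / d;
      }
    }
    for (int s = 0; s < 30; ++s)
      if (overlap_sweep(pos, radii, true, tol_frac) <= tol_frac) break;
    max_disp = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = pos(i, 0) - oldx[i], dy = pos(i, 1) - oldy[i],
             dz = pos(i, 2) - oldz[i];
      max_disp = std::max(max_disp, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    if (max_disp < conv_disp) { converged = true; ++it; break; }
    window_best = std::min(window_best, max_disp);
    if ((it + 1) % 25 == 0) {
      if (window_best >= 0.9 * prev_window_best) step *= 0.5;
      prev_window_best = window_best;
      window_best = R_PosInf;
      if (step < conv_disp) { converged = true; ++it; break; }
    }
  }
  // final settle so the overlap invariant holds even on early exit
  double worst = R_PosInf;
  for (int s = 0; s < settle_sweeps; ++s) {
    worst = overlap_sweep(pos, radii, true, tol_frac);
    if (worst <= tol_frac) break;
  }
  return List::create(_["pos"] = pos, _["iterations"] = it,
                      _["converged"] = converged, _["max_disp"] = max_disp,
                      _["max_overlap"] = worst);
}

// One overdamped mass-spring step: linear springs on all current contact
// edges (rest length = rest_factor * sum of radii), then hard-sphere
// overlap projection to the tolerance.
// [[Rcpp::export]]
List cpp_spring_step(NumericMatrix pos0, NumericVector radii, double slack,
                     double stiffness, double rest_factor, double dt,
                     double tol_frac, int max_sweeps) {
  NumericMatrix pos = clone(pos0);
  int n = pos.nrow();
  Grid g;
  g.build(pos, grid_cell_size(radii, slack));
  NumericMatrix disp(n, 3);
  g.pairs(pos, [&](int i, int j) {
    double d = dist3(pos, i, j);
    double touch = (radii[i] + radii[j]) * (1.0 + slack);
    if (d > touch || d < 1e-12) return;
    double L0 = rest_factor * (radii[i] + radii[j]);
    double f = dt * stiffness * (L0 - d); // >0 pushes apart
    double ux = (pos(i, 0) - pos(j, 0)) / d;
    double uy = (pos(i, 1) - pos(j, 1)) / d;
    double uz = (pos(i, 2) - pos(j, 2)) / d;
    disp(i, 0) += f * ux; disp(i, 1) += f * uy; disp(i, 2) += f * uz;
    disp(j, 0) -= f * ux; disp(j, 1) -= f * uy; disp(j, 2) -= f * uz;
  });
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) += disp(i, k);
  double worst = R_PosInf;
  int s = 0;
  for (; s < max_sweeps; ++s) {
    worst = overlap_sweep(pos, radii, true, tol_frac);
    if (worst <= tol_frac) break;
  }
  return List::create(_["pos"] = pos, _["max_overlap"] = worst);
}
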
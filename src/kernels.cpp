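// Geometry kernels: neighbour search, clearance lattice, widest-bottleneck path.
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <limits>
#include <queue>
#include <set>
#include <vector>
using namespace Rcpp;

static inline double mi(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// Unique inter-chain residue pairs with any bead-bead distance < cutoff (strict).
// xyz: bead coordinates; resid: 1-based global residue id per bead; chain:
// integer chain index per bead; box: length-3 edge lengths for minimum-image
// (periodic) distances, or length-0 for open boundaries.
// Cell-list search; results equal the all-pairs definition exactly.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix xyz, IntegerVector resid,
                                IntegerVector chain, double cutoff,
                                NumericVector box) {
  const int n = xyz.nrow();
  const bool periodic = box.size() == 3;
  std::set<std::pair<int, int> > out;
  if (n == 0 || cutoff <= 0) return IntegerMatrix(0, 2);

  std::vector<double> x(n), y(n), z(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i) {
    double p[3] = {xyz(i, 0), xyz(i, 1), xyz(i, 2)};
    if (periodic)
      for (int d = 0; d < 3; ++d) p[d] -= box[d] * std::floor(p[d] / box[d]);
    x[i] = p[0]; y[i] = p[1]; z[i] = p[2];
    for (int d = 0; d < 3; ++d) lo[d] = std::min(lo[d], p[d]);
  }
  int nc[3];
  double cs[3];
  for (int d = 0; d < 3; ++d) {
    if (periodic) {
      nc[d] = std::max(1, (int)std::floor(box[d] / cutoff));
      cs[d] = box[d] / nc[d];
      lo[d] = 0.0;
    } else {
      nc[d] = 1; // filled below from ranges
    }
  }
  if (!periodic) {
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i) {
      hi[0] = std::max(hi[0], x[i]); hi[1] = std::max(hi[1], y[i]);
      hi[2] = std::max(hi[2], z[i]);
    }
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cutoff) + 1);
      cs[d] = cutoff;
    }
  }
  const size_t ncell = (size_t)nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > cells(ncell);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    int a = std::min(nc[0] - 1, std::max(0, (int)std::floor((x[i] - lo[0]) / cs[0])));
    int b = std::min(nc[1] - 1, std::max(0, (int)std::floor((y[i] - lo[1]) / cs[1])));
    int c = std::min(nc[2] - 1, std::max(0, (int)std::floor((z[i] - lo[2]) / cs[2])));
    ci[i] = a; cj[i] = b; ck[i] = c;
    cells[a + (size_t)nc[0] * (b + (size_t)nc[1] * c)].push_back(i);
  }
  const double bx = periodic ? box[0] : 0.0, by = periodic ? box[1] : 0.0,
               bz = periodic ? box[2] : 0.0;
  const double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    std::set<size_t> nb;
    for (int da = -1; da <= 1; ++da)
      for (int db = -1; db <= 1; ++db)
        for (int dc = -1; dc <= 1; ++dc) {
          int a = ci[i] + da, b = cj[i] + db, c = ck[i] + dc;
          if (periodic) {
            a = (a % nc[0] + nc[0]) % nc[0];
            b = (b % nc[1] + nc[1]) % nc[1];
            c = (c % nc[2] + nc[2]) % nc[2];
          } else if (a < 0 || a >= nc[0] || b < 0 || b >= nc[1] || c < 0 ||
                     c >= nc[2])
            continue;
          nb.insert(a + (size_t)nc[0] * (b + (size_t)nc[1] * c));
        }
    for (size_t cell : nb)
      for (int j : cells[cell]) {
        if (j <= i || chain[j] == chain[i]) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        if (periodic) { dx = mi(dx, bx); dy = mi(dy, by); dz = mi(dz, bz); }
        if (dx * dx + dy * dy + dz * dz < cut2) {
          int r1 = resid[i], r2 = resid[j];
          out.insert(std::make_pair(std::min(r1, r2), std::max(r1, r2)));
        }
      }
  }
  IntegerMatrix res(out.size(), 2);
  int k = 0;
  for (std::set<std::pair<int, int> >::iterator it = out.begin();
       it != out.end(); ++it, ++k) {
    res(k, 0) = it->first;
    res(k, 1) = it->second;
  }
  return res;
}

// Exact nearest-bead distance field on a cubic lattice (expanding cell rings,
// equal to the brute-force all-beads scan).  radii: per-bead radii to subtract
// (length 0 => point mode).  cap: value used when no bead bounds the node.
// [[Rcpp::export]]
NumericVector cpp_clearance(NumericMatrix beads, NumericVector radii,
                            NumericVector origin, double spacing,
                            IntegerVector dims, double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int m = beads.nrow();
  if (m == 0) {
    std::fill(out.begin(), out.end(), cap);
    return out;
  }
  const bool subr = radii.size() == m;
  double rmax = 0.0;
  if (subr) rmax = *std::max_element(radii.begin(), radii.end());
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < m; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], beads(i, d));
      hi[d] = std::max(hi[d], beads(i, d));
    }
  const double cs = std::max(2.0 * spacing, 4.0);
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cs) + 1);
  std::vector<std::vector<int> > cells((size_t)nc[0] * nc[1] * nc[2]);
  for (int i = 0; i < m; ++i) {
    int a = std::min(nc[0] - 1, std::max(0, (int)std::floor((beads(i, 0) - lo[0]) / cs)));
    int b = std::min(nc[1] - 1, std::max(0, (int)std::floor((beads(i, 1) - lo[1]) / cs)));
    int c = std::min(nc[2] - 1, std::max(0, (int)std::floor((beads(i, 2) - lo[2]) / cs)));
    cells[a + (size_t)nc[0] * (b + (size_t)nc[1] * c)].push_back(i);
  }
  for (R_xlen_t g = 0; g < n; ++g) {
    const int gx = g % nx, gy = (int)((g / nx) % ny), gz = (int)(g / ((R_xlen_t)nx * ny));
    const double px = origin[0] + gx * spacing, py = origin[1] + gy * spacing,
                 pz = origin[2] + gz * spacing;
    const int cx = (int)std::floor((px - lo[0]) / cs),
              cy = (int)std::floor((py - lo[1]) / cs),
              cz = (int)std::floor((pz - lo[2]) / cs);
    const int kmax =
        std::max(std::max(std::abs(cx), std::abs(nc[0] - 1 - cx)),
                 std::max(std::max(std::abs(cy), std::abs(nc[1] - 1 - cy)),
                          std::max(std::abs(cz), std::abs(nc[2] - 1 - cz))));
    double best = R_PosInf;
    for (int k = 0; k <= kmax; ++k) {
      // beads in cell-ring k are at least (k-1)*cs away (minus max radius)
      if (best <= (double)(k - 1) * cs - rmax) break;
      for (int dc = -k; dc <= k; ++dc) {
        const int c = cz + dc;
        if (c < 0 || c >= nc[2]) continue;
        for (int db = -k; db <= k; ++db) {
          const int b = cy + db;
          if (b < 0 || b >= nc[1]) continue;
          for (int da = -k; da <= k; ++da) {
            if (std::max(std::abs(da), std::max(std::abs(db), std::abs(dc))) != k)
              continue;
            const int a = cx + da;
            if (a < 0 || a >= nc[0]) continue;
            const std::vector<int> &cell =
                cells[a + (size_t)nc[0] * (b + (size_t)nc[1] * c)];
            for (size_t q = 0; q < cell.size(); ++q) {
              const int i = cell[q];
              const double ddx = px - beads(i, 0), ddy = py - beads(i, 1),
                           ddz = pz - beads(i, 2);
              double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              if (subr) dd -= radii[i];
              if (dd < best) best = dd;
            }
          }
        }
      }
    }
    if (best < 0.0) best = 0.0;
    if (best > cap) best = cap;
    out[g] = best;
  }
  return out;
}

struct HeapItem {
  double val;
  int node;
};
struct HeapCmp {
  bool operator()(const HeapItem &a, const HeapItem &b) const {
    if (a.val != b.val) return a.val < b.val; // max-heap on bottleneck value
    return a.node > b.node;                   // smaller index wins ties
  }
};

// Maximum-bottleneck (widest) path on the lattice: Dijkstra variant with a
// max-heap on min-clearance-along-path.  sources/sinks/blocked: 0-based
// linear node indices (x fastest).  connectivity: 6 or 26.
// [[Rcpp::export]]
List cpp_widest_path(NumericVector clearance, IntegerVector dims,
                     IntegerVector sources, IntegerVector sinks,
                     int connectivity, IntegerVector blocked) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> is_blocked(n, 0), is_sink(n, 0), done(n, 0);
  for (int i = 0; i < blocked.size(); ++i) is_blocked[blocked[i]] = 1;
  for (int i = 0; i < sinks.size(); ++i) is_sink[sinks[i]] = 1;
  std::vector<double> best(n, -1.0);
  std::vector<int> parent(n, -1);
  std::priority_queue<HeapItem, std::vector<HeapItem>, HeapCmp> pq;
  for (int i = 0; i < sources.size(); ++i) {
    const int s = sources[i];
    if (is_blocked[s]) continue;
    const double v = clearance[s];
    if (v > best[s]) {
      best[s] = v;
      HeapItem it = {v, s};
      pq.push(it);
    }
  }
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        std::array<int, 3> o = {{dx, dy, dz}};
        offs.push_back(o);
      }
  int found = -1;
  while (!pq.empty()) {
    const HeapItem it = pq.top();
    pq.pop();
    const int u = it.node;
    if (done[u] || it.val < best[u]) continue;
    done[u] = 1;
    if (is_sink[u]) {
      found = u;
      break;
    }
    const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
    for (size_t q = 0; q < offs.size(); ++q) {
      const int vx = ux + offs[q][0], vy = uy + offs[q][1], vz = uz + offs[q][2];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      const int v = vx + nx * (vy + ny * vz);
      if (is_blocked[v] || done[v]) continue;
      const double nv = std::min(best[u], clearance[v]);
      if (nv > best[v]) {
        best[v] = nv;
        parent[v] = u;
        HeapItem jt = {nv, v};
        pq.push(jt);
      }
    }
  }
  if (found < 0)
    return List::create(_["reached"] = false, _["bottleneck"] = 0.0,
                        _["path"] = IntegerVector(0));
  std::vector<int> path;
  for (int u = found; u >= 0; u = parent[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  return List::create(_["reached"] = true, _["bottleneck"] = best[found],
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
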
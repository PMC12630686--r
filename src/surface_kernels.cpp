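// Surface kernels: deterministic SASA quadrature, SES signed-field meshing
// (marching tetrahedra), and exact nearest-neighbour queries on cell lists.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

// ---- uniform cell list -----------------------------------------------------
struct CellList {
  double cell;            // cell edge length
  double ox, oy, oz;      // origin
  std::unordered_map<std::uint64_t, std::vector<int>> cells;

  static std::uint64_t key(int i, int j, int k) {
    const std::uint64_t B = 1u << 20;
    return (static_cast<std::uint64_t>(i + (int)B)) |
           (static_cast<std::uint64_t>(j + (int)B) << 21) |
           (static_cast<std::uint64_t>(k + (int)B) << 42);
  }
  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    ox = oy = oz = 0.0;
    const int n = pts.nrow();
    cells.clear();
    cells.reserve(n);
    for (int a = 0; a < n; ++a) {
      int i = (int)std::floor(pts(a, 0) / cell);
      int j = (int)std::floor(pts(a, 1) / cell);
      int k = (int)std::floor(pts(a, 2) / cell);
      cells[key(i, j, k)].push_back(a);
    }
  }
  // collect members of the 27 cells around (x,y,z)
  void neighbours27(double x, double y, double z, std::vector<int>& out) const {
    out.clear();
    int ci = (int)std::floor(x / cell);
    int cj = (int)std::floor(y / cell);
    int ck = (int)std::floor(z / cell);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
        for (int dk = -1; dk <= 1; ++dk) {
          auto it = cells.find(key(ci + di, cj + dj, ck + dk));
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

inline double dist2(double ax, double ay, double az,
                    double bx, double by, double bz) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// Deterministic generalized-spiral (Fibonacci) point set on the unit sphere.
// [[Rcpp::export]]
NumericMatrix cpp_spiral_points(int n) {
  if (n < 1) stop("n must be >= 1");
  NumericMatrix pts(n, 3);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    pts(k, 0) = r * std::cos(phi);
    pts(k, 1) = r * std::sin(phi);
    pts(k, 2) = z;
  }
  return pts;
}

// Shrake-Rupley quadrature on probe-expanded spheres. Optionally returns the
// exposed quadrature points (samples of the solvent-accessible surface).
// [[Rcpp::export]]
List cpp_sasa(NumericMatrix coords, NumericVector radii, double probe,
              int n_points, bool return_points) {
  const int n = coords.nrow();
  if (n == 0) stop("no atoms");
  NumericVector R(n);
  double maxR = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radii[i] + probe;
    if (R[i] > maxR) maxR = R[i];
  }
  CellList cl;
  cl.build(coords, 2.0 * maxR + 1e-9);
  NumericMatrix unit = cpp_spiral_points(n_points);

  NumericVector area(n);
  std::vector<double> epx, epy, epz;
  std::vector<int> eatom;
  std::vector<int> nb;
  std::vector<int> occl;

  for (int i = 0; i < n; ++i) {
    cl.neighbours27(coords(i, 0), coords(i, 1), coords(i, 2), nb);
    occl.clear();
    for (int idx : nb) {
      if (idx == i) continue;
      double cut = R[i] + R[idx];
      if (dist2(coords(i, 0), coords(i, 1), coords(i, 2),
                coords(idx, 0), coords(idx, 1), coords(idx, 2)) < cut * cut)
        occl.push_back(idx);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = coords(i, 0) + R[i] * unit(k, 0);
      double py = coords(i, 1) + R[i] * unit(k, 1);
      double pz = coords(i, 2) + R[i] * unit(k, 2);
      bool free_pt = true;
      for (int j : occl) {
        if (dist2(px, py, pz, coords(j, 0), coords(j, 1), coords(j, 2)) <
            R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) {
        ++exposed;
        if (return_points) {
          epx.push_back(px); epy.push_back(py); epz.push_back(pz);
          eatom.push_back(i + 1);
        }
      }
    }
    area[i] = (4.0 * M_PI * R[i] * R[i]) * ((double)exposed / n_points);
  }

  List out = List::create(_["per_atom_area"] = area);
  if (return_points) {
    int m = (int)epx.size();
    NumericMatrix pts(m, 3);
    for (int k = 0; k < m; ++k) {
      pts(k, 0) = epx[k]; pts(k, 1) = epy[k]; pts(k, 2) = epz[k];
    }
    out["points"] = pts;
    out["point_atom"] = wrap(eatom);
  }
  return out;
}

// ---- SES meshing -----------------------------------------------------------
// Implicit function on a regular grid:
//   f(x) = min( -A(x),  dist(x, exposed SAS samples) - probe )
// where A(x) = min_i(|x - c_i| - (r_i + probe)) is the signed distance to the
// union of probe-expanded spheres. f > 0 inside the solvent-excluded body;
// the zero level set is the SES. Isosurfaced by marching tetrahedra on a
// translation-invariant 6-tet cube split (consistent face diagonals), so the
// resulting mesh is closed and orientable.
// [[Rcpp::export]]
List cpp_ses_mesh(NumericMatrix coords, NumericVector radii, double probe,
                  double spacing, NumericMatrix sas_points) {
  const int n = coords.nrow();
  if (n == 0) stop("no atoms");
  double maxr = 0.0;
  for (int i = 0; i < n; ++i) maxr = std::max(maxr, (double)radii[i]);
  const double pad = maxr + probe + 3.0 * spacing;

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], coords(i, d));
      hi[d] = std::max(hi[d], coords(i, d));
    }
  double org[3];
  int dim[3];
  for (int d = 0; d < 3; ++d) {
    org[d] = lo[d] - pad;
    dim[d] = (int)std::ceil((hi[d] + pad - org[d]) / spacing) + 2;
  }
  const std::int64_t nnode =
      (std::int64_t)dim[0] * dim[1] * dim[2];
  if (nnode > 80000000LL)
    stop("SES grid too large (%d x %d x %d nodes); increase grid spacing",
         dim[0], dim[1], dim[2]);

  // cell lists
  const double acap = 2.0 * spacing;               // clamp for A
  CellList atoms_cl;
  atoms_cl.build(coords, maxr + probe + acap + 1e-9);
  const double pcap = probe + 2.0 * spacing + 1e-9; // exact distP up to pcap
  CellList pts_cl;
  if (sas_points.nrow() == 0) stop("empty SAS sample set");
  pts_cl.build(sas_points, pcap);

  std::vector<double> f((size_t)nnode);
  std::vector<int> nb;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  for (int k = 0; k < nz; ++k) {
    double z = org[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = org[1] + j * spacing;
      for (int i = 0; i < nx; ++i) {
        double x = org[0] + i * spacing;
        // A(x): signed distance to union of expanded spheres (clamped above)
        double A = acap;
        atoms_cl.neighbours27(x, y, z, nb);
        for (int a : nb) {
          double d = std::sqrt(dist2(x, y, z, coords(a, 0), coords(a, 1),
                                     coords(a, 2))) - (radii[a] + probe);
          if (d < A) A = d;
        }
        // dist to SAS samples (clamped above at pcap)
        double dp2best = pcap * pcap;
        pts_cl.neighbours27(x, y, z, nb);
        for (int p : nb) {
          double d2 = dist2(x, y, z, sas_points(p, 0), sas_points(p, 1),
                            sas_points(p, 2));
          if (d2 < dp2best) dp2best = d2;
        }
        double v = std::min(-A, std::sqrt(dp2best) - probe);
        if (std::fabs(v) < 1e-9) v = -1e-9; // avoid on-grid zeros
        f[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = v;
      }
    }
  }

  // marching tetrahedra
  auto node_id = [&](int i, int j, int k) -> std::int64_t {
    return (std::int64_t)i + (std::int64_t)nx * (j + (std::int64_t)ny * k);
  };
  // cube corner offsets, bit pattern c0..c7
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                        {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                          {0,7,4,6},{0,4,5,6},{0,5,1,6}};

  std::unordered_map<std::uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tris;

  auto edge_point = [&](std::int64_t na, std::int64_t nb_,
                        const double pa[3], const double pb[3],
                        double fa, double fb) -> int {
    std::int64_t a = na, b = nb_;
    const double* p1 = pa; const double* p2 = pb;
    double f1 = fa, f2 = fb;
    if (a > b) { std::swap(a, b); std::swap(p1, p2); std::swap(f1, f2); }
    // node ids fit in 32 bits by the grid-size guard; key (a<<32)|b is unique
    std::uint64_t ekey = (static_cast<std::uint64_t>(a) << 32) |
                         (static_cast<std::uint64_t>(b) & 0xffffffffULL);
    auto it = edge_vertex.find(ekey);
    if (it != edge_vertex.end()) return it->second;
    double t = f1 / (f1 - f2); // f crosses zero between the nodes
    int idx = (int)vx.size();
    vx.push_back(p1[0] + t * (p2[0] - p1[0]));
    vy.push_back(p1[1] + t * (p2[1] - p1[1]));
    vz.push_back(p1[2] + t * (p2[2] - p1[2]));
    edge_vertex.emplace(ekey, idx);
    return idx;
  };

  auto emit_tri = [&](int a, int b, int c,
                      const double in_c[3], const double out_c[3]) {
    // orient so the normal points from inside (f>0) to outside
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy;
    double nyv = uz * wx - ux * wz;
    double nzv = ux * wy - uy * wx;
    double dx = out_c[0] - in_c[0], dy = out_c[1] - in_c[1],
           dz = out_c[2] - in_c[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(b, c);
    tris.push_back(a); tris.push_back(b); tris.push_back(c);
  };

  double cpos[8][3];
  std::int64_t cid[8];
  double cf[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cid[c] = node_id(ii, jj, kk);
          cf[c] = f[(size_t)cid[c]];
          cpos[c][0] = org[0] + ii * spacing;
          cpos[c][1] = org[1] + jj * spacing;
          cpos[c][2] = org[2] + kk * spacing;
          (cf[c] > 0 ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4], vo[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int v = tets[t][c];
            if (cf[v] > 0) vi[ni++] = v; else vo[no++] = v;
          }
          if (ni == 0 || ni == 4) continue;
          // centroids of inside/outside corners, for orientation
          double ic[3] = {0, 0, 0}, oc[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int d = 0; d < 3; ++d) ic[d] += cpos[vi[c]][d] / ni;
          for (int c = 0; c < no; ++c)
            for (int d = 0; d < 3; ++d) oc[d] += cpos[vo[c]][d] / no;
          if (ni == 1) {
            int a = edge_point(cid[vi[0]], cid[vo[0]], cpos[vi[0]],
                               cpos[vo[0]], cf[vi[0]], cf[vo[0]]);
            int b = edge_point(cid[vi[0]], cid[vo[1]], cpos[vi[0]],
                               cpos[vo[1]], cf[vi[0]], cf[vo[1]]);
            int c = edge_point(cid[vi[0]], cid[vo[2]], cpos[vi[0]],
                               cpos[vo[2]], cf[vi[0]], cf[vo[2]]);
            emit_tri(a, b, c, ic, oc);
          } else if (ni == 3) {
            int a = edge_point(cid[vo[0]], cid[vi[0]], cpos[vo[0]],
                               cpos[vi[0]], cf[vo[0]], cf[vi[0]]);
            int b = edge_point(cid[vo[0]], cid[vi[1]], cpos[vo[0]],
                               cpos[vi[1]], cf[vo[0]], cf[vi[1]]);
            int c = edge_point(cid[vo[0]], cid[vi[2]], cpos[vo[0]],
                               cpos[vi[2]], cf[vo[0]], cf[vi[2]]);
            emit_tri(a, b, c, ic, oc);
          } else { // 2 in, 2 out -> quad
            int a = edge_point(cid[vi[0]], cid[vo[0]], cpos[vi[0]],
                               cpos[vo[0]], cf[vi[0]], cf[vo[0]]);
            int b = edge_point(cid[vi[0]], cid[vo[1]], cpos[vi[0]],
                               cpos[vo[1]], cf[vi[0]], cf[vo[1]]);
            int c = edge_point(cid[vi[1]], cid[vo[1]], cpos[vi[1]],
                               cpos[vo[1]], cf[vi[1]], cf[vo[1]]);
            int d = edge_point(cid[vi[1]], cid[vo[0]], cpos[vi[1]],
                               cpos[vo[0]], cf[vi[1]], cf[vo[0]]);
            emit_tri(a, b, c, ic, oc);
            emit_tri(a, c, d, ic, oc);
          }
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v];
  }
  const int nt = (int)tris.size() / 3;
  IntegerMatrix Tm(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Tm(t, 0) = tris[3 * t] + 1;
    Tm(t, 1) = tris[3 * t + 1] + 1;
    Tm(t, 2) = tris[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = Tm,
                      _["grid_dim"] = IntegerVector::create(nx, ny, nz));
}

// Exact nearest-neighbour distance from each query point to the reference set.
// [[Rcpp::export]]
NumericVector cpp_nearest_point_dist(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  // heuristic cell size from reference bounding box
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref(i, d));
      hi[d] = std::max(hi[d], ref(i, d));
    }
  double vol = std::max(1e-3, (hi[0] - lo[0]) * (hi[1] - lo[1]) *
                                  (hi[2] - lo[2]));
  double cell = std::max(0.75, std::cbrt(vol / std::max(1, nr)) * 2.0);
  CellList cl;
  cl.build(ref, cell);
  // max shells needed to cover the reference box from any query
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    int ci = (int)std::floor(x / cell);
    int cj = (int)std::floor(y / cell);
    int ck = (int)std::floor(z / cell);
    double best2 = R_PosInf;
    for (int s = 0;; ++s) {
      if (best2 < R_PosInf) {
        double safe = (double)(s - 1) * cell;
        if (safe > 0 && safe * safe > best2) break;
      }
      bool visited = false;
      for (int di = -s; di <= s; ++di)
        for (int dj = -s; dj <= s; ++dj)
          for (int dk = -s; dk <= s; ++dk) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != s)
              continue;
            auto it = cl.cells.find(CellList::key(ci + di, cj + dj, ck + dk));
            if (it == cl.cells.end()) continue;
            visited = true;
            for (int p : it->second) {
              double d2 = dist2(x, y, z, ref(p, 0), ref(p, 1), ref(p, 2));
              if (d2 < best2) best2 = d2;
            }
          }
      (void)visited;
      if (s > 4000) stop("nearest-neighbour search failed to terminate");
    }
    out[q] = std::sqrt(best2);
  }
  return out;
}

// Nearest atom per vertex by surface distance |v - c| - r; ties -> lowest
// atom index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_atom(NumericMatrix verts, NumericMatrix coords,
                               NumericVector radii) {
  const int nv = verts.nrow(), na = coords.nrow();
  if (na == 0) stop("no atoms");
  double maxr = 0.0;
  for (int i = 0; i < na; ++i) maxr = std::max(maxr, (double)radii[i]);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < na; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], coords(i, d));
      hi[d] = std::max(hi[d], coords(i, d));
    }
  double vol = std::max(1e-3, (hi[0] - lo[0]) * (hi[1] - lo[1]) *
                                  (hi[2] - lo[2]));
  double cell = std::max(1.0, std::cbrt(vol / na) * 2.0);
  CellList cl;
  cl.build(coords, cell);
  IntegerVector out(nv);
  for (int q = 0; q < nv; ++q) {
    double x = verts(q, 0), y = verts(q, 1), z = verts(q, 2);
    int ci = (int)std::floor(x / cell);
    int cj = (int)std::floor(y / cell);
    int ck = (int)std::floor(z / cell);
    double best = R_PosInf;
    int best_idx = -1;
    for (int s = 0;; ++s) {
      if (best_idx >= 0) {
        double safe = (double)(s - 1) * cell - maxr;
        if (safe > best) break;
      }
      for (int di = -s; di <= s; ++di)
        for (int dj = -s; dj <= s; ++dj)
          for (int dk = -s; dk <= s; ++dk) {
            if (std::max({std::abs(di), std::abs(dj), std::abs(dk)}) != s)
              continue;
            auto it = cl.cells.find(CellList::key(ci + di, cj + dj, ck + dk));
            if (it == cl.cells.end()) continue;
            for (int a : it->second) {
              double sd = std::sqrt(dist2(x, y, z, coords(a, 0), coords(a, 1),
                                          coords(a, 2))) - radii[a];
              if (sd < best - 1e-9 ||
                  (std::fabs(sd - best) <= 1e-9 && a < best_idx)) {
                best = sd;
                best_idx = a;
              }
            }
          }
      if (s > 4000) stop("nearest-atom search failed to terminate");
    }
    out[q] = best_idx + 1;
  }
  return out;
}
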
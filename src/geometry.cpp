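// Compiled geometry kernels: brute-force k-nearest neighbours, greedy
// farthest-point sampling, tetrahedral isosurface extraction and
// ray/triangle-mesh intersection.  All coordinates are in mm.
#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-nearest neighbours (brute force, partial selection).
// Returns indices (1-based) and distances of the k nearest points in `ref`
// for every row of `query`.  self_skip: when ref and query are the same
// cloud, skip the zero-distance self match by index identity.
// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k, bool self_skip) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (k > (self_skip ? nr - 1 : nr))
    stop("k exceeds the number of available reference points");
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<std::pair<double, int>> d(nr);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int m = 0;
    for (int j = 0; j < nr; ++j) {
      if (self_skip && j == i) continue;
      const double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy,
                   dz = ref(j, 2) - qz;
      d[m++] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.begin() + m);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d[j].second + 1;
      dist(i, j) = std::sqrt(d[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Greedy farthest-point sampling.  `first` is the 1-based index of the seeded
// start point; each subsequent pick maximises the minimum distance to the
// already selected set, smallest index winning ties.
// [[Rcpp::export(name = ".cpp_fps")]]
IntegerVector cpp_fps(NumericMatrix pts, int m, int first) {
  const int n = pts.nrow();
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = first - 1;
  out[0] = first;
  for (int s = 1; s < m; ++s) {
    const double cx = pts(cur, 0), cy = pts(cur, 1), cz = pts(cur, 2);
    int best = -1;
    double bestd = -1.0;
    for (int j = 0; j < n; ++j) {
      const double dx = pts(j, 0) - cx, dy = pts(j, 1) - cy,
                   dz = pts(j, 2) - cz;
      const double dd = dx * dx + dy * dy + dz * dz;
      if (dd < mind[j]) mind[j] = dd;
      if (mind[j] > bestd) { bestd = mind[j]; best = j; }
    }
    cur = best;
    out[s] = best + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface extraction by tetrahedral decomposition of the voxel grid.
// Each grid cell is split into six tetrahedra sharing the 0-7 cell diagonal;
// the decomposition is mirror-consistent across shared cell faces, so the
// output surface is closed whenever the above-iso region does not touch the
// grid boundary.  Vertices are deduplicated exactly via the grid edge they
// lie on.  Triangles are oriented with normals pointing away from the
// above-iso (interior) side.

struct MTState {
  std::map<std::pair<int, int>, int> edge_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static int mt_edge_vertex(MTState &st, int ia, int ib, double fa, double fb,
                          double iso, const NumericVector &gx,
                          const NumericVector &gy, const NumericVector &gz,
                          int nx, int ny) {
  std::pair<int, int> key = ia < ib ? std::make_pair(ia, ib)
                                    : std::make_pair(ib, ia);
  std::map<std::pair<int, int>, int>::iterator it = st.edge_id.find(key);
  if (it != st.edge_id.end()) return it->second;
  const double t = (iso - fa) / (fb - fa);
  const int ai = ia % nx, aj = (ia / nx) % ny, ak = ia / (nx * ny);
  const int bi = ib % nx, bj = (ib / nx) % ny, bk = ib / (nx * ny);
  st.vx.push_back(gx[ai] + t * (gx[bi] - gx[ai]));
  st.vy.push_back(gy[aj] + t * (gy[bj] - gy[aj]));
  st.vz.push_back(gz[ak] + t * (gz[bk] - gz[ak]));
  const int id = (int)st.vx.size() - 1;
  st.edge_id[key] = id;
  return id;
}

static void mt_emit(MTState &st, int a, int b, int c, double ix, double iy,
                    double iz) {
  // orient so the normal points away from the interior reference point
  const double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a],
               uz = st.vz[b] - st.vz[a];
  const double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a],
               wz = st.vz[c] - st.vz[a];
  const double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
               nzv = ux * wy - uy * wx;
  const double cx = (st.vx[a] + st.vx[b] + st.vx[c]) / 3.0;
  const double cy = (st.vy[a] + st.vy[b] + st.vy[c]) / 3.0;
  const double cz = (st.vz[a] + st.vz[b] + st.vz[c]) / 3.0;
  const double dot = nxv * (ix - cx) + nyv * (iy - cy) + nzv * (iz - cz);
  if (dot > 0) std::swap(b, c);
  st.tri.push_back(a + 1);
  st.tri.push_back(b + 1);
  st.tri.push_back(c + 1);
}

static void mt_tet(MTState &st, const int id[4], const double f[4],
                   double iso, const NumericVector &gx,
                   const NumericVector &gy, const NumericVector &gz,
                   int nx, int ny) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = f[i] > iso; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return;

  // centroid of interior corners: orientation reference
  double ix = 0, iy = 0, iz = 0;
  for (int i = 0; i < 4; ++i) {
    if (!in[i]) continue;
    const int a = id[i] % nx, b = (id[i] / nx) % ny, c = id[i] / (nx * ny);
    ix += gx[a]; iy += gy[b]; iz += gz[c];
  }
  ix /= nin; iy /= nin; iz /= nin;

  int lone = -1;
  if (nin == 1 || nin == 3) {
    for (int i = 0; i < 4; ++i)
      if (in[i] == (nin == 1)) { lone = i; break; }
    int other[3], m = 0;
    for (int i = 0; i < 4; ++i) if (i != lone) other[m++] = i;
    int e[3];
    for (int i = 0; i < 3; ++i)
      e[i] = mt_edge_vertex(st, id[lone], id[other[i]], f[lone], f[other[i]],
                            iso, gx, gy, gz, nx, ny);
    mt_emit(st, e[0], e[1], e[2], ix, iy, iz);
  } else {  // 2 in / 2 out: quad split into two triangles
    int a[2], b[2], m = 0, p = 0;
    for (int i = 0; i < 4; ++i) { if (in[i]) a[m++] = i; else b[p++] = i; }
    const int e00 = mt_edge_vertex(st, id[a[0]], id[b[0]], f[a[0]], f[b[0]],
                                   iso, gx, gy, gz, nx, ny);
    const int e01 = mt_edge_vertex(st, id[a[0]], id[b[1]], f[a[0]], f[b[1]],
                                   iso, gx, gy, gz, nx, ny);
    const int e10 = mt_edge_vertex(st, id[a[1]], id[b[0]], f[a[1]], f[b[0]],
                                   iso, gx, gy, gz, nx, ny);
    const int e11 = mt_edge_vertex(st, id[a[1]], id[b[1]], f[a[1]], f[b[1]],
                                   iso, gx, gy, gz, nx, ny);
    mt_emit(st, e00, e01, e11, ix, iy, iz);
    mt_emit(st, e00, e11, e10, ix, iy, iz);
  }
}

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(NumericVector values, IntegerVector dims,
                    NumericVector gx, NumericVector gy, NumericVector gz,
                    double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // six tetrahedra per cell, all sharing the 0-7 diagonal
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  MTState st;
  int corner[8];
  double f[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          const int ci = i + (c & 1), cj = j + ((c >> 1) & 1),
                    ck = k + ((c >> 2) & 1);
          corner[c] = ci + nx * (cj + ny * ck);
          f[c] = values[corner[c]];
        }
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) (f[c] > iso ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int tid[4] = {corner[TETS[t][0]], corner[TETS[t][1]],
                              corner[TETS[t][2]], corner[TETS[t][3]]};
          const double tf[4] = {f[TETS[t][0]], f[TETS[t][1]],
                                f[TETS[t][2]], f[TETS[t][3]]};
          mt_tet(st, tid, tf, iso, gx, gy, gz, nx, ny);
        }
      }
  const int nv = (int)st.vx.size(), nf = (int)st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.tri[3 * i]; F(i, 1) = st.tri[3 * i + 1];
    F(i, 2) = st.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Ray / triangle-mesh intersection.  For every face: ray-plane solve
// t = (D - n.r0) / (n.rd) with D = n.P1, then the cyclic same-side
// point-in-triangle condition.  Hits with t <= eps or near-parallel planes
// are rejected; duplicate hits within eps_merge along t (shared-edge
// crossings) are merged.  Returns hits sorted by t with the sign of rd.n
// (entering = negative against outward normals).
// [[Rcpp::export(name = ".cpp_ray_mesh")]]
DataFrame cpp_ray_mesh(NumericVector r0, NumericVector rd,
                       NumericMatrix V, IntegerMatrix F,
                       double eps, double eps_merge) {
  const int nf = F.nrow();
  std::vector<std::pair<double, int>> hits;  // (t, face)
  std::vector<int> enter;
  for (int fidx = 0; fidx < nf; ++fidx) {
    const int a = F(fidx, 0) - 1, b = F(fidx, 1) - 1, c = F(fidx, 2) - 1;
    const double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    const double e1x = V(b, 0) - ax, e1y = V(b, 1) - ay, e1z = V(b, 2) - az;
    const double e2x = V(c, 0) - ax, e2y = V(c, 1) - ay, e2z = V(c, 2) - az;
    double nx = e1y * e2z - e1z * e2y;
    double ny = e1z * e2x - e1x * e2z;
    double nz = e1x * e2y - e1y * e2x;
    const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn < 1e-300) continue;  // degenerate face
    nx /= nn; ny /= nn; nz /= nn;
    const double denom = nx * rd[0] + ny * rd[1] + nz * rd[2];
    if (std::fabs(denom) < eps) continue;  // parallel
    const double D = nx * ax + ny * ay + nz * az;
    const double t = (D - (nx * r0[0] + ny * r0[1] + nz * r0[2])) / denom;
    if (t <= eps) continue;
    const double px = r0[0] + t * rd[0], py = r0[1] + t * rd[1],
                 pz = r0[2] + t * rd[2];
    // same-side test: for each vertex i, the cross products of (P - Pi) with
    // the two adjacent edges must not point to the same side
    const double vx3[3] = {V(a, 0), V(b, 0), V(c, 0)};
    const double vy3[3] = {V(a, 1), V(b, 1), V(c, 1)};
    const double vz3[3] = {V(a, 2), V(b, 2), V(c, 2)};
    bool inside = true;
    const double tol = 1e-10 * nn;  // area-scaled slack: edge contact counts
    for (int i = 0; i < 3 && inside; ++i) {
      const int ip = (i + 2) % 3, in = (i + 1) % 3;
      const double wx = px - vx3[i], wy = py - vy3[i], wz = pz - vz3[i];
      const double pxv = vx3[ip] - vx3[i], pyv = vy3[ip] - vy3[i],
                   pzv = vz3[ip] - vz3[i];
      const double qxv = vx3[in] - vx3[i], qyv = vy3[in] - vy3[i],
                   qzv = vz3[in] - vz3[i];
      const double c1x = wy * pzv - wz * pyv, c1y = wz * pxv - wx * pzv,
                   c1z = wx * pyv - wy * pxv;
      const double c2x = wy * qzv - wz * qyv, c2y = wz * qxv - wx * qzv,
                   c2z = wx * qyv - wy * qxv;
      if (c1x * c2x + c1y * c2y + c1z * c2z > tol) inside = false;
    }
    if (!inside) continue;
    hits.push_back(std::make_pair(t, fidx + 1));
    enter.push_back(denom < 0 ? 1 : 0);
  }
  // sort by t, keeping the entering flag aligned
  std::vector<int> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    return hits[i].first < hits[j].first;
  });
  std::vector<double> tv;
  std::vector<int> fv, ev;
  for (size_t i = 0; i < ord.size(); ++i) {
    const double t = hits[ord[i]].first;
    if (!tv.empty() && t - tv.back() < eps_merge) continue;  // merged
    tv.push_back(t);
    fv.push_back(hits[ord[i]].second);
    ev.push_back(enter[ord[i]]);
  }
  return DataFrame::create(_["t"] = tv, _["face"] = fv,
                           _["entering"] = ev);
}
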
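// Voxel-space kernels: parity voxelization of a closed mesh, 3D connected
// component labeling, and isosurface extraction by marching tetrahedra.
// Arrays use R's column-major layout: linear index = i + nx*(j + ny*k).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parity voxelization: cast a +z ray through each (i,j) voxel-column, collect
// triangle crossings, fill voxel centers between successive crossing pairs.
// Ray x/y positions are offset by a tiny deterministic jitter so rays never
// pass exactly through triangle edges or vertices of well-formed meshes.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_mask(NumericMatrix V, IntegerMatrix F,
                                 IntegerVector dims, NumericVector origin,
                                 NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double jx = 2.6458e-4 * sx, jy = 4.1231e-4 * sy; // deterministic jitter

  std::vector<std::vector<double>> cross((size_t)nx * ny);

  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    const double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    const double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    const double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);
    const double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (det == 0.0) continue; // vertical triangle: no transversal z-crossing
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - ox - jx) / sx);
    int i1 = (int)std::floor((xmax - ox - jx) / sx);
    int j0 = (int)std::ceil((ymin - oy - jy) / sy);
    int j1 = (int)std::floor((ymax - oy - jy) / sy);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      const double py = oy + j * sy + jy;
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + i * sx + jx;
        // barycentric in the xy projection
        const double l1 = ((px - ax) * (cy - ay) - (py - ay) * (cx - ax)) / det;
        const double l2 = ((bx - ax) * (py - ay) - (by - ay) * (px - ax)) / det;
        if (l1 < 0.0 || l2 < 0.0 || l1 + l2 > 1.0) continue;
        const double z = az + l1 * (bz - az) + l2 * (cz - az);
        cross[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }

  LogicalVector mask((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = cross[(size_t)i + (size_t)nx * j];
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      const size_t npair = zs.size() / 2; // odd counts cannot occur for closed meshes off the jittered ray
      for (size_t m = 0; m < npair; ++m) {
        const double zlo = zs[2 * m], zhi = zs[2 * m + 1];
        int k0 = (int)std::ceil((zlo - oz) / sz);
        int k1 = (int)std::floor((zhi - oz) / sz);
        k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          mask[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Connected component labeling (6 or 26 connectivity), flood fill.
// Returns integer labels, 0 = background; label ids are in first-encounter
// order of the scan, so the component containing the smallest linear index
// of any tied-size pair has the smaller label.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offs.push_back(dx);
        offs.push_back(dy);
        offs.push_back(dz);
      }
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < offs.size(); t += 3) {
        int ii = i + offs[t], jj = j + offs[t + 1], kk = k + offs[t + 2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra. Each grid cube is split into the six tetrahedra that
// share the main diagonal; the iso-level crossing on each cut edge is found
// by linear interpolation. Vertices are deduplicated on global grid edges,
// and each output triangle is oriented with its normal pointing away from
// the high-intensity (interior) side.
namespace {

struct MTBuilder {
  const double* field;
  int nx, ny, nz;
  double iso;
  double ox, oy, oz, sx, sy, sz;
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts; // x,y,z triplets
  std::vector<int> tris;     // 0-based

  inline double val(R_xlen_t g) const { return field[g]; }

  inline void coords(R_xlen_t g, double* p) const {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((R_xlen_t)nx * ny));
    p[0] = ox + i * sx;
    p[1] = oy + j * sy;
    p[2] = oz + k * sz;
  }

  int edge_point(R_xlen_t g1, R_xlen_t g2) {
    if (g1 > g2) std::swap(g1, g2);
    uint64_t key = (uint64_t)g1 * (uint64_t)((R_xlen_t)nx * ny * nz) + (uint64_t)g2;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double v1 = val(g1), v2 = val(g2);
    double t = (iso - v1) / (v2 - v1);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double p1[3], p2[3];
    coords(g1, p1);
    coords(g2, p2);
    int id = (int)(verts.size() / 3);
    for (int c = 0; c < 3; ++c) verts.push_back(p1[c] + t * (p2[c] - p1[c]));
    edge_vertex.emplace(key, id);
    return id;
  }

  void emit(int a, int b, int c, const double* inside_centroid) {
    // orient so the normal points away from the interior
    const double* pa = &verts[3 * a];
    const double* pb = &verts[3 * b];
    const double* pc = &verts[3 * c];
    double u[3], w[3], nrm[3], d[3];
    for (int i = 0; i < 3; ++i) {
      u[i] = pb[i] - pa[i];
      w[i] = pc[i] - pa[i];
      d[i] = inside_centroid[i] - pa[i];
    }
    nrm[0] = u[1] * w[2] - u[2] * w[1];
    nrm[1] = u[2] * w[0] - u[0] * w[2];
    nrm[2] = u[0] * w[1] - u[1] * w[0];
    double s = nrm[0] * d[0] + nrm[1] * d[1] + nrm[2] * d[2];
    if (s > 0.0) std::swap(b, c);
    tris.push_back(a);
    tris.push_back(b);
    tris.push_back(c);
  }

  void do_tet(const R_xlen_t g[4]) {
    bool in[4];
    int nin = 0;
    for (int i = 0; i < 4; ++i) {
      in[i] = val(g[i]) > iso;
      if (in[i]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    double cen[3] = {0, 0, 0};
    double p[3];
    for (int i = 0; i < 4; ++i) {
      if (!in[i]) continue;
      coords(g[i], p);
      for (int c = 0; c < 3; ++c) cen[c] += p[c] / nin;
    }
    int ins[4], outs[4];
    int ni = 0, no = 0;
    for (int i = 0; i < 4; ++i) (in[i] ? ins[ni++] : outs[no++]) = i;
    if (nin == 1) {
      int e0 = edge_point(g[ins[0]], g[outs[0]]);
      int e1 = edge_point(g[ins[0]], g[outs[1]]);
      int e2 = edge_point(g[ins[0]], g[outs[2]]);
      emit(e0, e1, e2, cen);
    } else if (nin == 3) {
      int e0 = edge_point(g[outs[0]], g[ins[0]]);
      int e1 = edge_point(g[outs[0]], g[ins[1]]);
      int e2 = edge_point(g[outs[0]], g[ins[2]]);
      emit(e0, e1, e2, cen);
    } else { // 2 in, 2 out: quad split into two triangles
      int e00 = edge_point(g[ins[0]], g[outs[0]]);
      int e01 = edge_point(g[ins[0]], g[outs[1]]);
      int e10 = edge_point(g[ins[1]], g[outs[0]]);
      int e11 = edge_point(g[ins[1]], g[outs[1]]);
      emit(e00, e01, e11, cen);
      emit(e00, e11, e10, cen);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims, double iso,
                        NumericVector origin, NumericVector spacing) {
  // Grid values exactly at the iso level would place surface vertices on
  // grid points, creating zero-area triangles whose corners collapse under
  // later vertex merging. Nudge such values just below the level; the
  // geometric perturbation is ~1e-4 of the field range.
  NumericVector fld = clone(field);
  double fmin = fld[0], fmax = fld[0];
  for (R_xlen_t i = 0; i < fld.size(); ++i) {
    if (fld[i] < fmin) fmin = fld[i];
    if (fld[i] > fmax) fmax = fld[i];
  }
  double delta = 1e-4 * (fmax - fmin);
  if (delta <= 0) delta = 1e-8;
  for (R_xlen_t i = 0; i < fld.size(); ++i)
    if (fld[i] == iso) fld[i] = iso - delta;

  MTBuilder b;
  b.field = fld.begin();
  b.nx = dims[0];
  b.ny = dims[1];
  b.nz = dims[2];
  b.iso = iso;
  b.ox = origin[0]; b.oy = origin[1]; b.oz = origin[2];
  b.sx = spacing[0]; b.sy = spacing[1]; b.sz = spacing[2];

  // six tetrahedra sharing the (0,0,0)-(1,1,1) diagonal; corner id = i+2j+4k
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  const R_xlen_t nxy = (R_xlen_t)b.nx * b.ny;
  for (int k = 0; k + 1 < b.nz; ++k) {
    for (int j = 0; j + 1 < b.ny; ++j) {
      for (int i = 0; i + 1 < b.nx; ++i) {
        R_xlen_t corner[8];
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          corner[c] = (R_xlen_t)(i + di) + (R_xlen_t)b.nx * (j + dj) + nxy * (k + dk);
        }
        // quick reject: all corners same side
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          if (b.val(corner[c]) > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          R_xlen_t g[4];
          for (int v = 0; v < 4; ++v) g[v] = corner[tets[t][v]];
          b.do_tet(g);
        }
      }
    }
  }

  int nv = (int)(b.verts.size() / 3);
  int nf = (int)(b.tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) V(i, c) = b.verts[3 * i + c];
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) F(f, c) = b.tris[3 * f + c] + 1; // 1-based for R
  return List::create(_["vertices"] = V, _["faces"] = F);
}
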
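#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D offsets: first nonzero component positive, infinity-norm 1.
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static void get_dims(const IntegerVector &lev, int &nx, int &ny, int &nz) {
  IntegerVector d = lev.attr("dim");
  if (d.size() != 3) stop("level array must be 3-dimensional");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// [[Rcpp::export(name = ".cpp_dir_offsets")]]
IntegerMatrix cpp_dir_offsets() {
  IntegerMatrix m(NDIR, 3);
  for (int d = 0; d < NDIR; ++d)
    for (int a = 0; a < 3; ++a) m(d, a) = DIRS[d][a];
  return m;
}

// Symmetric co-occurrence counts at distance 1, one Ng x Ng slab per direction.
// lev holds gray levels 1..ng inside the ROI and 0 elsewhere.
// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector lev, int ng) {
  int nx, ny, nz; get_dims(lev, nx, ny, nz);
  NumericVector out(ng * ng * NDIR);
  out.attr("dim") = IntegerVector::create(ng, ng, NDIR);
  for (int d = 0; d < NDIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = &out[(R_xlen_t)d * ng * ng];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      int li = lev[idx3(x, y, z, nx, ny)];
      if (li <= 0) continue;
      int x2 = x + dx, y2 = y + dy, z2 = z + dz;
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      int lj = lev[idx3(x2, y2, z2, nx, ny)];
      if (lj <= 0) continue;
      slab[(li - 1) + ng * (lj - 1)] += 1.0;
      slab[(lj - 1) + ng * (li - 1)] += 1.0;
    }
  }
  return out;
}

// Run-length counts: one Ng x maxlen slab per direction. A run is a maximal
// collinear segment of ROI voxels sharing one gray level.
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector lev, int ng) {
  int nx, ny, nz; get_dims(lev, nx, ny, nz);
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxlen * NDIR);
  out.attr("dim") = IntegerVector::create(ng, maxlen, NDIR);
  for (int d = 0; d < NDIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = &out[(R_xlen_t)d * ng * maxlen];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      int li = lev[idx3(x, y, z, nx, ny)];
      if (li <= 0) continue;
      // run starts where the backward neighbour is absent or differs
      int xp = x - dx, yp = y - dy, zp = z - dz;
      bool prev_in = xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz;
      if (prev_in && lev[idx3(xp, yp, zp, nx, ny)] == li) continue;
      int len = 1;
      int xn = x + dx, yn = y + dy, zn = z + dz;
      while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
             lev[idx3(xn, yn, zn, nx, ny)] == li) {
        ++len; xn += dx; yn += dy; zn += dz;
      }
      slab[(li - 1) + ng * (len - 1)] += 1.0;
    }
  }
  return out;
}

// Size zones: 26-connected components of equal gray level.
// Returns an n_zones x 2 matrix of (level, size).
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector lev, int ng) {
  int nx, ny, nz; get_dims(lev, nx, ny, nz);
  R_xlen_t n = lev.size();
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || lev[s] <= 0) continue;
    int li = lev[s], size = 0;
    stack.clear(); stack.push_back((int)s); seen[s] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back(); ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
        int w = idx3(x2, y2, z2, nx, ny);
        if (!seen[w] && lev[w] == li) { seen[w] = 1; stack.push_back(w); }
      }
    }
    zl.push_back(li); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}

// Dependence counts (alpha = 0): dependence size = 1 + number of 26-neighbours
// inside the ROI with the same gray level. Ng x 27 matrix.
// [[Rcpp::export(name = ".cpp_gldm_counts")]]
NumericMatrix cpp_gldm_counts(IntegerVector lev, int ng) {
  int nx, ny, nz; get_dims(lev, nx, ny, nz);
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = lev[idx3(x, y, z, nx, ny)];
    if (li <= 0) continue;
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int x2 = x + dx, y2 = y + dy, z2 = z + dz;
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      if (lev[idx3(x2, y2, z2, nx, ny)] == li) ++dep;
    }
    out(li - 1, dep) += 1.0;
  }
  return out;
}

// Neighbourhood gray-tone difference table: per level i, n_i = voxels of level
// i with at least one valid ROI 26-neighbour, s_i = summed |i - mean neighbour
// level| over those voxels. Ng x 2 matrix (n, s).
// [[Rcpp::export(name = ".cpp_ngtdm_counts")]]
NumericMatrix cpp_ngtdm_counts(IntegerVector lev, int ng) {
  int nx, ny, nz; get_dims(lev, nx, ny, nz);
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = lev[idx3(x, y, z, nx, ny)];
    if (li <= 0) continue;
    double sum = 0.0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int x2 = x + dx, y2 = y + dy, z2 = z + dz;
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
      int lj = lev[idx3(x2, y2, z2, nx, ny)];
      if (lj > 0) { sum += lj; ++cnt; }
    }
    if (cnt > 0) {
      out(li - 1, 0) += 1.0;
      out(li - 1, 1) += std::fabs((double)li - sum / cnt);
    }
  }
  return out;
}

// ---- surface mesh by marching tetrahedra -----------------------------------

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 mid(const V3 &a, const V3 &b) {
  return v3(0.5 * (a.x + b.x), 0.5 * (a.y + b.y), 0.5 * (a.z + b.z));
}
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// 6-tetra decomposition of the unit cube around diagonal 0-7
static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

static void add_tri(const V3 &p1, const V3 &p2, const V3 &p3, const V3 &inside_ref,
                    double &area, double &vol) {
  V3 n = cross(sub(p2, p1), sub(p3, p1));
  V3 cen = v3((p1.x + p2.x + p3.x) / 3.0, (p1.y + p2.y + p3.y) / 3.0,
              (p1.z + p2.z + p3.z) / 3.0);
  bool flip = dot(n, sub(cen, inside_ref)) < 0;
  const V3 &a = p1, &b = flip ? p3 : p2, &c = flip ? p2 : p3;
  V3 nn = cross(sub(b, a), sub(c, a));
  area += 0.5 * std::sqrt(dot(nn, nn));
  vol += dot(a, cross(b, c)) / 6.0;  // divergence theorem, outward orientation
}

// iso-crossing point on the edge a-b by linear interpolation
static inline V3 edge_pt(const V3 &pa, const V3 &pb, double va, double vb, double iso) {
  double t = (vb == va) ? 0.5 : (iso - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  return v3(pa.x + t * (pb.x - pa.x), pa.y + t * (pb.y - pa.y),
            pa.z + t * (pb.z - pa.z));
}

// Triangulated iso-surface of a scalar field sampled at voxel centres
// (marching tetrahedra with linear interpolation; the field is expected to
// be zero on its outer border so the surface closes). Vertex positions in
// physical mm. Returns surface area (mm^2) and enclosed mesh volume (mm^3).
// [[Rcpp::export(name = ".cpp_mesh_area_volume")]]
List cpp_mesh_area_volume(NumericVector field, NumericVector spacing, double iso) {
  int nx, ny, nz;
  IntegerVector d = field.attr("dim");
  if (d.size() != 3) stop("field must be a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol = 0.0;
  for (int z = 0; z < nz - 1; ++z) for (int y = 0; y < ny - 1; ++y)
  for (int x = 0; x < nx - 1; ++x) {
    double val[8]; V3 pos[8]; int insum = 0;
    for (int m = 0; m < 8; ++m) {
      int cx = x + (m & 1), cy = y + ((m >> 1) & 1), cz = z + ((m >> 2) & 1);
      val[m] = field[idx3(cx, cy, cz, nx, ny)];
      insum += val[m] >= iso;
      pos[m] = v3(cx * sx, cy * sy, cz * sz);
    }
    if (insum == 0 || insum == 8) continue;
    for (int t = 0; t < 6; ++t) {
      int a = TETS[t][0], b = TETS[t][1], c = TETS[t][2], d4 = TETS[t][3];
      double vi[4] = {val[a], val[b], val[c], val[d4]};
      V3 pp[4] = {pos[a], pos[b], pos[c], pos[d4]};
      int in_ix[4], out_ix[4], ni = 0, no = 0;
      for (int m = 0; m < 4; ++m) {
        if (vi[m] >= iso) in_ix[ni++] = m; else out_ix[no++] = m;
      }
      if (ni == 0 || ni == 4) continue;
      if (ni == 1) {
        V3 ref = pp[in_ix[0]];
        add_tri(edge_pt(pp[in_ix[0]], pp[out_ix[0]], vi[in_ix[0]], vi[out_ix[0]], iso),
                edge_pt(pp[in_ix[0]], pp[out_ix[1]], vi[in_ix[0]], vi[out_ix[1]], iso),
                edge_pt(pp[in_ix[0]], pp[out_ix[2]], vi[in_ix[0]], vi[out_ix[2]], iso),
                ref, area, vol);
      } else if (ni == 3) {
        V3 ref = v3((pp[in_ix[0]].x + pp[in_ix[1]].x + pp[in_ix[2]].x) / 3.0,
                    (pp[in_ix[0]].y + pp[in_ix[1]].y + pp[in_ix[2]].y) / 3.0,
                    (pp[in_ix[0]].z + pp[in_ix[1]].z + pp[in_ix[2]].z) / 3.0);
        add_tri(edge_pt(pp[out_ix[0]], pp[in_ix[0]], vi[out_ix[0]], vi[in_ix[0]], iso),
                edge_pt(pp[out_ix[0]], pp[in_ix[1]], vi[out_ix[0]], vi[in_ix[1]], iso),
                edge_pt(pp[out_ix[0]], pp[in_ix[2]], vi[out_ix[0]], vi[in_ix[2]], iso),
                ref, area, vol);
      } else {  // ni == 2: quad split into two triangles
        int a1 = in_ix[0], a2 = in_ix[1], b1 = out_ix[0], b2 = out_ix[1];
        V3 ref = mid(pp[a1], pp[a2]);
        V3 q1 = edge_pt(pp[a1], pp[b1], vi[a1], vi[b1], iso);
        V3 q2 = edge_pt(pp[a1], pp[b2], vi[a1], vi[b2], iso);
        V3 q3 = edge_pt(pp[a2], pp[b2], vi[a2], vi[b2], iso);
        V3 q4 = edge_pt(pp[a2], pp[b1], vi[a2], vi[b1], iso);
        add_tri(q1, q2, q3, ref, area, vol);
        add_tri(q1, q3, q4, ref, area, vol);
      }
    }
  }
  return List::create(Named("surface_area") = area, Named("mesh_volume") = std::fabs(vol));
}

// Largest pairwise distances between boundary-voxel centres (physical mm):
// overall 3D, and within planes sharing the x, y and z index respectively.
// A boundary voxel has at least one face neighbour outside the mask.
// [[Rcpp::export(name = ".cpp_max_diameters")]]
NumericVector cpp_max_diameters(IntegerVector mask, NumericVector spacing) {
  int nx, ny, nz; get_dims(mask, nx, ny, nz);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<int> bx, by, bz;
  static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    if (mask[idx3(x, y, z, nx, ny)] <= 0) continue;
    bool edge = false;
    for (int f = 0; f < 6 && !edge; ++f) {
      int x2 = x + F[f][0], y2 = y + F[f][1], z2 = z + F[f][2];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz ||
          mask[idx3(x2, y2, z2, nx, ny)] <= 0) edge = true;
    }
    if (edge) { bx.push_back(x); by.push_back(y); bz.push_back(z); }
  }
  size_t n = bx.size();
  double d3 = 0, dslice = 0, dcol = 0, drow = 0;  // slice: same z; col: same x; row: same y
  for (size_t i = 0; i < n; ++i) for (size_t j = i + 1; j < n; ++j) {
    double dx = (bx[i] - bx[j]) * sx, dy = (by[i] - by[j]) * sy, dz = (bz[i] - bz[j]) * sz;
    double dx2 = dx * dx, dy2 = dy * dy, dz2 = dz * dz;
    double q = dx2 + dy2 + dz2;
    if (q > d3) d3 = q;
    if (bz[i] == bz[j] && dx2 + dy2 > dslice) dslice = dx2 + dy2;
    if (bx[i] == bx[j] && dy2 + dz2 > dcol) dcol = dy2 + dz2;
    if (by[i] == by[j] && dx2 + dz2 > drow) drow = dx2 + dz2;
  }
  NumericVector out = NumericVector::create(
    Named("max3d") = std::sqrt(d3), Named("max2d_slice") = std::sqrt(dslice),
    Named("max2d_column") = std::sqrt(dcol), Named("max2d_row") = std::sqrt(drow));
  return out;
}
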
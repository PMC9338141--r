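#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Flattened column-major indexing: i + nx*(j + ny*k), all indices 0-based.

static inline double get3(const NumericVector &v, int i, int j, int k,
                          int nx, int ny) {
  return v[i + nx * (j + (size_t)ny * k)];
}

// Trilinear interpolation at continuous 0-based index coordinates.
// Points outside [0, n-1] on any axis return `outside`.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(const NumericVector &vol,
                                   const IntegerVector &dim,
                                   const NumericMatrix &idx,
                                   double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = idx.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = outside;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = get3(vol, i0, j0, k0, nx, ny);
    double c100 = get3(vol, i0 + 1, j0, k0, nx, ny);
    double c010 = get3(vol, i0, j0 + 1, k0, nx, ny);
    double c110 = get3(vol, i0 + 1, j0 + 1, k0, nx, ny);
    double c001 = get3(vol, i0, j0, k0 + 1, nx, ny);
    double c101 = get3(vol, i0 + 1, j0, k0 + 1, nx, ny);
    double c011 = get3(vol, i0, j0 + 1, k0 + 1, nx, ny);
    double c111 = get3(vol, i0 + 1, j0 + 1, k0 + 1, nx, ny);
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (for categorical label grids).
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(const NumericVector &vol,
                                 const IntegerVector &dim,
                                 const NumericMatrix &idx,
                                 double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = idx.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y),
        k = (int)std::lround(z);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      out[p] = outside;
    else
      out[p] = get3(vol, i, j, k, nx, ny);
  }
  return out;
}

// Joint intensity histogram over paired samples; pairs with a
// non-finite moving value (outside the moving grid) are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(const NumericVector &fvals,
                             const NumericVector &mvals, int bins,
                             double fmin, double fmax, double mmin,
                             double mmax) {
  NumericMatrix h(bins, bins);
  const double fw = (fmax > fmin) ? (fmax - fmin) : 1.0;
  const double mw = (mmax > mmin) ? (mmax - mmin) : 1.0;
  const int n = fvals.size();
  for (int p = 0; p < n; ++p) {
    double mv = mvals[p];
    if (!std::isfinite(mv)) continue;
    double fv = fvals[p];
    int bi = (int)((fv - fmin) / fw * bins);
    int bj = (int)((mv - mmin) / mw * bins);
    if (bi < 0) bi = 0;
    if (bi >= bins) bi = bins - 1;
    if (bj < 0) bj = 0;
    if (bj >= bins) bj = bins - 1;
    h(bi, bj) += 1.0;
  }
  return h;
}

// Fused registration kernel: maps sample points through an affine into
// the moving volume's index space (idx = pts %*% M + off), interpolates
// trilinearly, and accumulates the joint histogram against the paired
// fixed values in one pass. Returns bins x bins counts.
// [[Rcpp::export]]
NumericMatrix cpp_affine_joint_hist(const NumericVector &mov,
                                    const IntegerVector &dim,
                                    const NumericMatrix &pts,
                                    const NumericMatrix &M,
                                    const NumericVector &off,
                                    const NumericVector &fvals, int bins,
                                    double fmin, double fmax, double mmin,
                                    double mmax) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericMatrix h(bins, bins);
  const double fw = (fmax > fmin) ? (fmax - fmin) : 1.0;
  const double mw = (mmax > mmin) ? (mmax - mmin) : 1.0;
  for (int p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double x = px * M(0, 0) + py * M(1, 0) + pz * M(2, 0) + off[0];
    double y = px * M(0, 1) + py * M(1, 1) + pz * M(2, 1) + off[1];
    double z = px * M(0, 2) + py * M(1, 2) + pz * M(2, 2) + off[2];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0))
      continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = get3(mov, i0, j0, k0, nx, ny) * (1 - fx) +
                 get3(mov, i0 + 1, j0, k0, nx, ny) * fx;
    double c10 = get3(mov, i0, j0 + 1, k0, nx, ny) * (1 - fx) +
                 get3(mov, i0 + 1, j0 + 1, k0, nx, ny) * fx;
    double c01 = get3(mov, i0, j0, k0 + 1, nx, ny) * (1 - fx) +
                 get3(mov, i0 + 1, j0, k0 + 1, nx, ny) * fx;
    double c11 = get3(mov, i0, j0 + 1, k0 + 1, nx, ny) * (1 - fx) +
                 get3(mov, i0 + 1, j0 + 1, k0 + 1, nx, ny) * fx;
    double mv = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                (c01 * (1 - fy) + c11 * fy) * fz;
    int bi = (int)((fvals[p] - fmin) / fw * bins);
    int bj = (int)((mv - mmin) / mw * bins);
    if (bi < 0) bi = 0;
    if (bi >= bins) bi = bins - 1;
    if (bj < 0) bj = 0;
    if (bj >= bins) bj = bins - 1;
    h(bi, bj) += 1.0;
  }
  return h;
}

static const int OFF6[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                               {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

// Seeded region growing: breadth-first growth from seeds through voxels
// with lower <= value <= upper (inclusive), restricted to the half-open
// bbox [lo, hi) per axis. conn is 6 or 26. Seeds out of range or out of
// the bbox contribute nothing.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(const NumericVector &vol,
                              const IntegerVector &dim,
                              const IntegerMatrix &seeds, double lower,
                              double upper, const IntegerVector &bbox,
                              int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector mask((size_t)nx * ny * nz);
  std::vector<size_t> queue;
  auto admissible = [&](int i, int j, int k) -> bool {
    if (i < bbox[0] || i >= bbox[1] || j < bbox[2] || j >= bbox[3] ||
        k < bbox[4] || k >= bbox[5])
      return false;
    double v = get3(vol, i, j, k, nx, ny);
    return v >= lower && v <= upper;
  };
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0), j = seeds(s, 1), k = seeds(s, 2);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
    if (!admissible(i, j, k)) continue;
    size_t lin = i + nx * (j + (size_t)ny * k);
    if (!mask[lin]) {
      mask[lin] = true;
      queue.push_back(lin);
    }
  }
  while (!queue.empty()) {
    size_t lin = queue.back();
    queue.pop_back();
    int k = lin / ((size_t)nx * ny);
    int rem = lin - (size_t)k * nx * ny;
    int j = rem / nx, i = rem % nx;
    if (conn == 6) {
      for (int d = 0; d < 6; ++d) {
        int ii = i + OFF6[d][0], jj = j + OFF6[d][1], kk = k + OFF6[d][2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t nl = ii + nx * (jj + (size_t)ny * kk);
        if (!mask[nl] && admissible(ii, jj, kk)) {
          mask[nl] = true;
          queue.push_back(nl);
        }
      }
    } else {
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                kk >= nz)
              continue;
            size_t nl = ii + nx * (jj + (size_t)ny * kk);
            if (!mask[nl] && admissible(ii, jj, kk)) {
              mask[nl] = true;
              queue.push_back(nl);
            }
          }
    }
  }
  return mask;
}

// Connected-component labelling of a binary mask (6- or 26-connectivity).
// Components are numbered 1..n in discovery order (raster order of the
// first voxel), 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector &mask,
                                   const IntegerVector &dim, int conn) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      size_t lin = queue.back();
      queue.pop_back();
      int k = lin / ((size_t)nx * ny);
      int rem = lin - (size_t)k * nx * ny;
      int j = rem / nx, i = rem % nx;
      int lo = (conn == 6) ? 0 : -1;
      if (conn == 6) {
        for (int d = 0; d < 6; ++d) {
          int ii = i + OFF6[d][0], jj = j + OFF6[d][1], kk = k + OFF6[d][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          size_t nl = ii + nx * (jj + (size_t)ny * kk);
          if (mask[nl] && lab[nl] == 0) {
            lab[nl] = next;
            queue.push_back(nl);
          }
        }
      } else {
        (void)lo;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                  kk >= nz)
                continue;
              size_t nl = ii + nx * (jj + (size_t)ny * kk);
              if (mask[nl] && lab[nl] == 0) {
                lab[nl] = next;
                queue.push_back(nl);
              }
            }
      }
    }
  }
  return lab;
}

// Distance from every voxel centre (world mm) to a set of polyline
// segments, evaluated only within each segment's bounding box inflated
// by maxdist; voxels never visited keep +Inf. Used to voxelize tubes.
// dirmat is the 3x3 direction matrix in column-major order (orthonormal).
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(const IntegerVector &dim,
                                const NumericVector &spacing,
                                const NumericVector &origin,
                                const NumericVector &dirmat,
                                const NumericMatrix &segs, double maxdist) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector dist(n, R_PosInf);
  // direction matrix D (column-major), world = origin + D * (idx * spacing)
  double D[3][3];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) D[r][c] = dirmat[r + 3 * c];
  for (int s = 0; s < segs.nrow(); ++s) {
    double p0[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double p1[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    // index coords of endpoints: idx = D^T (x - origin) / spacing
    double i0[3], i1[3];
    for (int a = 0; a < 3; ++a) {
      double u0 = 0.0, u1 = 0.0;
      for (int r = 0; r < 3; ++r) {
        u0 += D[r][a] * (p0[r] - origin[r]);
        u1 += D[r][a] * (p1[r] - origin[r]);
      }
      i0[a] = u0 / spacing[a];
      i1[a] = u1 / spacing[a];
    }
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      double pad = maxdist / spacing[a] + 1.0;
      lo[a] = (int)std::floor(std::min(i0[a], i1[a]) - pad);
      hi[a] = (int)std::ceil(std::max(i0[a], i1[a]) + pad);
      if (lo[a] < 0) lo[a] = 0;
      int top = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1;
      if (hi[a] > top) hi[a] = top;
    }
    double d01[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double len2 = d01[0] * d01[0] + d01[1] * d01[1] + d01[2] * d01[2];
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double w[3];
          for (int r = 0; r < 3; ++r)
            w[r] = origin[r] + D[r][0] * i * spacing[0] +
                   D[r][1] * j * spacing[1] + D[r][2] * k * spacing[2];
          double t = 0.0;
          if (len2 > 0) {
            t = ((w[0] - p0[0]) * d01[0] + (w[1] - p0[1]) * d01[1] +
                 (w[2] - p0[2]) * d01[2]) /
                len2;
            if (t < 0) t = 0;
            if (t > 1) t = 1;
          }
          double dx = w[0] - (p0[0] + t * d01[0]);
          double dy = w[1] - (p0[1] + t * d01[1]);
          double dz = w[2] - (p0[2] + t * d01[2]);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          size_t lin = i + nx * (j + (size_t)ny * k);
          if (d < dist[lin]) dist[lin] = d;
        }
  }
  return dist;
}
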
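#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D volumes are stored as R arrays with dim = c(nz, ny, nx), column-major:
// linear index = iz + nz * (iy + ny * ix), all 0-based here.

static inline int lin(int iz, int iy, int ix, int nz, int ny) {
  return iz + nz * (iy + ny * ix);
}

//' 26-connected component labeling of a 3D mask
//'
//' @param mask logical vector of a 3D array (dim attribute read from `dim`)
//' @param dim integer vector (nz, ny, nx)
//' @param connectivity 6 or 26
//' @return integer vector of labels (0 = background), same length as mask
//' @keywords internal
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dim,
                                  int connectivity = 26) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nb = (int)dz.size();

  IntegerVector labels(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        R_xlen_t i = lin(iz, iy, ix, nz, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++current;
        labels[i] = current;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t j = stack.back(); stack.pop_back();
          int jz = (int)(j % nz);
          int rest = (int)(j / nz);
          int jy = rest % ny;
          int jx = rest / ny;
          for (int k = 0; k < nb; ++k) {
            int qz = jz + dz[k], qy = jy + dy[k], qx = jx + dx[k];
            if (qz < 0 || qz >= nz || qy < 0 || qy >= ny || qx < 0 || qx >= nx)
              continue;
            R_xlen_t q = lin(qz, qy, qx, nz, ny);
            if (mask[q] && labels[q] == 0) {
              labels[q] = current;
              stack.push_back(q);
            }
          }
        }
      }
  return labels;
}

//' Anisotropic chamfer distance transform of a 3D mask
//'
//' Two-pass chamfer approximation of the Euclidean distance (in micrometres)
//' from each foreground voxel to the nearest background voxel. Voxels on the
//' array boundary are treated as adjacent to background.
//'
//' @param mask logical vector of a 3D array
//' @param dim integer vector (nz, ny, nx)
//' @param spacing numeric vector (dz, dy, dx) in micrometres
//' @return numeric vector of distances, 0 outside the mask
//' @keywords internal
// [[Rcpp::export(name = ".chamfer_distance_3d")]]
NumericVector chamfer_distance_3d(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dim");
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double big = 1e30;

  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) dist[i] = mask[i] ? big : 0.0;

  // 26-neighbourhood split into causal halves (lexicographic order x, y, z)
  std::vector<int> dz, dy, dx; std::vector<double> w;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        // causal: earlier in scan order (ix, then iy, then iz)
        if (c < 0 || (c == 0 && (b < 0 || (b == 0 && a < 0)))) {
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
          w.push_back(std::sqrt(a * a * sz * sz + b * b * sy * sy + c * c * sx * sx));
        }
      }
  const int nb = (int)dz.size();
  const double edge_w = std::min(sz, std::min(sy, sx));

  // forward pass
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        R_xlen_t i = lin(iz, iy, ix, nz, ny);
        if (dist[i] == 0.0) continue;
        double best = dist[i];
        if (iz == 0 || iz == nz - 1 || iy == 0 || iy == ny - 1 ||
            ix == 0 || ix == nx - 1)
          best = std::min(best, edge_w);
        for (int k = 0; k < nb; ++k) {
          int qz = iz + dz[k], qy = iy + dy[k], qx = ix + dx[k];
          if (qz < 0 || qz >= nz || qy < 0 || qy >= ny || qx < 0 || qx >= nx)
            continue;
          double cand = dist[lin(qz, qy, qx, nz, ny)] + w[k];
          if (cand < best) best = cand;
        }
        dist[i] = best;
      }

  // backward pass (mirror neighbourhood)
  for (int ix = nx - 1; ix >= 0; --ix)
    for (int iy = ny - 1; iy >= 0; --iy)
      for (int iz = nz - 1; iz >= 0; --iz) {
        R_xlen_t i = lin(iz, iy, ix, nz, ny);
        if (dist[i] == 0.0) continue;
        double best = dist[i];
        for (int k = 0; k < nb; ++k) {
          int qz = iz - dz[k], qy = iy - dy[k], qx = ix - dx[k];
          if (qz < 0 || qz >= nz || qy < 0 || qy >= ny || qx < 0 || qx >= nx)
            continue;
          double cand = dist[lin(qz, qy, qx, nz, ny)] + w[k];
          if (cand < best) best = cand;
        }
        dist[i] = best;
      }

  return dist;
}
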
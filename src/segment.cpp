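// Low-level voxel routines for 3D segmentation.
// All arrays are in (z, y, x) order, z fastest (R column-major with dim =
// c(nz, ny, nx)), so linear index = z + nz*(y + ny*x), 0-based here.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t lin3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// Connected components under 26-connectivity. Labels are assigned in scan
// (raster) order of each component's first voxel, giving a deterministic
// contiguous labelling 1..N.
// [[Rcpp::export]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      R_xlen_t r = v / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t w = lin3(zz, yy, xx, nz, ny);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Local maxima under 26-connectivity: voxel value >= every neighbour value
// (neighbourhood clipped at the volume border). Plateaus yield multiple
// maxima; downstream thinning resolves them deterministically.
// [[Rcpp::export]]
LogicalVector local_max_26(NumericVector img, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img length does not match dims");
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin3(z, y, x, nz, ny);
        double v = img[i];
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              if (img[lin3(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        out[i] = ismax;
      }
  return out;
}

// Seeded watershed by priority flooding: seeds grow into 26-neighbour voxels
// of the same parent object, brightest (highest priority) front first.
// Ties are broken by insertion order, making the result deterministic.
// seed_idx is 1-based linear indices into the volume.
// [[Rcpp::export]]
IntegerVector seeded_watershed(NumericVector priority, IntegerVector parent,
                               IntegerVector seed_idx, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (priority.size() != n || parent.size() != n)
    stop("array length does not match dims");
  IntegerVector out(n, 0);
  typedef std::tuple<double, long long, R_xlen_t> Node;  // (prio, -order, idx)
  std::priority_queue<Node> pq;
  long long counter = 0;
  for (int k = 0; k < seed_idx.size(); ++k) {
    R_xlen_t i = (R_xlen_t)seed_idx[k] - 1;
    if (i < 0 || i >= n) stop("seed index out of range");
    if (parent[i] <= 0) stop("seed lies outside the foreground");
    if (out[i] != 0) stop("duplicate seed voxel");
    out[i] = k + 1;
    pq.push(Node(priority[i], -(counter++), i));
  }
  while (!pq.empty()) {
    R_xlen_t v = std::get<2>(pq.top());
    pq.pop();
    int z = (int)(v % nz);
    R_xlen_t r = v / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    int lab = out[v];
    int par = parent[v];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t w = lin3(zz, yy, xx, nz, ny);
          if (parent[w] == par && out[w] == 0) {
            out[w] = lab;
            pq.push(Node(priority[w], -(counter++), w));
          }
        }
  }
  return out;
}
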
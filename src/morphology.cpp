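// Grayscale erosion/dilation with a flat digital disk (dy^2 + dx^2 <= r^2),
// decomposed into column segments: a monotonic-deque sliding extreme along
// y within each column (contiguous in memory, O(1) amortized per pixel,
// independent of the radius), then an extreme across shifted columns.
// Windows are clipped at the image border, so a constant image is a fixed
// point of both operators.
#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// sliding extreme along y (down each column), half-width w, clipped
static void run_extreme_y(const double* m, int ny, int nx, int w,
                          bool take_max, double* out) {
  if (w == 0) {
    std::copy(m, m + (size_t)ny * nx, out);
    return;
  }
  std::deque<int> dq;
  for (int x = 0; x < nx; ++x) {
    const double* col = m + (size_t)x * ny;
    double* ocol = out + (size_t)x * ny;
    dq.clear();
    int right = 0;
    for (int y = 0; y < ny; ++y) {
      int hi = std::min(ny - 1, y + w);
      for (; right <= hi; ++right) {
        double v = col[right];
        while (!dq.empty() &&
               (take_max ? col[dq.back()] <= v : col[dq.back()] >= v))
          dq.pop_back();
        dq.push_back(right);
      }
      while (dq.front() < y - w) dq.pop_front();
      ocol[y] = col[dq.front()];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix disc_morph(NumericMatrix m, int r, bool dilate) {
  const int ny = m.nrow(), nx = m.ncol();
  const double pad = dilate ? R_NegInf : R_PosInf;
  NumericMatrix out(ny, nx);
  std::fill(out.begin(), out.end(), pad);
  std::vector<double> colf((size_t)ny * nx);
  const double* src = REAL(m);
  double* o = REAL(out);
  for (int dx = 0; dx <= r; ++dx) {
    int wy = (int)std::floor(std::sqrt((double)r * r - (double)dx * dx + 1e-9));
    run_extreme_y(src, ny, nx, wy, dilate, colf.data());
    for (int pass = 0; pass < (dx == 0 ? 1 : 2); ++pass) {
      int s = (pass == 0) ? dx : -dx;
      for (int x = 0; x < nx; ++x) {
        int sx = x + s;
        if (sx < 0 || sx >= nx) continue;
        const double* c = colf.data() + (size_t)sx * ny;
        double* oc = o + (size_t)x * ny;
        if (dilate) {
          for (int y = 0; y < ny; ++y)
            if (c[y] > oc[y]) oc[y] = c[y];
        } else {
          for (int y = 0; y < ny; ++y)
            if (c[y] < oc[y]) oc[y] = c[y];
        }
      }
    }
  }
  return out;
}
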
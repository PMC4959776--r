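#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Reflecting (mirror) boundary index: ..., 2, 1, 0 | 0, 1, 2, ...
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur, kernel radius ceil(3*sigma), reflect boundary.
static NumericMatrix gaussian_blur(const NumericMatrix& x, double sigma) {
  int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * x(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  // along columns (horizontal pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// Sobel gradients on the smoothed image; magnitude scaled by 1/4 so that a
// unit step edge yields magnitude <= 1 (thresholds live on this scale).
static void sobel(const NumericMatrix& x, NumericMatrix& gx, NumericMatrix& gy) {
  int nr = x.nrow(), nc = x.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int im = reflect(i - 1, nr), ip = reflect(i + 1, nr);
      int jm = reflect(j - 1, nc), jp = reflect(j + 1, nc);
      // gx: horizontal derivative (along columns), gy: vertical (along rows)
      gx(i, j) = (x(im, jp) + 2.0 * x(i, jp) + x(ip, jp)
                - x(im, jm) - 2.0 * x(i, jm) - x(ip, jm)) / 4.0;
      gy(i, j) = (x(ip, jm) + 2.0 * x(ip, j) + x(ip, jp)
                - x(im, jm) - 2.0 * x(im, j) - x(im, jp)) / 4.0;
    }
}

// Smoothed Sobel gradients and magnitude in one pass.
// [[Rcpp::export]]
List cpp_gradients(NumericMatrix img, double sigma) {
  NumericMatrix sm = gaussian_blur(img, sigma);
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc), mag(nr, nc);
  sobel(sm, gx, gy);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      mag(i, j) = std::sqrt(gx(i, j) * gx(i, j) + gy(i, j) * gy(i, j));
  return List::create(_["gx"] = gx, _["gy"] = gy, _["mag"] = mag);
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient_magnitude(NumericMatrix img, double sigma) {
  List g = cpp_gradients(img, sigma);
  return as<NumericMatrix>(g["mag"]);
}

// Non-maximum suppression with 4-sector direction quantization, then
// hysteresis by 8-connected BFS from strong pixels. Out-of-image neighbours
// count as zero magnitude during NMS.
// [[Rcpp::export]]
LogicalMatrix cpp_nms_hysteresis(NumericMatrix gx, NumericMatrix gy,
                                 NumericMatrix mag, double low, double high) {
  int nr = mag.nrow(), nc = mag.ncol();
  LogicalMatrix nms(nr, nc);
  const double pi = 3.14159265358979323846;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = mag(i, j);
      if (m <= 0.0) { nms(i, j) = false; continue; }
      double a = std::atan2(gy(i, j), gx(i, j));
      if (a < 0) a += pi;                       // direction mod pi
      int sector = (int)std::floor((a + pi / 8.0) / (pi / 4.0)) % 4;
      int di1, dj1, di2, dj2;
      switch (sector) {
        case 0: di1 = 0;  dj1 = 1;  di2 = 0;  dj2 = -1; break; // horiz gradient
        case 1: di1 = 1;  dj1 = 1;  di2 = -1; dj2 = -1; break; // diagonal
        case 2: di1 = 1;  dj1 = 0;  di2 = -1; dj2 = 0;  break; // vert gradient
        default: di1 = 1; dj1 = -1; di2 = -1; dj2 = 1;  break; // anti-diagonal
      }
      double n1 = 0.0, n2 = 0.0;
      int i1 = i + di1, j1 = j + dj1, i2 = i + di2, j2 = j + dj2;
      if (i1 >= 0 && i1 < nr && j1 >= 0 && j1 < nc) n1 = mag(i1, j1);
      if (i2 >= 0 && i2 < nr && j2 >= 0 && j2 < nc) n2 = mag(i2, j2);
      nms(i, j) = (m >= n1 && m >= n2);
    }

  LogicalMatrix edges(nr, nc);
  std::vector<char> weak((size_t)nr * nc, 0);
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!nms(i, j)) continue;
      double m = mag(i, j);
      if (m >= high) { edges(i, j) = true; q.push(i + j * nr); }
      else if (m >= low) weak[(size_t)i + (size_t)j * nr] = 1;
    }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int i = p % nr, j = p / nr;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        size_t idx = (size_t)ii + (size_t)jj * nr;
        if (weak[idx] && !edges(ii, jj)) { edges(ii, jj) = true; q.push(ii + jj * nr); }
      }
  }
  return edges;
}

// Full Canny with absolute hysteresis thresholds.
// [[Rcpp::export]]
LogicalMatrix cpp_canny(NumericMatrix img, double sigma, double low, double high) {
  List g = cpp_gradients(img, sigma);
  return cpp_nms_hysteresis(as<NumericMatrix>(g["gx"]), as<NumericMatrix>(g["gy"]),
                            as<NumericMatrix>(g["mag"]), low, high);
}
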
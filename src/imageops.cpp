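#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale erosion with a (possibly non-flat) structuring element.
// Offsets outside the image are ignored (treated as +Inf for erosion,
// -Inf for dilation), the usual convention for border handling.
// The loops run offset-outer over valid index rectangles so the inner
// loop is a straight contiguous min/max scan the compiler can vectorize;
// pixels near the border simply see fewer offsets, the usual "ignore
// outside" convention.
static NumericMatrix gray_morph(const NumericMatrix& img,
                                const IntegerVector& dr,
                                const IntegerVector& dc,
                                const NumericVector& h,
                                const bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), m = dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), erode ? R_PosInf : R_NegInf);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int k = 0; k < m; ++k) {
    const int orow = dr[k], ocol = dc[k];
    const double hk = erode ? -h[k] : h[k];
    const int c0 = std::max(0, -ocol), c1 = std::min(nc, nc - ocol);
    const int r0 = std::max(0, -orow), r1 = std::min(nr, nr - orow);
    for (int c = c0; c < c1; ++c) {
      const double* s = src + (size_t)(c + ocol) * nr + (r0 + orow);
      double* d = dst + (size_t)c * nr + r0;
      const int len = r1 - r0;
      if (erode) {
        for (int i = 0; i < len; ++i) {
          const double x = s[i] + hk;
          if (x < d[i]) d[i] = x;
        }
      } else {
        for (int i = 0; i < len; ++i) {
          const double x = s[i] + hk;
          if (x > d[i]) d[i] = x;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dr,
                             const IntegerVector& dc,
                             const NumericVector& h) {
  return gray_morph(img, dr, dc, h, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dr,
                              const IntegerVector& dc,
                              const NumericVector& h) {
  return gray_morph(img, dr, dc, h, false);
}

// Separable convolution (one 1-D pass along rows or columns) with
// reflect-101 border padding, matching the common image-filter default.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(const NumericMatrix& img,
                               const NumericVector& kernel,
                               const bool along_rows) {
  const int nr = img.nrow(), nc = img.ncol(), m = kernel.size();
  const int half = m / 2;
  NumericMatrix out(nr, nc);
  if (along_rows) {            // convolve down each column (varying row)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double s = 0.0;
        for (int k = 0; k < m; ++k)
          s += kernel[k] * img(reflect_idx(r + k - half, nr), c);
        out(r, c) = s;
      }
  } else {                     // convolve along each row (varying col)
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        double s = 0.0;
        for (int k = 0; k < m; ++k)
          s += kernel[k] * img(r, reflect_idx(c + k - half, nc));
        out(r, c) = s;
      }
  }
  return out;
}

// Connected-component labeling of a binary mask (BFS, labels 1..n in
// raster-scan discovery order).  connectivity = 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nnb; ++k) {
          const int rr = p.first + dr8[k], cc = p.second + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}

// Local maxima of a response image within a circular window of the given
// radius; only pixels with value >= threshold are candidates.  Plateau
// ties are broken toward the smallest (row, col) in column-major order so
// detection is deterministic.  Returns an n x 2 matrix of 0-based (row, col).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(const NumericMatrix& img,
                               const int radius,
                               const double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> mr, mc;
  const int r2 = radius * radius;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const double v = img(r, c);
      if (!(v >= threshold)) continue;
      bool is_max = true;
      for (int dc = -radius; dc <= radius && is_max; ++dc)
        for (int dr = -radius; dr <= radius; ++dr) {
          if (dr == 0 && dc == 0) continue;
          if (dr * dr + dc * dc > r2) continue;
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const double w = img(rr, cc);
          if (w > v || (w == v && (cc < c || (cc == c && rr < r)))) {
            is_max = false;
            break;
          }
        }
      if (is_max) { mr.push_back(r); mc.push_back(c); }
    }
  IntegerMatrix out(mr.size(), 2);
  for (size_t i = 0; i < mr.size(); ++i) {
    out(i, 0) = mr[i];
    out(i, 1) = mc[i];
  }
  return out;
}

// 3x3 median filter with reflect-101 borders.
// [[Rcpp::export]]
NumericMatrix cpp_median3(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double buf[9];
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          buf[k++] = img(reflect_idx(r + dr, nr), reflect_idx(c + dc, nc));
      std::nth_element(buf, buf + 4, buf + 9);
      out(r, c) = buf[4];
    }
  return out;
}
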
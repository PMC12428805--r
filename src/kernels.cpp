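#include <Rcpp.h>
using namespace Rcpp;

// reflect index into [0, n) (symmetric, edge pixel included once)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

//' Separable 2D correlation with reflected boundaries.
//'
//' Correlates along x (columns) with kx, then along y (rows) with ky.
//' Kernels are centered: length must be odd, tap j corresponds to offset
//' j - (length-1)/2.
//'
//' @keywords internal
// [[Rcpp::export(name = "cf_sep_correlate")]]
NumericMatrix cf_sep_correlate(const NumericMatrix& img,
                               const NumericVector& kx,
                               const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);

  // along columns (x direction)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) tmp(r, c) = 0.0;
  }
  for (int j = -rx; j <= rx; ++j) {
    const double w = kx[j + rx];
    if (w == 0.0) continue;
    for (int c = 0; c < nc; ++c) {
      const int cs = reflect_idx(c + j, nc);
      for (int r = 0; r < nr; ++r) tmp(r, c) += w * img(r, cs);
    }
  }
  // along rows (y direction)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) out(r, c) = 0.0;
  }
  for (int j = -ry; j <= ry; ++j) {
    const double w = ky[j + ry];
    if (w == 0.0) continue;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int rs = reflect_idx(r + j, nr);
        out(r, c) += w * tmp(rs, c);
      }
    }
  }
  return out;
}

//' Bilinear sampling of a matrix at fractional 0-based coordinates.
//'
//' X holds column coordinates, Y row coordinates (same shape as the output).
//' Coordinates are clamped to the image domain.
//'
//' @keywords internal
// [[Rcpp::export(name = "cf_bilinear")]]
NumericMatrix cf_bilinear(const NumericMatrix& img,
                          const NumericMatrix& X,
                          const NumericMatrix& Y) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = X.nrow(), onc = X.ncol();
  NumericMatrix out(onr, onc);
  for (int c = 0; c < onc; ++c) {
    for (int r = 0; r < onr; ++r) {
      double x = X(r, c), y = Y(r, c);
      if (x < 0) x = 0; else if (x > nc - 1) x = nc - 1;
      if (y < 0) y = 0; else if (y > nr - 1) y = nr - 1;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      if (x0 > nc - 2) x0 = nc - 2;
      if (y0 > nr - 2) y0 = nr - 2;
      if (x0 < 0) x0 = 0;
      if (y0 < 0) y0 = 0;
      const double fx = x - x0, fy = y - y0;
      const double v00 = img(y0, x0), v01 = img(y0, x0 + 1);
      const double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
      out(r, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}

//' Stamp filled discs onto a canvas (max blend), used by the stroke
//' rasterizer of the synthetic angiogram generator.
//'
//' @keywords internal
// [[Rcpp::export(name = "cf_stamp_discs")]]
NumericMatrix cf_stamp_discs(NumericMatrix canvas,
                             const NumericVector& xs,
                             const NumericVector& ys,
                             const double radius,
                             const double value) {
  const int nr = canvas.nrow(), nc = canvas.ncol();
  const int ri = (int)std::ceil(radius);
  const double r2 = radius * radius;
  for (int k = 0; k < xs.size(); ++k) {
    const int cx = (int)std::round(xs[k]);
    const int cy = (int)std::round(ys[k]);
    for (int dy = -ri; dy <= ri; ++dy) {
      const int y = cy + dy;
      if (y < 0 || y >= nr) continue;
      for (int dx = -ri; dx <= ri; ++dx) {
        const int x = cx + dx;
        if (x < 0 || x >= nc) continue;
        if (dx * dx + dy * dy <= r2 && canvas(y, x) < value)
          canvas(y, x) = value;
      }
    }
  }
  return canvas;
}
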
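#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Anti-aliased polyline rasterization of a trace onto a square master
// raster. Coordinates: x = sample index mapped to [0, res-1], y = current
// mapped so yLow -> bottom row, yHigh -> top row. Coverage accumulates and
// is clamped to [0, 1]; the line is high-valued on a zero background.

static inline void plot(arma::mat &img, int x, int y, double a) {
  int res = img.n_rows;
  if (x < 0 || x >= res || y < 0 || y >= res) return;
  double v = img(y, x) + a;
  img(y, x) = v > 1.0 ? 1.0 : v;
}

// Xiaolin Wu style anti-aliased segment
static void wuLine(arma::mat &img, double x0, double y0,
                   double x1, double y1) {
  bool steep = std::abs(y1 - y0) > std::abs(x1 - x0);
  if (steep) { std::swap(x0, y0); std::swap(x1, y1); }
  if (x0 > x1) { std::swap(x0, x1); std::swap(y0, y1); }
  double dx = x1 - x0, dy = y1 - y0;
  double gradient = (dx == 0.0) ? 1.0 : dy / dx;

  double xend = std::round(x0);
  double yend = y0 + gradient * (xend - x0);
  double xgap = 1.0 - (x0 + 0.5 - std::floor(x0 + 0.5));
  int xpxl1 = (int)xend;
  int ypxl1 = (int)std::floor(yend);
  double f = yend - std::floor(yend);
  if (steep) {
    plot(img, ypxl1, xpxl1, (1 - f) * xgap);
    plot(img, ypxl1 + 1, xpxl1, f * xgap);
  } else {
    plot(img, xpxl1, ypxl1, (1 - f) * xgap);
    plot(img, xpxl1, ypxl1 + 1, f * xgap);
  }
  double intery = yend + gradient;

  xend = std::round(x1);
  yend = y1 + gradient * (xend - x1);
  xgap = x1 + 0.5 - std::floor(x1 + 0.5);
  int xpxl2 = (int)xend;
  int ypxl2 = (int)std::floor(yend);
  f = yend - std::floor(yend);
  if (steep) {
    plot(img, ypxl2, xpxl2, (1 - f) * xgap);
    plot(img, ypxl2 + 1, xpxl2, f * xgap);
  } else {
    plot(img, xpxl2, ypxl2, (1 - f) * xgap);
    plot(img, xpxl2, ypxl2 + 1, f * xgap);
  }

  for (int x = xpxl1 + 1; x <= xpxl2 - 1; ++x) {
    double fi = intery - std::floor(intery);
    int yi = (int)std::floor(intery);
    if (steep) {
      plot(img, yi, x, 1 - fi);
      plot(img, yi + 1, x, fi);
    } else {
      plot(img, x, yi, 1 - fi);
      plot(img, x, yi + 1, fi);
    }
    intery += gradient;
  }
}

// [[Rcpp::export(name = ".raster_trace_cpp")]]
arma::mat raster_trace_cpp(const arma::vec &samples, int res,
                           double yLow, double yHigh) {
  arma::mat img(res, res, arma::fill::zeros); // row = y (0 = top), col = x
  int n = samples.n_elem;
  if (n < 1) return img;
  double xs = (n > 1) ? (double)(res - 1) / (n - 1) : 0.0;
  double ysc = (res - 1) / (yHigh - yLow);
  auto ymap = [&](double v) { return (yHigh - v) * ysc; };
  if (n == 1) {
    plot(img, 0, (int)std::floor(ymap(samples(0))), 1.0);
    return img;
  }
  for (int i = 0; i + 1 < n; ++i) {
    // wuLine works in (x, y); img is indexed (row=y, col=x) via plot's
    // (x, y) argument order below, so wrap with a col-major adapter.
    double x0 = i * xs, x1 = (i + 1) * xs;
    double y0 = ymap(samples(i)), y1 = ymap(samples(i + 1));
    // draw into transposed view: plot() expects (img, x=col, y=row)
    // our plot() signature is plot(img, x, y) with img(y, x)
    wuLine(img, x0, y0, x1, y1);
  }
  return img;
}
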
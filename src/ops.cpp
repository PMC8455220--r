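#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Window primitives share one border convention: the window is intersected
// with the image and statistics use the actual in-image count (no padding).

// [[Rcpp::export]]
NumericMatrix box_mean_cpp(const NumericMatrix& x, int r) {
  const int nr = x.nrow(), nc = x.ncol();
  // summed-area table, padded with a zero row/column
  std::vector<double> S((size_t)(nr + 1) * (nc + 1), 0.0);
  const size_t W = nc + 1;
  for (int i = 1; i <= nr; ++i) {
    double rs = 0.0;
    for (int j = 1; j <= nc; ++j) {
      rs += x(i - 1, j - 1);
      S[(size_t)i * W + j] = S[(size_t)(i - 1) * W + j] + rs;
    }
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    const int r0 = std::max(0, i - r), r1 = std::min(nr - 1, i + r);
    for (int j = 0; j < nc; ++j) {
      const int c0 = std::max(0, j - r), c1 = std::min(nc - 1, j + r);
      const double s = S[(size_t)(r1 + 1) * W + (c1 + 1)]
                     - S[(size_t)r0 * W + (c1 + 1)]
                     - S[(size_t)(r1 + 1) * W + c0]
                     + S[(size_t)r0 * W + c0];
      out(i, j) = s / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix window_median_cpp(const NumericMatrix& x, int r) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)(2 * r + 1) * (2 * r + 1));
  for (int i = 0; i < nr; ++i) {
    const int r0 = std::max(0, i - r), r1 = std::min(nr - 1, i + r);
    for (int j = 0; j < nc; ++j) {
      const int c0 = std::max(0, j - r), c1 = std::min(nc - 1, j + r);
      buf.clear();
      for (int jj = c0; jj <= c1; ++jj)
        for (int ii = r0; ii <= r1; ++ii)
          buf.push_back(x(ii, jj));
      const size_t n = buf.size();
      const size_t h = n / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (n % 2 == 0) {
        // average of the two middle order statistics
        double lo = *std::max_element(buf.begin(), buf.begin() + h);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  }
  return out;
}

static NumericMatrix morph_op(const NumericMatrix& x, const LogicalMatrix& se,
                              bool dilate) {
  const int nr = x.nrow(), nc = x.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int ci = (sh - 1) / 2, cj = (sw - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int sj = 0; sj < sw; ++sj) {
        const int jj = j + sj - cj;
        if (jj < 0 || jj >= nc) continue;
        for (int si = 0; si < sh; ++si) {
          if (!se(si, sj)) continue;
          const int ii = i + si - ci;
          if (ii < 0 || ii >= nr) continue;
          const double v = x(ii, jj);
          if (dilate) { if (v > best) best = v; }
          else        { if (v < best) best = v; }
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gray_dilate_cpp(const NumericMatrix& x, const LogicalMatrix& se) {
  return morph_op(x, se, true);
}

// [[Rcpp::export]]
NumericMatrix gray_erode_cpp(const NumericMatrix& x, const LogicalMatrix& se) {
  return morph_op(x, se, false);
}

// Geodesic reconstruction: iterate g <- min(dilate(g), mask) (dilation form)
// or g <- max(erode(g), mask) (erosion form) to the fixed point.  This is the
// literal iterative definition; the fixed point is unique so the stopping
// rule (sup-norm change <= tol, tol below any quantization step for integer
// valued images) returns the exact stable image.
// [[Rcpp::export]]
List geodesic_reconstruct_cpp(const NumericMatrix& marker,
                              const NumericMatrix& mask,
                              const LogicalMatrix& se,
                              bool dilation, double tol, int max_iter) {
  NumericMatrix g = clone(marker);
  const int nr = g.nrow(), nc = g.ncol();
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    NumericMatrix h = morph_op(g, se, dilation);
    double delta = 0.0;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double v = dilation ? std::min(h(i, j), mask(i, j))
                            : std::max(h(i, j), mask(i, j));
        double d = std::abs(v - g(i, j));
        if (d > delta) delta = d;
        g(i, j) = v;
      }
    }
    if (delta <= tol) break;
  }
  if (it > max_iter)
    stop("geodesic reconstruction did not reach a fixed point in %d iterations",
         max_iter);
  return List::create(_["image"] = g, _["iterations"] = it);
}
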
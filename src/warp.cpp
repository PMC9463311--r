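#include <Rcpp.h>
using namespace Rcpp;

// Inverse-mapped affine warp of an RGB image and its binary mask.
//
// The forward map takes 0-based continuous input coordinates p = (x, y) to
// A * (p - centroid) + offset in the output plane. RGB is sampled bilinearly,
// the mask by nearest neighbor. Pixel centers sit at (c - 0.5, r - 0.5) for
// 1-based matrix indices (r, c).
//
// Besides the clipped output frame, the warped mask's total (unclipped) pixel
// count is measured over the bounding box [bx0, bx1] x [by0, by1] of the
// warped support, so callers can apply the out-of-frame rule.
// [[Rcpp::export]]
List warp_asset_cpp(NumericVector rgb, LogicalMatrix mask,
                    NumericMatrix ainv, double cx, double cy,
                    double ox, double oy, int out_w, int out_h,
                    double bx0, double by0, double bx1, double by1) {
  IntegerVector dims = rgb.attr("dim");
  const int h = dims[0], w = dims[1];
  const double a11 = ainv(0, 0), a12 = ainv(0, 1);
  const double a21 = ainv(1, 0), a22 = ainv(1, 1);

  NumericVector out_rgb(out_h * out_w * 3);
  out_rgb.attr("dim") = IntegerVector::create(out_h, out_w, 3);
  LogicalMatrix out_mask(out_h, out_w);

  const int plane = h * w, out_plane = out_h * out_w;
  for (int c = 0; c < out_w; ++c) {
    const double x = c + 0.5;  // 0-based continuous center of column c+1
    for (int r = 0; r < out_h; ++r) {
      const double y = r + 0.5;
      const double xi = a11 * (x - ox) + a12 * (y - oy) + cx;
      const double yi = a21 * (x - ox) + a22 * (y - oy) + cy;
      // nearest-neighbor mask lookup
      const int cn = (int)std::floor(xi), rn = (int)std::floor(yi);
      bool inside = cn >= 0 && cn < w && rn >= 0 && rn < h;
      if (inside && mask(rn, cn)) {
        out_mask(r, c) = true;
        // bilinear RGB at (xi, yi): neighbor centers at integer+0.5
        double fx = xi - 0.5, fy = yi - 0.5;
        int c0 = (int)std::floor(fx), r0 = (int)std::floor(fy);
        double wx = fx - c0, wy = fy - r0;
        int c1 = c0 + 1, r1 = r0 + 1;
        c0 = std::min(std::max(c0, 0), w - 1);
        c1 = std::min(std::max(c1, 0), w - 1);
        r0 = std::min(std::max(r0, 0), h - 1);
        r1 = std::min(std::max(r1, 0), h - 1);
        for (int k = 0; k < 3; ++k) {
          const double *p = &rgb[k * plane];
          double v00 = p[r0 + h * c0], v01 = p[r0 + h * c1];
          double v10 = p[r1 + h * c0], v11 = p[r1 + h * c1];
          out_rgb[r + out_h * c + k * out_plane] =
              (1 - wy) * ((1 - wx) * v00 + wx * v01) +
              wy * ((1 - wx) * v10 + wx * v11);
        }
      }
    }
  }

  // unclipped warped pixel count over the warped-support bounding box
  long total = 0;
  const int cc0 = (int)std::floor(bx0), cc1 = (int)std::ceil(bx1);
  const int rr0 = (int)std::floor(by0), rr1 = (int)std::ceil(by1);
  for (int c = cc0; c <= cc1; ++c) {
    const double x = c + 0.5;
    for (int r = rr0; r <= rr1; ++r) {
      const double y = r + 0.5;
      const double xi = a11 * (x - ox) + a12 * (y - oy) + cx;
      const double yi = a21 * (x - ox) + a22 * (y - oy) + cy;
      const int cn = (int)std::floor(xi), rn = (int)std::floor(yi);
      if (cn >= 0 && cn < w && rn >= 0 && rn < h && mask(rn, cn)) ++total;
    }
  }

  return List::create(_["rgb"] = out_rgb, _["mask"] = out_mask,
                      _["total_px"] = (double)total);
}
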
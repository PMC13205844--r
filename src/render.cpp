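// In-place pixel operations for the face renderer. The canvas is three H x W
// numeric matrices held in a private environment; modifying them here avoids
// R's copy-on-complex-assignment, which dominates rendering cost otherwise.
#include <Rcpp.h>
using namespace Rcpp;

// Fill pixels with xl[row] <= x <= xr[row] (NA rows skipped); optional
// per-row shade multiplier on the color.
// [[Rcpp::export(name = ".fill_rowband_cpp")]]
void fill_rowband_cpp(NumericMatrix ch1, NumericMatrix ch2, NumericMatrix ch3,
                      NumericVector xl, NumericVector xr, NumericVector color,
                      NumericVector shade) {
  const int H = ch1.nrow(), W = ch1.ncol();
  const bool has_shade = shade.size() == H;
  for (int r = 0; r < H; ++r) {
    if (NumericVector::is_na(xl[r]) || NumericVector::is_na(xr[r])) continue;
    int c0 = std::max(0, (int)std::ceil(xl[r]));
    int c1 = std::min(W - 1, (int)std::floor(xr[r]));
    const double f = has_shade ? shade[r] : 1.0;
    for (int c = c0; c <= c1; ++c) {
      ch1(r, c) = color[0] * f;
      ch2(r, c) = color[1] * f;
      ch3(r, c) = color[2] * f;
    }
  }
}

// Recolor the part of the row band lying above a per-column boundary
// y < ytop[col].
// [[Rcpp::export(name = ".fill_above_cpp")]]
void fill_above_cpp(NumericMatrix ch1, NumericMatrix ch2, NumericMatrix ch3,
                    NumericVector xl, NumericVector xr, NumericVector ytop,
                    NumericVector color) {
  const int H = ch1.nrow(), W = ch1.ncol();
  for (int r = 0; r < H; ++r) {
    if (NumericVector::is_na(xl[r]) || NumericVector::is_na(xr[r])) continue;
    int c0 = std::max(0, (int)std::ceil(xl[r]));
    int c1 = std::min(W - 1, (int)std::floor(xr[r]));
    for (int c = c0; c <= c1; ++c) {
      if ((double)r < ytop[c]) {
        ch1(r, c) = color[0];
        ch2(r, c) = color[1];
        ch3(r, c) = color[2];
      }
    }
  }
}

// Alpha-blend a patch (alpha matrix anchored at 1-based r0, c0).
// [[Rcpp::export(name = ".blend_patch_cpp")]]
void blend_patch_cpp(NumericMatrix ch1, NumericMatrix ch2, NumericMatrix ch3,
                     int r0, int c0, NumericMatrix alpha,
                     NumericVector color) {
  const int H = ch1.nrow(), W = ch1.ncol();
  const int pr = alpha.nrow(), pc = alpha.ncol();
  for (int j = 0; j < pc; ++j) {
    const int c = c0 - 1 + j;
    if (c < 0 || c >= W) continue;
    for (int i = 0; i < pr; ++i) {
      const int r = r0 - 1 + i;
      if (r < 0 || r >= H) continue;
      const double a = alpha(i, j);
      if (a <= 0.0) continue;
      ch1(r, c) = ch1(r, c) * (1 - a) + color[0] * a;
      ch2(r, c) = ch2(r, c) * (1 - a) + color[1] * a;
      ch3(r, c) = ch3(r, c) * (1 - a) + color[2] * a;
    }
  }
}

// Round and clamp a numeric array to 8-bit raw.
// [[Rcpp::export(name = ".to_u8_cpp")]]
RawVector to_u8_cpp(NumericVector x) {
  RawVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = std::nearbyint(x[i]);
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    out[i] = (Rbyte)v;
  }
  return out;
}
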
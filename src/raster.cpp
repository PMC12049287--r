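#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic orthographic z-buffer rasteriser.  Vertices are given
// already in camera coordinates (x right, y up, z toward the viewer);
// window maps [xmin,xmax]x[ymin,ymax] to the pixel grid.  Colours are
// per-vertex RGB in [0,1], interpolated barycentrically, modulated by a
// Lambert factor from the camera-space face normal for depth cueing.
// [[Rcpp::export]]
NumericVector cpp_render_zbuffer(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix C, int width, int height,
                                 NumericVector window, NumericVector bg,
                                 double ambient) {
  const int nf = F.nrow();
  const double xmin = window[0], xmax = window[1], ymin = window[2], ymax = window[3];
  const double sx = width / (xmax - xmin), sy = height / (ymax - ymin);
  std::vector<double> zbuf((size_t)width * height, -1e300);
  NumericVector img((R_xlen_t)width * height * 3);
  for (int p = 0; p < width * height; p++) {
    img[p] = bg[0]; img[p + (R_xlen_t)width*height] = bg[1];
    img[p + 2*(R_xlen_t)width*height] = bg[2];
  }
  for (int t = 0; t < nf; t++) {
    int ia = F(t,0)-1, ib = F(t,1)-1, ic = F(t,2)-1;
    double ax = (V(ia,0)-xmin)*sx, ay = (ymax-V(ia,1))*sy, az = V(ia,2);
    double bx = (V(ib,0)-xmin)*sx, by = (ymax-V(ib,1))*sy, bz = V(ib,2);
    double cx = (V(ic,0)-xmin)*sx, cy = (ymax-V(ic,1))*sy, cz = V(ic,2);
    // camera-space normal z for Lambert shading (headlight)
    double ux = V(ib,0)-V(ia,0), uy = V(ib,1)-V(ia,1), uz = V(ib,2)-V(ia,2);
    double vx = V(ic,0)-V(ia,0), vy = V(ic,1)-V(ia,1), vz = V(ic,2)-V(ia,2);
    double nz = ux*vy - uy*vx;
    double nn = std::sqrt(std::pow(uy*vz-uz*vy,2)+std::pow(uz*vx-ux*vz,2)+nz*nz);
    double lam = nn > 0 ? std::fabs(nz)/nn : 1.0;
    double shade = ambient + (1.0 - ambient) * lam;

    double area = (bx-ax)*(cy-ay) - (by-ay)*(cx-ax);
    if (std::fabs(area) < 1e-12) continue;
    int x0 = std::max(0, (int)std::floor(std::min(ax, std::min(bx, cx))));
    int x1 = std::min(width-1, (int)std::ceil(std::max(ax, std::max(bx, cx))));
    int y0 = std::max(0, (int)std::floor(std::min(ay, std::min(by, cy))));
    int y1 = std::min(height-1, (int)std::ceil(std::max(ay, std::max(by, cy))));
    for (int py = y0; py <= y1; py++)
      for (int px = x0; px <= x1; px++) {
        double qx = px + 0.5, qy = py + 0.5;
        double w0 = ((bx-qx)*(cy-qy) - (by-qy)*(cx-qx)) / area;
        double w1 = ((cx-qx)*(ay-qy) - (cy-qy)*(ax-qx)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double z = w0*az + w1*bz + w2*cz;
        size_t pix = (size_t)px * height + py; // column-major [row=py, col=px]
        if (z <= zbuf[pix]) continue;
        zbuf[pix] = z;
        for (int ch = 0; ch < 3; ch++) {
          double col = (w0*C(ia,ch) + w1*C(ib,ch) + w2*C(ic,ch)) * shade;
          img[pix + (R_xlen_t)ch * width * height] = std::min(1.0, std::max(0.0, col));
        }
      }
  }
  img.attr("dim") = IntegerVector::create(height, width, 3);
  return img;
}
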
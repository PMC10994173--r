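#include <Rcpp.h>
using namespace Rcpp;

// Images are R matrices indexed [row, col] = [y, x]; coordinates below are
// (x, y) in 1-based pixel units so they line up with R code.

static inline double bilinear(const NumericMatrix& img, double x, double y,
                              double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  if (x < 1.0 || y < 1.0 || x > nx || y > ny) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 == nx) x0 = nx - 1;
  if (y0 == ny) y0 = ny - 1;
  const double fx = x - x0, fy = y - y0;
  const double v00 = img(y0 - 1, x0 - 1), v01 = img(y0 - 1, x0);
  const double v10 = img(y0, x0 - 1), v11 = img(y0, x0);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// Inverse-mapping warp: source (x,y) = M %*% (dest - c) + c + t, with c the
// image centre ((nx+1)/2, (ny+1)/2). M is 2x2 column-major (m11 m21 m12 m22).
// [[Rcpp::export(name = ".warp_affine_cpp")]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericVector M,
                              NumericVector t, double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  const double cx = (nx + 1) / 2.0, cy = (ny + 1) / 2.0;
  const double m11 = M[0], m21 = M[1], m12 = M[2], m22 = M[3];
  NumericMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    const double dx = (c + 1) - cx;
    for (int r = 0; r < ny; ++r) {
      const double dy = (r + 1) - cy;
      const double xs = m11 * dx + m12 * dy + cx + t[0];
      const double ys = m21 * dx + m22 * dy + cy + t[1];
      out(r, c) = bilinear(img, xs, ys, fill);
    }
  }
  return out;
}

// Parallel-beam ray-driven projector about the volume Y axis with a static
// X-tilt pre-rotation.  Volume is an R array dim (nx, ny, nz); the projection
// is an (nx, ny) matrix indexed [u, v] (detector x along volume x at 0 deg,
// v along the tilt axis).  Beam-frame point (u, v, t) maps to the sample
// frame through the transpose of R = Ry(alpha) * Rx(beta); rays are sampled
// at unit steps in t with trilinear interpolation, and back projection
// scatters with identical weights so the pair is an exact adjoint.

struct Geom {
  double r11, r12, r13, r21, r22, r23, r31, r32, r33;  // rows of R^T
};

static Geom make_geom(double alpha_deg, double beta_deg) {
  const double d2r = M_PI / 180.0;
  const double ca = std::cos(alpha_deg * d2r), sa = std::sin(alpha_deg * d2r);
  const double cb = std::cos(beta_deg * d2r), sb = std::sin(beta_deg * d2r);
  // R = Ry(a) Rx(b); sample point = R^T (u,v,t)
  // Ry = [ca 0 sa; 0 1 0; -sa 0 ca], Rx = [1 0 0; 0 cb -sb; 0 sb cb]
  // R  = [ca, sa*sb, sa*cb; 0, cb, -sb; -sa, ca*sb, ca*cb]
  Geom g;
  g.r11 = ca;      g.r12 = 0.0; g.r13 = -sa;
  g.r21 = sa * sb; g.r22 = cb;  g.r23 = ca * sb;
  g.r31 = sa * cb; g.r32 = -sb; g.r33 = ca * cb;
  return g;
}

// [[Rcpp::export(name = ".forward_project_cpp")]]
NumericMatrix forward_project_cpp(NumericVector vol, IntegerVector dims,
                                  double alpha_deg, double beta_deg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const Geom g = make_geom(alpha_deg, beta_deg);
  const int T = (int)std::ceil(0.5 * std::sqrt((double)nx * nx +
                                               (double)ny * ny +
                                               (double)nz * nz));
  NumericMatrix out(nx, ny);
  const double* v = vol.begin();
  for (int iv = 0; iv < ny; ++iv) {
    const double vv = iv - cy;
    for (int iu = 0; iu < nx; ++iu) {
      const double uu = iu - cx;
      double acc = 0.0;
      for (int it = -T; it <= T; ++it) {
        const double tt = it;
        const double x = g.r11 * uu + g.r12 * vv + g.r13 * tt + cx;
        const double y = g.r21 * uu + g.r22 * vv + g.r23 * tt + cy;
        const double z = g.r31 * uu + g.r32 * vv + g.r33 * tt + cz;
        if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
          continue;
        int x0 = (int)x, y0 = (int)y, z0 = (int)z;
        if (x0 == nx - 1) x0--;
        if (y0 == ny - 1) y0--;
        if (z0 == nz - 1) z0--;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        const size_t b000 = (size_t)x0 + (size_t)nx * (y0 + (size_t)ny * z0);
        const size_t b001 = b000 + (size_t)nx * ny;
        acc += (1 - fz) * ((1 - fy) * ((1 - fx) * v[b000] + fx * v[b000 + 1]) +
                           fy * ((1 - fx) * v[b000 + nx] + fx * v[b000 + nx + 1])) +
               fz * ((1 - fy) * ((1 - fx) * v[b001] + fx * v[b001 + 1]) +
                     fy * ((1 - fx) * v[b001 + nx] + fx * v[b001 + nx + 1]));
      }
      out(iu, iv) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".back_project_cpp")]]
NumericVector back_project_cpp(NumericMatrix proj, IntegerVector dims,
                               double alpha_deg, double beta_deg) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  const Geom g = make_geom(alpha_deg, beta_deg);
  const int T = (int)std::ceil(0.5 * std::sqrt((double)nx * nx +
                                               (double)ny * ny +
                                               (double)nz * nz));
  NumericVector vol((R_xlen_t)nx * ny * nz);
  double* v = vol.begin();
  for (int iv = 0; iv < ny; ++iv) {
    const double vv = iv - cy;
    for (int iu = 0; iu < nx; ++iu) {
      const double p = proj(iu, iv);
      if (p == 0.0) continue;
      const double uu = iu - cx;
      for (int it = -T; it <= T; ++it) {
        const double tt = it;
        const double x = g.r11 * uu + g.r12 * vv + g.r13 * tt + cx;
        const double y = g.r21 * uu + g.r22 * vv + g.r23 * tt + cy;
        const double z = g.r31 * uu + g.r32 * vv + g.r33 * tt + cz;
        if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
          continue;
        int x0 = (int)x, y0 = (int)y, z0 = (int)z;
        if (x0 == nx - 1) x0--;
        if (y0 == ny - 1) y0--;
        if (z0 == nz - 1) z0--;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        const size_t b000 = (size_t)x0 + (size_t)nx * (y0 + (size_t)ny * z0);
        const size_t b001 = b000 + (size_t)nx * ny;
        v[b000] += p * (1 - fz) * (1 - fy) * (1 - fx);
        v[b000 + 1] += p * (1 - fz) * (1 - fy) * fx;
        v[b000 + nx] += p * (1 - fz) * fy * (1 - fx);
        v[b000 + nx + 1] += p * (1 - fz) * fy * fx;
        v[b001] += p * fz * (1 - fy) * (1 - fx);
        v[b001 + 1] += p * fz * (1 - fy) * fx;
        v[b001 + nx] += p * fz * fy * (1 - fx);
        v[b001 + nx + 1] += p * fz * fy * fx;
      }
    }
  }
  vol.attr("dim") = dims;
  return vol;
}
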
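#include <Rcpp.h>
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared conventions (must match R/volume.R):
//   * volumes are column-major arrays with dim (nz, ny, nx)
//   * world coordinate of 0-based voxel index i (per axis): origin + i * spacing
//   * 2D feature maps / patches are arrays with dim (H, W, C)
// ---------------------------------------------------------------------------

static inline int idx3(int iz, int iy, int ix, int nz, int ny) {
  return iz + nz * (iy + (R_xlen_t)ny * ix);
}

// --------------------------- conv2d ----------------------------------------
// x: (H, W, Cin); w: (kh, kw, Cin, Cout); b: length Cout.
// Zero padding `pad`, stride `stride`.

// im2col: col is (N x K) with N = Ho*Wo patch positions and
// K = kh*kw*Cin unrolled offsets, matching the column-major flattening of
// the (kh, kw, Cin, Cout) weight array so conv becomes one dgemm.
static void im2col(const double *px, int H, int W, int Cin, int kh, int kw,
                   int stride, int pad, int Ho, int Wo, double *col) {
  const int N = Ho * Wo;
  std::fill(col, col + (size_t)N * kh * kw * Cin, 0.0);
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = px + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double *cc = col + (size_t)N * (ki + kh * (kj + kw * ci));
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double *xcol = xc + (size_t)H * j;
          double *cdst = cc + (size_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i >= 0 && i < H) cdst[io] = xcol[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int N = Ho * Wo, K = kh * kw * Cin;
  NumericVector y((R_xlen_t)N * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  std::vector<double> col((size_t)N * K);
  im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, col.data());
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &N, const_cast<int *>(&Cout), const_cast<int *>(&K),
                  &one, col.data(), &N, w.begin(), const_cast<int *>(&K),
                  &zero, y.begin(), &N FCONE FCONE);
  double *py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    const double bc = b[co];
    for (int n = 0; n < N; ++n) py[(size_t)N * co + n] += bc;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  const int N = Ho * Wo, K = kh * kw * Cin;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  std::vector<double> col((size_t)N * K), gcol((size_t)N * K);
  im2col(x.begin(), H, W, Cin, kh, kw, stride, pad, Ho, Wo, col.data());
  const double one = 1.0, zero = 0.0;
  // gW (K x Cout) = col^T (K x N) . gy (N x Cout)
  F77_CALL(dgemm)("T", "N", const_cast<int *>(&K), const_cast<int *>(&Cout),
                  const_cast<int *>(&N), &one, col.data(),
                  const_cast<int *>(&N), gy.begin(), const_cast<int *>(&N),
                  &zero, gw.begin(), const_cast<int *>(&K) FCONE FCONE);
  // gcol (N x K) = gy (N x Cout) . W^T (Cout x K)
  F77_CALL(dgemm)("N", "T", const_cast<int *>(&N), const_cast<int *>(&K),
                  const_cast<int *>(&Cout), &one, gy.begin(),
                  const_cast<int *>(&N), w.begin(), const_cast<int *>(&K),
                  &zero, gcol.data(), const_cast<int *>(&N) FCONE FCONE);
  // col2im scatter-add
  double *pgx = gx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    double *xc = pgx + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double *cc = gcol.data() + (size_t)N * (ki + kh * (kj + kw * ci));
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double *xcol = xc + (size_t)H * j;
          const double *csrc = cc + (size_t)Ho * jo;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * stride - pad + ki;
            if (i >= 0 && i < H) xcol[i] += csrc[io];
          }
        }
      }
    }
  }
  const double *pg = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    for (int n = 0; n < N; ++n) acc += pg[(size_t)N * co + n];
    gb[co] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// --------------------------- trilinear sampling -----------------------------

static inline double sample_tri(const double *v, int nz, int ny, int nx,
                                double fz, double fy, double fx) {
  // clamp-to-edge trilinear interpolation at fractional 0-based index
  if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
  if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
  if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
  int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
  int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
      x1 = std::min(x0 + 1, nx - 1);
  double tz = fz - z0, ty = fy - y0, tx = fx - x0;
  double c00 = v[idx3(z0, y0, x0, nz, ny)] * (1 - tz) + v[idx3(z1, y0, x0, nz, ny)] * tz;
  double c10 = v[idx3(z0, y1, x0, nz, ny)] * (1 - tz) + v[idx3(z1, y1, x0, nz, ny)] * tz;
  double c01 = v[idx3(z0, y0, x1, nz, ny)] * (1 - tz) + v[idx3(z1, y0, x1, nz, ny)] * tz;
  double c11 = v[idx3(z0, y1, x1, nz, ny)] * (1 - tz) + v[idx3(z1, y1, x1, nz, ny)] * tz;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tx) + c1 * tx;
}

// Resample src (with its own geometry) onto a target geometry.
// Returns values plus a validity mask (target centers inside source extent).
// [[Rcpp::export(name = ".resample_tri")]]
List resample_tri(NumericVector src, NumericVector src_origin,
                  NumericVector src_spacing, IntegerVector tgt_dim,
                  NumericVector tgt_origin, NumericVector tgt_spacing) {
  IntegerVector sd = src.attr("dim");
  const int nz = sd[0], ny = sd[1], nx = sd[2];
  const int mz = tgt_dim[0], my = tgt_dim[1], mx = tgt_dim[2];
  NumericVector out(mz * (R_xlen_t)my * mx);
  LogicalVector valid(out.size());
  out.attr("dim") = tgt_dim;
  valid.attr("dim") = tgt_dim;
  const double *pv = src.begin();
  const double eps = 1e-9;
  R_xlen_t k = 0;
  for (int ix = 0; ix < mx; ++ix)
    for (int iy = 0; iy < my; ++iy)
      for (int iz = 0; iz < mz; ++iz, ++k) {
        double wz = tgt_origin[0] + iz * tgt_spacing[0];
        double wy = tgt_origin[1] + iy * tgt_spacing[1];
        double wx = tgt_origin[2] + ix * tgt_spacing[2];
        double fz = (wz - src_origin[0]) / src_spacing[0];
        double fy = (wy - src_origin[1]) / src_spacing[1];
        double fx = (wx - src_origin[2]) / src_spacing[2];
        // column-major target order matches loop nesting (iz fastest)
        R_xlen_t oi = iz + mz * (iy + (R_xlen_t)my * ix);
        out[oi] = sample_tri(pv, nz, ny, nx, fz, fy, fx);
        valid[oi] = (fz >= -eps && fz <= nz - 1 + eps &&
                     fy >= -eps && fy <= ny - 1 + eps &&
                     fx >= -eps && fx <= nx - 1 + eps);
      }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Inverse-warp a volume by a displacement field given in mm (same grid):
// out(i) = vol(i - disp(i)/spacing). order: 0 nearest, 1 trilinear.
// [[Rcpp::export(name = ".warp_vol")]]
NumericVector warp_vol(NumericVector vol, NumericVector dz, NumericVector dy,
                       NumericVector dx, NumericVector spacing, int order) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  NumericVector out(vol.size());
  out.attr("dim") = d;
  const double *pv = vol.begin();
  R_xlen_t k = 0;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz, ++k) {
        R_xlen_t i = iz + nz * (iy + (R_xlen_t)ny * ix);
        double fz = iz - dz[i] / spacing[0];
        double fy = iy - dy[i] / spacing[1];
        double fx = ix - dx[i] / spacing[2];
        if (order == 0) {
          int z0 = (int)std::lround(fz), y0 = (int)std::lround(fy),
              x0 = (int)std::lround(fx);
          z0 = std::max(0, std::min(nz - 1, z0));
          y0 = std::max(0, std::min(ny - 1, y0));
          x0 = std::max(0, std::min(nx - 1, x0));
          out[i] = pv[idx3(z0, y0, x0, nz, ny)];
        } else {
          out[i] = sample_tri(pv, nz, ny, nx, fz, fy, fx);
        }
      }
  return out;
}

// In-plane (y,x) separable Gaussian blur, reflect padding.
// [[Rcpp::export(name = ".blur_inplane")]]
NumericVector blur_inplane(NumericVector vol, double sigma_y, double sigma_x) {
  IntegerVector d = vol.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  NumericVector tmp(clone(vol)), out(vol.size());
  out.attr("dim") = d;
  auto kernel = [](double s) {
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (auto &v : k) v /= sum;
    return k;
  };
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  if (sigma_y > 0) {
    std::vector<double> ky = kernel(sigma_y);
    int r = ((int)ky.size() - 1) / 2;
    NumericVector src = clone(tmp);
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          double acc = 0;
          for (int o = -r; o <= r; ++o)
            acc += ky[o + r] * src[idx3(iz, reflect(iy + o, ny), ix, nz, ny)];
          tmp[idx3(iz, iy, ix, nz, ny)] = acc;
        }
  }
  if (sigma_x > 0) {
    std::vector<double> kx = kernel(sigma_x);
    int r = ((int)kx.size() - 1) / 2;
    NumericVector src = clone(tmp);
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          double acc = 0;
          for (int o = -r; o <= r; ++o)
            acc += kx[o + r] * src[idx3(iz, iy, reflect(ix + o, nx), nz, ny)];
          tmp[idx3(iz, iy, ix, nz, ny)] = acc;
        }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = tmp[i];
  return out;
}

// --------------------------- ray tracing ------------------------------------

// Clip ray P(t) = S + t*dir against the volume's bounding box (voxel-center
// extent padded by half a voxel). Returns false if no intersection.
static bool ray_box(const double S[3], const double dir[3],
                    const double lo[3], const double hi[3],
                    double &t0, double &t1) {
  t0 = 0.0; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (S[a] < lo[a] || S[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - S[a]) / dir[a], tb = (hi[a] - S[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
      if (t0 > t1) return false;
    }
  }
  return true;
}

static double radio_depth_one(const double *ed, int nz, int ny, int nx,
                              const double origin[3], const double spacing[3],
                              const double S[3], const double P[3],
                              double step) {
  double dir[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
  double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
  if (L < 1e-9) return 0.0;
  for (int a = 0; a < 3; ++a) dir[a] /= L;
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    int n = (a == 0 ? nz : (a == 1 ? ny : nx));
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (n - 0.5) * spacing[a];
  }
  double t0, t1;
  if (!ray_box(S, dir, lo, hi, t0, t1)) return 0.0;
  t1 = std::min(t1, L);          // integrate only up to the target point
  if (t1 <= t0) return 0.0;
  int nstep = std::max(1, (int)std::ceil((t1 - t0) / step));
  double ds = (t1 - t0) / nstep, acc = 0.0;
  for (int s = 0; s < nstep; ++s) {
    double t = t0 + (s + 0.5) * ds;
    double fz = (S[0] + t * dir[0] - origin[0]) / spacing[0];
    double fy = (S[1] + t * dir[1] - origin[1]) / spacing[1];
    double fx = (S[2] + t * dir[2] - origin[2]) / spacing[2];
    acc += sample_tri(ed, nz, ny, nx, fz, fy, fx) * ds;
  }
  return acc;
}

// Water-equivalent depth from one source to each row of `targets` (world mm,
// columns z,y,x).
// [[Rcpp::export(name = ".radio_depth")]]
NumericVector radio_depth(NumericVector ed, NumericVector origin,
                          NumericVector spacing, NumericVector source,
                          NumericMatrix targets, double step) {
  IntegerVector d = ed.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  double S[3] = {source[0], source[1], source[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double spc[3] = {spacing[0], spacing[1], spacing[2]};
  NumericVector out(targets.nrow());
  for (int i = 0; i < targets.nrow(); ++i) {
    double P[3] = {targets(i, 0), targets(i, 1), targets(i, 2)};
    out[i] = radio_depth_one(ed.begin(), nz, ny, nx, org, spc, S, P, step);
  }
  return out;
}

// Divergent-beam exponential-attenuation dose for one beam; accumulates into
// `dose` in place semantics via returned copy.
// beam geometry: source S, unit axis toward isocenter, SAD, field half-sizes
// defined at the isocenter plane (lat = in axial plane, z = along z).
// [[Rcpp::export(name = ".beam_dose")]]
NumericVector beam_dose(NumericVector ed, NumericVector origin,
                        NumericVector spacing, NumericVector source,
                        NumericVector iso, double half_lat, double half_z,
                        double weight, double mu, double step) {
  IntegerVector d = ed.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  double S[3] = {source[0], source[1], source[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double spc[3] = {spacing[0], spacing[1], spacing[2]};
  double axis[3] = {iso[0] - S[0], iso[1] - S[1], iso[2] - S[2]};
  double SAD = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  for (int a = 0; a < 3; ++a) axis[a] /= SAD;
  // lateral unit vector: axis x e_z, expressed in (z,y,x) ordering; for an
  // axis confined to the (y,x) plane this is the in-plane perpendicular.
  double lat[3] = {0.0, -axis[2], axis[1]};
  double ln = std::sqrt(lat[1] * lat[1] + lat[2] * lat[2]);
  if (ln < 1e-12) { lat[1] = 1.0; lat[2] = 0.0; ln = 1.0; }
  lat[1] /= ln; lat[2] /= ln;
  NumericVector dose(ed.size());
  dose.attr("dim") = d;
  const double *pe = ed.begin();
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        double P[3] = {org[0] + iz * spc[0], org[1] + iy * spc[1],
                       org[2] + ix * spc[2]};
        double v[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        double t = v[0] * axis[0] + v[1] * axis[1] + v[2] * axis[2];
        if (t <= 1e-6) continue;
        double scale = SAD / t;  // project lateral offsets to the iso plane
        double off_lat = (v[0] * lat[0] + v[1] * lat[1] + v[2] * lat[2]) * scale;
        // residual z component: v_z - t*axis_z (axis has no z for gantry beams)
        double off_z = (v[0] - t * axis[0]) * scale;
        if (std::fabs(off_lat) > half_lat || std::fabs(off_z) > half_z) continue;
        double drad = radio_depth_one(pe, nz, ny, nx, org, spc, S, P, step);
        dose[idx3(iz, iy, ix, nz, ny)] = weight * std::exp(-mu * drad);
      }
  return dose;
}

// --------------------------- gamma index ------------------------------------

// Gamma of `ev` vs `ref` on a shared grid. Candidate positions form a global
// lattice refining the grid by integer factors (kz,ky,kx); evaluated dose is
// trilinearly interpolated there. Search restricted to |dr| <= radius_mm,
// which is exact as long as radius_mm >= cap * dta (distance term alone then
// exceeds the cap). NA where below threshold or invalid.
// [[Rcpp::export(name = ".gamma_search")]]
NumericVector gamma_search(NumericVector ref, NumericVector ev,
                           LogicalVector valid, NumericVector spacing,
                           double dd_abs, double dta, double thresh_abs,
                           double radius_mm, double cap,
                           IntegerVector kfac) {
  IntegerVector d = ref.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const int kz = kfac[0], ky = kfac[1], kx = kfac[2];
  const double sz = spacing[0] / kz, sy = spacing[1] / ky, sx = spacing[2] / kx;
  const int Nz = (nz - 1) * kz + 1, Ny = (ny - 1) * ky + 1, Nx = (nx - 1) * kx + 1;
  const int rz = (nz > 1) ? (int)std::ceil(radius_mm / sz) : 0;
  const int ry = (ny > 1) ? (int)std::ceil(radius_mm / sy) : 0;
  const int rx = (nx > 1) ? (int)std::ceil(radius_mm / sx) : 0;
  NumericVector out(ref.size());
  out.attr("dim") = d;
  const double *pr = ref.begin(), *pv = ev.begin();
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs, cap2 = cap * cap;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        R_xlen_t i = iz + nz * (iy + (R_xlen_t)ny * ix);
        if (!valid[i] || pr[i] < thresh_abs) { out[i] = NA_REAL; continue; }
        double Dr = pr[i];
        double best = cap2;
        int cz = iz * kz, cy = iy * ky, cx = ix * kx;
        for (int oz = -rz; oz <= rz; ++oz) {
          int z = cz + oz; if (z < 0 || z >= Nz) continue;
          double dz = oz * sz, dz2 = dz * dz;
          if (dz2 / dta2 >= best) continue;
          for (int oy = -ry; oy <= ry; ++oy) {
            int y = cy + oy; if (y < 0 || y >= Ny) continue;
            double dy = oy * sy, dzy = dz2 + dy * dy;
            if (dzy / dta2 >= best) continue;
            for (int ox = -rx; ox <= rx; ++ox) {
              int x = cx + ox; if (x < 0 || x >= Nx) continue;
              double dxm = ox * sx;
              double dist2 = dzy + dxm * dxm;
              double gd = dist2 / dta2;
              if (gd >= best) continue;
              double De = sample_tri(pv, nz, ny, nx,
                                     (double)z / kz, (double)y / ky,
                                     (double)x / kx);
              double dd = De - Dr;
              double g2 = gd + dd * dd / dd2;
              if (g2 < best) best = g2;
            }
          }
        }
        out[i] = std::sqrt(best);
        if (out[i] > cap) out[i] = cap;
      }
  return out;
}
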
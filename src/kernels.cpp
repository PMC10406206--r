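#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared low-level grids: volumes are 3D double arrays in R's column-major
// layout, displacement/gradient stacks are (nx,ny,nz,3). World coordinates
// follow the cell-centered convention world = origin + index * spacing with
// 0-based indices.

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear (or nearest-neighbour) sampling of a volume at arbitrary world
// points with clamp-to-edge extension. Optionally returns the derivative of
// the interpolant with respect to the world coordinates; the derivative is
// zero along axes where the query point lies outside the grid, matching the
// constant (clamped) extension.
// [[Rcpp::export]]
List c_interp_points(NumericVector vol, IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericMatrix pts, bool nearest,
                     bool want_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  NumericMatrix grad(want_grad ? np : 0, want_grad ? 3 : 0);

  for (R_xlen_t p = 0; p < np; ++p) {
    double c[3];
    bool inside[3];
    for (int a = 0; a < 3; ++a) {
      double ca = (pts(p, a) - origin[a]) / spacing[a];
      double hi = (double)dim[a] - 1.0;
      inside[a] = (ca >= 0.0 && ca <= hi);
      if (ca < 0.0) ca = 0.0;
      if (ca > hi) ca = hi;
      c[a] = ca;
    }
    if (nearest) {
      int i = (int)std::lround(c[0]);
      int j = (int)std::lround(c[1]);
      int k = (int)std::lround(c[2]);
      out[p] = vol[vidx(i, j, k, nx, ny)];
      continue;
    }
    int i0 = (int)std::floor(c[0]); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(c[1]); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    int k0 = (int)std::floor(c[2]); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = c[0] - i0, fy = c[1] - j0, fz = c[2] - k0;

    double v000 = vol[vidx(i0,     j0,     k0,     nx, ny)];
    double v100 = vol[vidx(i0 + 1, j0,     k0,     nx, ny)];
    double v010 = vol[vidx(i0,     j0 + 1, k0,     nx, ny)];
    double v110 = vol[vidx(i0 + 1, j0 + 1, k0,     nx, ny)];
    double v001 = vol[vidx(i0,     j0,     k0 + 1, nx, ny)];
    double v101 = vol[vidx(i0 + 1, j0,     k0 + 1, nx, ny)];
    double v011 = vol[vidx(i0,     j0 + 1, k0 + 1, nx, ny)];
    double v111 = vol[vidx(i0 + 1, j0 + 1, k0 + 1, nx, ny)];

    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;

    if (want_grad) {
      // d/dx: difference of the bilinear interpolants on the two x-faces
      double dx00 = v100 - v000, dx10 = v110 - v010;
      double dx01 = v101 - v001, dx11 = v111 - v011;
      double gx = ((dx00 * (1 - fy) + dx10 * fy) * (1 - fz) +
                   (dx01 * (1 - fy) + dx11 * fy) * fz) / spacing[0];
      double dy0 = c10 - c00, dy1 = c11 - c01;
      double gy = (dy0 * (1 - fz) + dy1 * fz) / spacing[1];
      double gz = (c1 - c0) / spacing[2];
      grad(p, 0) = inside[0] ? gx : 0.0;
      grad(p, 1) = inside[1] ? gy : 0.0;
      grad(p, 2) = inside[2] ? gz : 0.0;
    }
  }
  if (want_grad) return List::create(_["values"] = out, _["grad"] = grad);
  return List::create(_["values"] = out);
}

// Spacing-aware finite-difference gradient: central differences in the
// interior, one-sided on the boundary faces. Returns an (nx*ny*nz, 3) block
// laid out as three stacked volumes.
// [[Rcpp::export]]
NumericVector c_spatial_gradient(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n * 3);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int a = 0; a < 3; ++a) {
    const double h = spacing[a];
    const R_xlen_t s = stride[a];
    NumericVector::iterator g = out.begin() + a * n;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = vidx(i, j, k, nx, ny);
          int ia = (a == 0) ? i : (a == 1) ? j : k;
          if (nn[a] == 1) { g[id] = 0.0; continue; }
          if (ia == 0)               g[id] = (vol[id + s] - vol[id]) / h;
          else if (ia == nn[a] - 1)  g[id] = (vol[id] - vol[id - s]) / h;
          else                       g[id] = (vol[id + s] - vol[id - s]) / (2.0 * h);
        }
  }
  return out;
}

// Adjoint of c_spatial_gradient: maps per-voxel gradient weights (n, 3)
// back to a scalar volume, so that sum(w * grad(v)) == sum(adjoint(w) * v).
// [[Rcpp::export]]
NumericVector c_gradient_adjoint(NumericVector w, IntegerVector dim,
                                 NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int a = 0; a < 3; ++a) {
    const double h = spacing[a];
    const R_xlen_t s = stride[a];
    NumericVector::const_iterator wa = w.begin() + a * n;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = vidx(i, j, k, nx, ny);
          int ia = (a == 0) ? i : (a == 1) ? j : k;
          if (nn[a] == 1) continue;
          if (ia == 0) {
            out[id]     -= wa[id] / h;
            out[id + s] += wa[id] / h;
          } else if (ia == nn[a] - 1) {
            out[id]     += wa[id] / h;
            out[id - s] -= wa[id] / h;
          } else {
            out[id + s] += wa[id] / (2.0 * h);
            out[id - s] -= wa[id] / (2.0 * h);
          }
        }
  }
  return out;
}

// 7-point discrete Laplacian with a "natural" boundary: along each axis the
// second difference is only formed at interior points, so any affine field
// has exactly zero Laplacian everywhere. `adjoint` applies the transpose.
// [[Rcpp::export]]
NumericVector c_laplacian(NumericVector vol, IntegerVector dim,
                          NumericVector spacing, bool adjoint) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int a = 0; a < 3; ++a) {
    const double ih2 = 1.0 / (spacing[a] * spacing[a]);
    const R_xlen_t s = stride[a];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int ia = (a == 0) ? i : (a == 1) ? j : k;
          if (ia == 0 || ia == nn[a] - 1) continue;
          R_xlen_t id = vidx(i, j, k, nx, ny);
          if (!adjoint) {
            out[id] += (vol[id - s] - 2.0 * vol[id] + vol[id + s]) * ih2;
          } else {
            out[id - s] += vol[id] * ih2;
            out[id]     -= 2.0 * vol[id] * ih2;
            out[id + s] += vol[id] * ih2;
          }
        }
  }
  return out;
}

// 2x2x2 average pooling; every edge must be even.
// [[Rcpp::export]]
NumericVector c_restrict_volume(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector out((R_xlen_t)mx * my * mz);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double sum = 0.0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              sum += vol[vidx(2 * i + di, 2 * j + dj, 2 * k + dk, nx, ny)];
        out[(R_xlen_t)i + (R_xlen_t)mx * ((R_xlen_t)j + (R_xlen_t)my * k)] = sum / 8.0;
      }
  return out;
}

// Fused masked-NGF objective: warps the template, forms the warped image's
// finite-difference gradient, evaluates the NGF integrand against the
// precomputed reference gradient, and chains the derivative back through
// the stencils and the trilinear warp. One call per objective evaluation.
// gr is the (n, 3) reference gradient; excl marks voxels excluded by the
// pathology mask (length 0 = no mask). Returns the distance value and its
// (n, 3) gradient with respect to the displacement components.
// [[Rcpp::export]]
List c_ngf_gradient(NumericVector tvol, IntegerVector tdim,
                    NumericVector tspacing, NumericVector torigin,
                    NumericVector u, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericVector gr, LogicalVector excl,
                    double epsR, double epsT) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h3 = spacing[0] * spacing[1] * spacing[2];
  const bool masked = excl.size() > 0;

  std::vector<double> tw(n), tgx(n), tgy(n), tgz(n);

  // pass 1: trilinear warp with point-derivatives
  const int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  {
    R_xlen_t id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          double p[3] = {origin[0] + i * spacing[0] + u[id],
                         origin[1] + j * spacing[1] + u[id + n],
                         origin[2] + k * spacing[2] + u[id + 2 * n]};
          double c[3];
          bool inside[3];
          for (int a = 0; a < 3; ++a) {
            double ca = (p[a] - torigin[a]) / tspacing[a];
            double hi = (double)tdim[a] - 1.0;
            inside[a] = (ca >= 0.0 && ca <= hi);
            if (ca < 0.0) ca = 0.0;
            if (ca > hi) ca = hi;
            c[a] = ca;
          }
          int i0 = (int)std::floor(c[0]); if (i0 > tnx - 2) i0 = tnx - 2; if (i0 < 0) i0 = 0;
          int j0 = (int)std::floor(c[1]); if (j0 > tny - 2) j0 = tny - 2; if (j0 < 0) j0 = 0;
          int k0 = (int)std::floor(c[2]); if (k0 > tnz - 2) k0 = tnz - 2; if (k0 < 0) k0 = 0;
          double fx = c[0] - i0, fy = c[1] - j0, fz = c[2] - k0;
          R_xlen_t b = vidx(i0, j0, k0, tnx, tny);
          R_xlen_t sx = 1, sy = tnx, sz = (R_xlen_t)tnx * tny;
          double v000 = tvol[b], v100 = tvol[b + sx];
          double v010 = tvol[b + sy], v110 = tvol[b + sx + sy];
          double v001 = tvol[b + sz], v101 = tvol[b + sx + sz];
          double v011 = tvol[b + sy + sz], v111 = tvol[b + sx + sy + sz];
          double c00 = v000 * (1 - fx) + v100 * fx;
          double c10 = v010 * (1 - fx) + v110 * fx;
          double c01 = v001 * (1 - fx) + v101 * fx;
          double c11 = v011 * (1 - fx) + v111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          tw[id] = c0 * (1 - fz) + c1 * fz;
          double dx00 = v100 - v000, dx10 = v110 - v010;
          double dx01 = v101 - v001, dx11 = v111 - v011;
          tgx[id] = inside[0] ? ((dx00 * (1 - fy) + dx10 * fy) * (1 - fz) +
                                 (dx01 * (1 - fy) + dx11 * fy) * fz) / tspacing[0] : 0.0;
          tgy[id] = inside[1] ? ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / tspacing[1] : 0.0;
          tgz[id] = inside[2] ? (c1 - c0) / tspacing[2] : 0.0;
        }
  }

  // pass 2+3: warped-image gradient, NGF core, stencil weights (reuse gt)
  std::vector<double> w0(n), w1(n), w2(n);
  double value = 0.0;
  {
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    R_xlen_t id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          double g0, g1, g2;
          if (i == 0)            g0 = (tw[id + sx] - tw[id]) / spacing[0];
          else if (i == nx - 1)  g0 = (tw[id] - tw[id - sx]) / spacing[0];
          else                   g0 = (tw[id + sx] - tw[id - sx]) / (2 * spacing[0]);
          if (j == 0)            g1 = (tw[id + sy] - tw[id]) / spacing[1];
          else if (j == ny - 1)  g1 = (tw[id] - tw[id - sy]) / spacing[1];
          else                   g1 = (tw[id + sy] - tw[id - sy]) / (2 * spacing[1]);
          if (k == 0)            g2 = (tw[id + sz] - tw[id]) / spacing[2];
          else if (k == nz - 1)  g2 = (tw[id] - tw[id - sz]) / spacing[2];
          else                   g2 = (tw[id + sz] - tw[id - sz]) / (2 * spacing[2]);
          if (masked && excl[id]) { w0[id] = w1[id] = w2[id] = 0.0; continue; }
          double r0 = gr[id], r1 = gr[id + n], r2 = gr[id + 2 * n];
          double ip = r0 * g0 + r1 * g1 + r2 * g2 + epsR * epsT;
          double nr = std::sqrt(r0 * r0 + r1 * r1 + r2 * r2 + epsR * epsR);
          double nt = std::sqrt(g0 * g0 + g1 * g1 + g2 * g2 + epsT * epsT);
          double rho = ip / (nr * nt);
          value += 0.5 * (1.0 - rho * rho);
          double common = -rho / (nr * nt) * h3;
          double ratio = rho * rho / (nt * nt) * h3;
          w0[id] = common * r0 + ratio * g0;
          w1[id] = common * r1 + ratio * g1;
          w2[id] = common * r2 + ratio * g2;
        }
    value *= h3;
  }

  // pass 4: adjoint of the gradient stencils -> dD/dT(y), then chain with
  // the warp's point-derivative into the output gradient
  std::vector<double> dtw(n, 0.0);
  {
    const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    const int nn[3] = {nx, ny, nz};
    const std::vector<double>* ws[3] = {&w0, &w1, &w2};
    for (int a = 0; a < 3; ++a) {
      const double h = spacing[a];
      const R_xlen_t s = stride[a];
      const std::vector<double>& wa = *ws[a];
      R_xlen_t id = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i, ++id) {
            int ia = (a == 0) ? i : (a == 1) ? j : k;
            if (ia == 0) {
              dtw[id]     -= wa[id] / h;
              dtw[id + s] += wa[id] / h;
            } else if (ia == nn[a] - 1) {
              dtw[id]     += wa[id] / h;
              dtw[id - s] -= wa[id] / h;
            } else {
              dtw[id + s] += wa[id] / (2 * h);
              dtw[id - s] -= wa[id] / (2 * h);
            }
          }
    }
  }
  NumericVector grad(3 * n);
  for (R_xlen_t id = 0; id < n; ++id) {
    grad[id] = dtw[id] * tgx[id];
    grad[id + n] = dtw[id] * tgy[id];
    grad[id + 2 * n] = dtw[id] * tgz[id];
  }
  return List::create(_["value"] = value, _["gradient"] = grad);
}

// Fused curvature energy + gradient: E = h3 * sum_k sum_x (Lap u_k)^2,
// gradient = 2 h3 Lap^T (Lap u_k) per component, natural boundary.
// [[Rcpp::export]]
List c_curvature(NumericVector u, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double h3 = spacing[0] * spacing[1] * spacing[2];
  const double ihx2 = 1.0 / (spacing[0] * spacing[0]);
  const double ihy2 = 1.0 / (spacing[1] * spacing[1]);
  const double ihz2 = 1.0 / (spacing[2] * spacing[2]);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  NumericVector grad(3 * n);
  std::vector<double> lap(n);
  double value = 0.0;
  for (int comp = 0; comp < 3; ++comp) {
    NumericVector::const_iterator uc = u.begin() + comp * n;
    R_xlen_t id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          double l = 0.0;
          if (i > 0 && i < nx - 1)
            l += (uc[id - sx] - 2.0 * uc[id] + uc[id + sx]) * ihx2;
          if (j > 0 && j < ny - 1)
            l += (uc[id - sy] - 2.0 * uc[id] + uc[id + sy]) * ihy2;
          if (k > 0 && k < nz - 1)
            l += (uc[id - sz] - 2.0 * uc[id] + uc[id + sz]) * ihz2;
          lap[id] = l;
          value += l * l;
        }
    NumericVector::iterator gc = grad.begin() + comp * n;
    id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          double w = 2.0 * h3 * lap[id];
          if (w == 0.0) continue;
          if (i > 0 && i < nx - 1) {
            gc[id - sx] += w * ihx2; gc[id] -= 2.0 * w * ihx2; gc[id + sx] += w * ihx2;
          }
          if (j > 0 && j < ny - 1) {
            gc[id - sy] += w * ihy2; gc[id] -= 2.0 * w * ihy2; gc[id + sy] += w * ihy2;
          }
          if (k > 0 && k < nz - 1) {
            gc[id - sz] += w * ihz2; gc[id] -= 2.0 * w * ihz2; gc[id + sz] += w * ihz2;
          }
        }
  }
  return List::create(_["value"] = value * h3, _["gradient"] = grad);
}
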
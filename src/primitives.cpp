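// Low-level image kernels: interpolation, resampling, separable Gaussian
// smoothing, demons iterations, TFCE, and the skeleton owner partition.
// All linear indices here are 0-based, column-major (x fastest), matching
// how R lays out a dim=c(nx,ny,nz) array.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double sample_trilinear(const double *src, int nx, int ny, int nz,
                                      double x, double y, double z) {
  // pull-back sample at continuous 0-based voxel coords; outside -> 0
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double val = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz; if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy; if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx; if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        val += wx * wy * wz * src[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return val;
}

static inline double sample_nearest(const double *src, int nx, int ny, int nz,
                                    double x, double y, double z) {
  int xx = (int)std::round(x), yy = (int)std::round(y), zz = (int)std::round(z);
  if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) return 0.0;
  return src[xx + (size_t)nx * (yy + (size_t)ny * zz)];
}

// [[Rcpp::export]]
NumericVector c_resample_affine(NumericVector src, IntegerVector sdim,
                                IntegerVector odim, NumericMatrix M, int mode) {
  // M: 3x4, maps output 0-based voxel coords to source 0-based voxel coords
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *s = src.begin();
  double *o = out.begin();
  size_t k = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++k) {
        double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + M(0,3);
        double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + M(1,3);
        double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + M(2,3);
        o[k] = mode == 0 ? sample_trilinear(s, nx, ny, nz, sx, sy, sz)
                         : sample_nearest(s, nx, ny, nz, sx, sy, sz);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector c_resample_field(NumericVector src, IntegerVector sdim,
                               NumericVector field, IntegerVector odim,
                               NumericVector pixdim, int mode) {
  // field: mm displacements on the output grid, length 3*prod(odim),
  // component-major blocks (ux all voxels, then uy, then uz).
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  size_t n = (size_t)ox * oy * oz;
  NumericVector out(n);
  const double *s = src.begin(), *u = field.begin();
  double px = pixdim[0], py = pixdim[1], pz = pixdim[2];
  size_t k = 0;
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x, ++k) {
        double sx = x + u[k] / px;
        double sy = y + u[k + n] / py;
        double sz = z + u[k + 2*n] / pz;
        out[k] = mode == 0 ? sample_trilinear(s, nx, ny, nz, sx, sy, sz)
                           : sample_nearest(s, nx, ny, nz, sx, sy, sz);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector c_sample_points(NumericVector src, IntegerVector sdim,
                              NumericMatrix pts, int mode) {
  // pts: N x 3, 0-based continuous voxel coords
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *s = src.begin();
  for (int i = 0; i < n; ++i)
    out[i] = mode == 0
      ? sample_trilinear(s, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2))
      : sample_nearest(s, nx, ny, nz, pts(i,0), pts(i,1), pts(i,2));
  return out;
}

static void gauss1d(const double *in, double *out, int n, size_t stride,
                    size_t nlines, size_t line_stride, const double *kern,
                    int r) {
  // convolve each of nlines lines of length n (element stride `stride`,
  // line start spacing handled by caller via offsets array) -- here caller
  // passes contiguous blocks; reflection boundary.
  for (size_t l = 0; l < nlines; ++l) {
    const double *ip = in + l * line_stride;
    double *op = out + l * line_stride;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = -r; j <= r; ++j) {
        int idx = i + j;
        if (idx < 0) idx = -idx - 1;          // reflect
        if (idx >= n) idx = 2*n - idx - 1;
        acc += kern[j + r] * ip[(size_t)idx * stride];
      }
      op[(size_t)i * stride] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector c_gauss3d(NumericVector vol, IntegerVector dim,
                        NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector buf1(clone(vol)), buf2(n);
  double *a = buf1.begin(), *b = buf2.begin();
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2*r + 1);
    double sum = 0.0;
    for (int j = -r; j <= r; ++j) { kern[j+r] = std::exp(-0.5*j*j/(s*s)); sum += kern[j+r]; }
    for (double &kv : kern) kv /= sum;
    if (ax == 0) {
      gauss1d(a, b, nx, 1, (size_t)ny*nz, nx, kern.data(), r);
    } else if (ax == 1) {
      // lines along y: for each (z, x): start = x + nx*ny*z, stride = nx
      for (int z = 0; z < nz; ++z)
        gauss1d(a + (size_t)nx*ny*z, b + (size_t)nx*ny*z, ny, nx, nx, 1,
                kern.data(), r);
    } else {
      gauss1d(a, b, nz, (size_t)nx*ny, (size_t)nx*ny, 1, kern.data(), r);
    }
    std::swap(a, b);
  }
  if (a == buf1.begin()) return buf1; else return buf2;
}

// [[Rcpp::export]]
NumericMatrix c_gradient(NumericVector vol, IntegerVector dim,
                         NumericVector pixdim) {
  // central differences, per mm; one-sided at boundaries
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  const double *v = vol.begin();
  size_t k = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++k) {
        int xp = std::min(x+1, nx-1), xm = std::max(x-1, 0);
        int yp = std::min(y+1, ny-1), ym = std::max(y-1, 0);
        int zp = std::min(z+1, nz-1), zm = std::max(z-1, 0);
        g(k,0) = (v[xp + (size_t)nx*(y + (size_t)ny*z)] -
                  v[xm + (size_t)nx*(y + (size_t)ny*z)]) / ((xp-xm) * pixdim[0]);
        g(k,1) = (v[x + (size_t)nx*(yp + (size_t)ny*z)] -
                  v[x + (size_t)nx*(ym + (size_t)ny*z)]) / ((yp-ym) * pixdim[1]);
        g(k,2) = (v[x + (size_t)nx*(y + (size_t)ny*zp)] -
                  v[x + (size_t)nx*(y + (size_t)ny*zm)]) / ((zp-zm) * pixdim[2]);
      }
  return g;
}

// [[Rcpp::export]]
NumericVector c_demons(NumericVector fixed, NumericVector moving,
                       IntegerVector dim, NumericVector pixdim,
                       NumericVector field_init, int n_iter,
                       double sigma_fluid_mm, double sigma_elastic_mm,
                       double max_step_mm) {
  // classic Thirion demons with fluid (update) and elastic (total)
  // Gaussian regularisation; field in mm, pull-back convention.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector field(clone(field_init));
  NumericVector warped(n), upd(3*n);
  NumericVector sig_f(3), sig_e(3);
  for (int a = 0; a < 3; ++a) {
    sig_f[a] = sigma_fluid_mm / pixdim[a];
    sig_e[a] = sigma_elastic_mm / pixdim[a];
  }
  double mean_sp = (pixdim[0] + pixdim[1] + pixdim[2]) / 3.0;
  double alpha2 = 1.0 / (mean_sp * mean_sp);
  IntegerVector d3 = IntegerVector::create(nx, ny, nz);
  for (int it = 0; it < n_iter; ++it) {
    warped = c_resample_field(moving, d3, field, d3, pixdim, 0);
    NumericMatrix g = c_gradient(warped, d3, pixdim);
    for (size_t k = 0; k < n; ++k) {
      double diff = fixed[k] - warped[k];
      double g2 = g(k,0)*g(k,0) + g(k,1)*g(k,1) + g(k,2)*g(k,2);
      double den = g2 + alpha2 * diff * diff;
      double f = den > 1e-12 ? diff / den : 0.0;
      double ux = f * g(k,0), uy = f * g(k,1), uz = f * g(k,2);
      double mag = std::sqrt(ux*ux + uy*uy + uz*uz);
      if (mag > max_step_mm) { double sc = max_step_mm/mag; ux*=sc; uy*=sc; uz*=sc; }
      upd[k] = ux; upd[k+n] = uy; upd[k+2*n] = uz;
    }
    if (sigma_fluid_mm > 0) {
      for (int c = 0; c < 3; ++c) {
        NumericVector comp(upd.begin() + c*n, upd.begin() + (c+1)*n);
        comp = c_gauss3d(comp, d3, sig_f);
        std::copy(comp.begin(), comp.end(), upd.begin() + c*n);
      }
    }
    // additive composition: sample existing field at x + upd, then add
    for (int c = 0; c < 3; ++c) {
      NumericVector comp(field.begin() + c*n, field.begin() + (c+1)*n);
      NumericVector warped_comp = c_resample_field(comp, d3, upd, d3, pixdim, 0);
      for (size_t k = 0; k < n; ++k) field[k + c*n] = warped_comp[k] + upd[k + c*n];
    }
    if (sigma_elastic_mm > 0) {
      for (int c = 0; c < 3; ++c) {
        NumericVector comp(field.begin() + c*n, field.begin() + (c+1)*n);
        comp = c_gauss3d(comp, d3, sig_e);
        std::copy(comp.begin(), comp.end(), field.begin() + c*n);
      }
    }
  }
  return field;
}

// [[Rcpp::export]]
List c_ffd(NumericVector fixed, NumericVector moving, IntegerVector dim,
           NumericVector pixdim, int spacing_vox, int n_iter,
           double step0, double max_step_mm, NumericMatrix cp_init) {
  // free-form deformation on a coarse control lattice: the dense field is
  // the trilinear interpolation of control-point displacements (mm).
  // Iterates demons-style normalised force restriction onto the lattice
  // with monotone (backtracking) acceptance of SSD.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  int cx = (nx - 1) / spacing_vox + 2, cy = (ny - 1) / spacing_vox + 2,
      cz = (nz - 1) / spacing_vox + 2;
  size_t nc = (size_t)cx * cy * cz;
  IntegerVector d3 = IntegerVector::create(nx, ny, nz);
  NumericMatrix cp(nc, 3);
  if (cp_init.nrow() == (int)nc)
    for (size_t k = 0; k < nc; ++k)
      for (int c = 0; c < 3; ++c) cp(k, c) = cp_init(k, c);
  double inv_sp = 1.0 / spacing_vox;
  double mean_sp = (pixdim[0] + pixdim[1] + pixdim[2]) / 3.0;
  double alpha2 = 1.0 / (mean_sp * mean_sp);

  NumericVector field(3 * n), warped(n);
  std::vector<double> fsplat(3 * nc), wsplat(nc);
  NumericMatrix trial(nc, 3);

  // upsample control lattice to dense field
  auto upsample = [&](NumericMatrix &cpts) {
    size_t k = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++k) {
          double gx = x * inv_sp, gy = y * inv_sp, gz = z * inv_sp;
          int x0 = (int)gx, y0 = (int)gy, z0 = (int)gz;
          double fx = gx - x0, fy = gy - y0, fz = gz - z0;
          double ux = 0, uy = 0, uz = 0;
          for (int dz2 = 0; dz2 <= 1; ++dz2)
            for (int dy2 = 0; dy2 <= 1; ++dy2)
              for (int dx2 = 0; dx2 <= 1; ++dx2) {
                int xx = std::min(x0 + dx2, cx - 1);
                int yy = std::min(y0 + dy2, cy - 1);
                int zz = std::min(z0 + dz2, cz - 1);
                double w = (dx2 ? fx : 1 - fx) * (dy2 ? fy : 1 - fy) *
                           (dz2 ? fz : 1 - fz);
                size_t ck = xx + (size_t)cx * (yy + (size_t)cy * zz);
                ux += w * cpts(ck, 0);
                uy += w * cpts(ck, 1);
                uz += w * cpts(ck, 2);
              }
          field[k] = ux; field[k + n] = uy; field[k + 2*n] = uz;
        }
  };
  auto ssd_of = [&]() {
    warped = c_resample_field(moving, d3, field, d3, pixdim, 0);
    double s = 0;
    for (size_t k = 0; k < n; ++k) {
      double d = fixed[k] - warped[k]; s += d * d;
    }
    return s / n;
  };

  upsample(cp);
  double cur = ssd_of();
  double step = step0;
  for (int it = 0; it < n_iter; ++it) {
    // demons-style force at voxels (uses `warped` from the last ssd_of)
    NumericMatrix g = c_gradient(warped, d3, pixdim);
    std::fill(fsplat.begin(), fsplat.end(), 0.0);
    std::fill(wsplat.begin(), wsplat.end(), 0.0);
    size_t k = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++k) {
          double diff = fixed[k] - warped[k];
          double g2 = g(k,0)*g(k,0) + g(k,1)*g(k,1) + g(k,2)*g(k,2);
          double den = g2 + alpha2 * diff * diff;
          double f = den > 1e-12 ? diff / den : 0.0;
          double ux = f * g(k,0), uy = f * g(k,1), uz = f * g(k,2);
          double gx = x * inv_sp, gy = y * inv_sp, gz = z * inv_sp;
          int x0 = (int)gx, y0 = (int)gy, z0 = (int)gz;
          double fx = gx - x0, fy = gy - y0, fz = gz - z0;
          for (int dz2 = 0; dz2 <= 1; ++dz2)
            for (int dy2 = 0; dy2 <= 1; ++dy2)
              for (int dx2 = 0; dx2 <= 1; ++dx2) {
                int xx = std::min(x0 + dx2, cx - 1);
                int yy = std::min(y0 + dy2, cy - 1);
                int zz = std::min(z0 + dz2, cz - 1);
                double w = (dx2 ? fx : 1 - fx) * (dy2 ? fy : 1 - fy) *
                           (dz2 ? fz : 1 - fz);
                size_t ck = xx + (size_t)cx * (yy + (size_t)cy * zz);
                fsplat[ck] += w * ux;
                fsplat[ck + nc] += w * uy;
                fsplat[ck + 2*nc] += w * uz;
                wsplat[ck] += w;
              }
        }
    for (size_t ck = 0; ck < nc; ++ck) {
      double w = wsplat[ck] > 1e-9 ? wsplat[ck] : 1.0;
      double ux = step * fsplat[ck] / w;
      double uy = step * fsplat[ck + nc] / w;
      double uz = step * fsplat[ck + 2*nc] / w;
      double mag = std::sqrt(ux*ux + uy*uy + uz*uz);
      if (mag > max_step_mm) {
        double sc = max_step_mm / mag; ux *= sc; uy *= sc; uz *= sc;
      }
      trial(ck, 0) = cp(ck, 0) + ux;
      trial(ck, 1) = cp(ck, 1) + uy;
      trial(ck, 2) = cp(ck, 2) + uz;
    }
    upsample(trial);
    double val = ssd_of();
    if (val < cur) {
      cur = val;
      for (size_t ck = 0; ck < nc; ++ck)
        for (int c = 0; c < 3; ++c) cp(ck, c) = trial(ck, c);
      step = std::min(step * 1.1, 8.0 * step0);
    } else {
      step *= 0.5;
      upsample(cp);      // restore field/warped consistency
      cur = ssd_of();
      if (step < 0.05 * step0) break;
    }
  }
  upsample(cp);
  return List::create(_["field"] = field, _["cp"] = cp, _["ssd"] = cur);
}

// [[Rcpp::export]]
double c_ncc(NumericVector a, NumericVector b) {
  size_t n = a.size();
  double ma = 0, mb = 0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (size_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da*db; saa += da*da; sbb += db*db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// [[Rcpp::export]]
NumericVector c_tfce(NumericVector stat, IntegerVector adj,
                     IntegerVector adj_start, double E, double H, double dh) {
  // discrete TFCE on an arbitrary graph (the skeleton): for thresholds
  // h = dh, 2dh, ... compute connected components of {stat >= h} and add
  // size^E * h^H * dh to every member voxel.
  int nv = stat.size();
  NumericVector out(nv);
  double mx = 0.0;
  for (int i = 0; i < nv; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0 || dh <= 0) return out;
  std::vector<int> comp(nv), queue_buf(nv), members(nv);
  int nh = (int)std::floor(mx / dh + 1e-9);
  for (int ih = 1; ih <= nh; ++ih) {
    double h = ih * dh;
    std::fill(comp.begin(), comp.end(), -1);
    for (int i = 0; i < nv; ++i) {
      if (stat[i] < h - 1e-12 || comp[i] >= 0) continue;
      // BFS from i
      int head = 0, tail = 0, nmem = 0;
      queue_buf[tail++] = i; comp[i] = i;
      while (head < tail) {
        int v = queue_buf[head++];
        members[nmem++] = v;
        for (int e = adj_start[v]; e < adj_start[v+1]; ++e) {
          int w = adj[e];
          if (stat[w] >= h - 1e-12 && comp[w] < 0) {
            comp[w] = i; queue_buf[tail++] = w;
          }
        }
      }
      double add = std::pow((double)nmem, E) * std::pow(h, H) * dh;
      for (int m = 0; m < nmem; ++m) out[members[m]] += add;
    }
  }
  return out;
}

// [[Rcpp::export]]
List c_owner_partition(IntegerVector dim, NumericVector pixdim,
                       IntegerVector seed_idx0, double max_dist_mm) {
  // exact Euclidean nearest-seed partition: every voxel within max_dist_mm
  // of a seed gets the (1-based) id of its nearest seed (ties -> lower
  // seed id); 0 elsewhere. Each seed scans only its bounding box.
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  IntegerVector owner(n, 0);
  int rx = (int)std::ceil(max_dist_mm / pixdim[0]);
  int ry = (int)std::ceil(max_dist_mm / pixdim[1]);
  int rz = (int)std::ceil(max_dist_mm / pixdim[2]);
  double m2 = max_dist_mm * max_dist_mm;
  for (int s = 0; s < seed_idx0.size(); ++s) {
    size_t k = (size_t)seed_idx0[s];
    int x = k % nx, y = (k / nx) % ny, z = k / ((size_t)nx * ny);
    for (int dz = -rz; dz <= rz; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      double z2 = dz * pixdim[2] * dz * pixdim[2];
      for (int dy = -ry; dy <= ry; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        double yz2 = z2 + dy * pixdim[1] * dy * pixdim[1];
        if (yz2 > m2) continue;
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          double d2 = yz2 + dx * pixdim[0] * dx * pixdim[0];
          if (d2 > m2) continue;
          size_t kk = xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (d2 < dist[kk] - 1e-12) { dist[kk] = d2; owner[kk] = s + 1; }
        }
      }
    }
  }
  NumericVector dmm(n);
  for (size_t k = 0; k < n; ++k)
    dmm[k] = std::isfinite(dist[k]) ? std::sqrt(dist[k]) : -1.0;
  return List::create(_["owner"] = owner, _["dist_mm"] = dmm);
}
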
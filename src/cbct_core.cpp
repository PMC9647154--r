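// Numerical core: cone-beam ray tracing, FDK backprojection, point-source
// dose deposition with attenuation, and 3D local gamma search.
// All physical quantities in mm; attenuation in 1/mm.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trilinear sample of a volume at continuous 0-based voxel coordinates.
// Coordinates outside the grid sample as zero.
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (x0 >= 0 && y0 >= 0 && z0 >= 0 &&
      x0 < nx - 1 && y0 < ny - 1 && z0 < nz - 1) {   // interior fast path
    const size_t sxy = (size_t)nx * ny;
    const double* b = v + (size_t)z0 * sxy + (size_t)y0 * nx + x0;
    double c00 = b[0] + fx * (b[1] - b[0]);
    double c10 = b[nx] + fx * (b[nx + 1] - b[nx]);
    double c01 = b[sxy] + fx * (b[sxy + 1] - b[sxy]);
    double c11 = b[sxy + nx] + fx * (b[sxy + nx + 1] - b[sxy + nx]);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    return c0 + fz * (c1 - c0);
  }
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
      }
    }
  }
  return acc;
}

// Line integral of the volume between two world points (midpoint rule,
// fixed step). spacing/origin map world mm -> voxel index.
static double lineIntegral(const double* v, int nx, int ny, int nz,
                           const double* spacing, const double* origin,
                           double sx, double sy, double sz,
                           double ex, double ey, double ez, double step) {
  double dx = ex - sx, dy = ey - sy, dz = ez - sz;
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len <= 0.0) return 0.0;
  dx /= len; dy /= len; dz /= len;
  // clip to volume bounding box (voxel-centred grid, half-voxel margin)
  double t0 = 0.0, t1 = len;
  for (int ax = 0; ax < 3; ++ax) {
    double s0 = (ax == 0 ? sx : ax == 1 ? sy : sz);
    double d0 = (ax == 0 ? dx : ax == 1 ? dy : dz);
    double lo = origin[ax] - 0.5 * spacing[ax];
    double hi = origin[ax] + ((ax == 0 ? nx : ax == 1 ? ny : nz) - 0.5) * spacing[ax];
    if (std::fabs(d0) < 1e-12) {
      if (s0 < lo || s0 > hi) return 0.0;
    } else {
      double ta = (lo - s0) / d0, tb = (hi - s0) / d0;
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return 0.0;
  double seg = t1 - t0;
  int n = (int)std::ceil(seg / step);
  if (n < 1) n = 1;
  double h = seg / n, acc = 0.0;
  double t = t0 + 0.5 * h;
  double px = (sx + t * dx - origin[0]) / spacing[0];
  double py = (sy + t * dy - origin[1]) / spacing[1];
  double pz = (sz + t * dz - origin[2]) / spacing[2];
  double ix = h * dx / spacing[0], iy = h * dy / spacing[1],
         iz = h * dz / spacing[2];
  for (int i = 0; i < n; ++i) {
    acc += trilinear(v, nx, ny, nz, px, py, pz);
    px += ix; py += iy; pz += iz;
  }
  return acc * h;
}

// [[Rcpp::export(name = ".forwardProjectCpp")]]
NumericVector forwardProjectCpp(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                double sad, double sdd,
                                int nu, int nv, double pitch,
                                NumericVector anglesDeg, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2], nV = anglesDeg.size();
  NumericVector out((size_t)nu * nv * nV);
  const double* v = vol.begin();
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  for (int a = 0; a < nV; ++a) {
    double th = anglesDeg[a] * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    // source on the rotation circle; detector centre opposite
    double srcx = sad * c, srcy = sad * s, srcz = 0.0;
    double dcx = srcx - sdd * c, dcy = srcy - sdd * s, dcz = 0.0;
    double ux = -s, uy = c;         // in-plane detector axis
    for (int iv = 0; iv < nv; ++iv) {
      double voff = (iv - (nv - 1) / 2.0) * pitch;
      for (int iu = 0; iu < nu; ++iu) {
        double uoff = (iu - (nu - 1) / 2.0) * pitch;
        double px = dcx + uoff * ux, py = dcy + uoff * uy, pz = dcz + voff;
        out[(size_t)a * nu * nv + (size_t)iv * nu + iu] =
          lineIntegral(v, nx, ny, nz, sp, org, srcx, srcy, srcz, px, py, pz, step);
      }
    }
  }
  return out;
}

// FDK voxel-driven backprojection of cosine-weighted, ramp-filtered
// projections. Projections are indexed on the physical detector; detector
// coordinates are rescaled to the virtual detector at the isocenter inside.
// [[Rcpp::export(name = ".fdkBackprojectCpp")]]
NumericVector fdkBackprojectCpp(NumericVector proj, int nu, int nv,
                                NumericVector anglesDeg,
                                double sad, double sdd, double pitch,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin, double fovRadius) {
  int nx = dim[0], ny = dim[1], nz = dim[2], nV = anglesDeg.size();
  NumericVector out((size_t)nx * ny * nz);
  const double* p = proj.begin();
  double mag = sad / sdd;               // detector mm -> isocenter mm
  double pitchIso = pitch * mag;
  double dAng = 2.0 * M_PI / nV;        // full-scan angular weight
  double r2lim = fovRadius > 0 ? fovRadius * fovRadius : -1.0;
  std::vector<double> cs(nV), sn(nV);
  for (int a = 0; a < nV; ++a) {
    double th = anglesDeg[a] * M_PI / 180.0;
    cs[a] = std::cos(th); sn[a] = std::sin(th);
  }
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix) {
        double x = origin[0] + ix * spacing[0];
        if (r2lim > 0 && x * x + y * y > r2lim) continue;
        double acc = 0.0;
        for (int a = 0; a < nV; ++a) {
          double U = sad - (x * cs[a] + y * sn[a]);
          if (U < 1e-6) continue;
          double w = sad * sad / (U * U);
          double uIso = sad * (-x * sn[a] + y * cs[a]) / U;
          double vIso = sad * z / U;
          double fu = uIso / pitchIso + (nu - 1) / 2.0;
          double fv = vIso / pitchIso + (nv - 1) / 2.0;
          if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) continue;
          int u0 = (int)std::floor(fu), v0 = (int)std::floor(fv);
          if (u0 >= nu - 1) u0 = nu - 2;
          if (v0 >= nv - 1) v0 = nv - 2;
          double au = fu - u0, av = fv - v0;
          const double* pv = p + (size_t)a * nu * nv;
          double q00 = pv[(size_t)v0 * nu + u0];
          double q10 = pv[(size_t)v0 * nu + u0 + 1];
          double q01 = pv[(size_t)(v0 + 1) * nu + u0];
          double q11 = pv[(size_t)(v0 + 1) * nu + u0 + 1];
          double q = (1 - au) * (1 - av) * q00 + au * (1 - av) * q10 +
                     (1 - au) * av * q01 + au * av * q11;
          acc += w * q;
        }
        out[(size_t)iz * nx * ny + (size_t)iy * nx + ix] = acc * dAng * 0.5;
      }
    }
  }
  return out;
}

// Point-source dose with inverse-square geometry and exponential
// attenuation along the source-to-point ray through the LAC volume.
// [[Rcpp::export(name = ".doseCpp")]]
NumericVector doseCpp(NumericVector mu, IntegerVector muDim,
                      NumericVector muSpacing, NumericVector muOrigin,
                      NumericMatrix dwellPos, NumericVector dwellTimes,
                      double strength,
                      IntegerVector doseDim, NumericVector doseSpacing,
                      NumericVector doseOrigin,
                      double dMin, double step) {
  int nx = doseDim[0], ny = doseDim[1], nz = doseDim[2];
  int nd = dwellPos.nrow();
  NumericVector out((size_t)nx * ny * nz);
  const double* v = mu.begin();
  double sp[3] = {muSpacing[0], muSpacing[1], muSpacing[2]};
  double org[3] = {muOrigin[0], muOrigin[1], muOrigin[2]};
  double d2min = dMin * dMin;
  for (int iz = 0; iz < nz; ++iz) {
    double z = doseOrigin[2] + iz * doseSpacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = doseOrigin[1] + iy * doseSpacing[1];
      for (int ix = 0; ix < nx; ++ix) {
        double x = doseOrigin[0] + ix * doseSpacing[0];
        double acc = 0.0;
        for (int j = 0; j < nd; ++j) {
          double dx = x - dwellPos(j, 0), dy = y - dwellPos(j, 1),
                 dz = z - dwellPos(j, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          double rs = lineIntegral(v, muDim[0], muDim[1], muDim[2], sp, org,
                                   dwellPos(j, 0), dwellPos(j, 1), dwellPos(j, 2),
                                   x, y, z, step);
          acc += strength * dwellTimes[j] * std::exp(-rs) / std::max(d2, d2min);
        }
        out[(size_t)iz * nx * ny + (size_t)iy * nx + ix] = acc;
      }
    }
  }
  return out;
}

// 3D local gamma. Reference and evaluated dose share one grid. For every
// reference voxel at or above `threshold`, search trilinearly interpolated
// evaluated dose on a subgrid of spacing dta/subdiv within
// searchFactor*dta; gamma^2 = (d/dta)^2 + (dD / (dd% * Dref_local))^2.
// Offsets are distance-sorted so the search can stop early.
// Returns gamma values, NA below threshold.
// [[Rcpp::export(name = ".gammaCpp")]]
NumericVector gammaCpp(NumericVector ref, NumericVector eval,
                       IntegerVector dim, NumericVector spacing,
                       NumericVector origin,
                       double ddPercent, double dtaMm, double threshold,
                       double searchFactor, int subdiv) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);
  const double* rv = ref.begin();
  const double* ev = eval.begin();
  double stepMm = dtaMm / subdiv;
  double radius = searchFactor * dtaMm;
  int m = (int)std::floor(radius / stepMm);
  struct Off { double dx, dy, dz, d2; };
  std::vector<Off> offs;
  for (int k = -m; k <= m; ++k)
    for (int j = -m; j <= m; ++j)
      for (int i = -m; i <= m; ++i) {
        double dx = i * stepMm, dy = j * stepMm, dz = k * stepMm;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= radius * radius) offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.d2 < b.d2; });
  double dta2 = dtaMm * dtaMm;
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix) {
        size_t idx = (size_t)iz * nx * ny + (size_t)iy * nx + ix;
        double dr = rv[idx];
        if (dr < threshold) continue;
        double x = origin[0] + ix * spacing[0];
        double denom = (ddPercent / 100.0) * dr;
        double best = R_PosInf;
        for (const Off& o : offs) {
          double dterm = o.d2 / dta2;
          if (dterm >= best) break;  // sorted by distance: no better ahead
          double px = (x + o.dx - origin[0]) / spacing[0];
          double py = (y + o.dy - origin[1]) / spacing[1];
          double pz = (z + o.dz - origin[2]) / spacing[2];
          if (px < 0 || py < 0 || pz < 0 ||
              px > nx - 1 || py > ny - 1 || pz > nz - 1) continue;
          double de = trilinear(ev, nx, ny, nz, px, py, pz);
          double dd = (de - dr) / denom;
          double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".lineIntegralCpp")]]
double lineIntegralCpp(NumericVector vol, IntegerVector dim,
                       NumericVector spacing, NumericVector origin,
                       NumericVector from, NumericVector to, double step) {
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  return lineIntegral(vol.begin(), dim[0], dim[1], dim[2], sp, org,
                      from[0], from[1], from[2], to[0], to[1], to[2], step);
}
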
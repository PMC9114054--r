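#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation on a voxel-center grid; coordinates in fractional
// voxel units (0 at the first voxel center). Out-of-grid neighbours read 0
// (air), which is valid because phantoms are required to sit inside the FOV.
static inline double trilinear(const double* m, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
    int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy), z0 = (int)std::floor(gz);
    double ax = gx - x0, ay = gy - y0, az = gz - z0;
    if (x0 >= 0 && x0 < nx - 1 && y0 >= 0 && y0 < ny - 1 &&
        z0 >= 0 && z0 < nz - 1) {
        const R_xlen_t i000 = (R_xlen_t)x0 + (R_xlen_t)nx * ((R_xlen_t)y0 + (R_xlen_t)ny * z0);
        const double* p0 = m + i000;
        const double* p1 = p0 + (R_xlen_t)nx * ny;
        const double c00 = p0[0] + ax * (p0[1] - p0[0]);
        const double c10 = p0[nx] + ax * (p0[nx + 1] - p0[nx]);
        const double c01 = p1[0] + ax * (p1[1] - p1[0]);
        const double c11 = p1[nx] + ax * (p1[nx + 1] - p1[nx]);
        const double c0 = c00 + ay * (c10 - c00);
        const double c1 = c01 + ay * (c11 - c01);
        return c0 + az * (c1 - c0);
    }
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
        int z = z0 + dz;
        if (z < 0 || z >= nz) continue;
        double wz = dz ? az : 1.0 - az;
        if (wz == 0.0) continue;
        for (int dy = 0; dy < 2; ++dy) {
            int y = y0 + dy;
            if (y < 0 || y >= ny) continue;
            double wy = dy ? ay : 1.0 - ay;
            if (wy == 0.0) continue;
            for (int dx = 0; dx < 2; ++dx) {
                int x = x0 + dx;
                if (x < 0 || x >= nx) continue;
                double wx = dx ? ax : 1.0 - ax;
                if (wx == 0.0) continue;
                acc += wx * wy * wz *
                       m[(R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z)];
            }
        }
    }
    return acc;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector mu, IntegerVector dim,
                                  double voxel, NumericVector origin,
                                  double sod, double sdd,
                                  int nu, int nv, double pitch,
                                  NumericVector angles_rad, double step) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int na = angles_rad.size();
    NumericVector out((R_xlen_t)nu * nv * na);
    const double* m = REAL(mu);
    double* o = REAL(out);
    const double ox = origin[0], oy = origin[1], oz = origin[2];
    const double hx = ox + nx * voxel, hy = oy + ny * voxel, hz = oz + nz * voxel;
    const double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;

    for (int ia = 0; ia < na; ++ia) {
        const double th = angles_rad[ia];
        const double ct = std::cos(th), st = std::sin(th);
        const double sx = sod * ct, sy = sod * st;          // source
        const double dcx = sx - sdd * ct, dcy = sy - sdd * st; // detector centre
        const double eux = -st, euy = ct;                    // detector u axis

        for (int iv = 0; iv < nv; ++iv) {
            const double v = (iv - cv) * pitch;
            for (int iu = 0; iu < nu; ++iu) {
                const double u = (iu - cu) * pitch;
                const double px = dcx + u * eux, py = dcy + u * euy, pz = v;
                double rx = px - sx, ry = py - sy, rz = pz;
                const double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
                rx /= rn; ry /= rn; rz /= rn;

                // ray / axis-aligned box clipping
                double t0 = 0.0, t1 = rn;
                bool miss = false;
                const double p0[3] = {sx, sy, 0.0};
                const double rd[3] = {rx, ry, rz};
                const double lo[3] = {ox, oy, oz}, hi[3] = {hx, hy, hz};
                for (int k = 0; k < 3 && !miss; ++k) {
                    if (std::fabs(rd[k]) < 1e-12) {
                        if (p0[k] < lo[k] || p0[k] > hi[k]) miss = true;
                    } else {
                        double ta = (lo[k] - p0[k]) / rd[k];
                        double tb = (hi[k] - p0[k]) / rd[k];
                        if (ta > tb) std::swap(ta, tb);
                        if (ta > t0) t0 = ta;
                        if (tb < t1) t1 = tb;
                        if (t0 >= t1) miss = true;
                    }
                }

                double val = 0.0;
                if (!miss) {
                    const double L = t1 - t0;
                    const int ns = (int)std::ceil(L / step);
                    const double dl = L / ns;
                    double s = 0.0;
                    for (int is = 0; is < ns; ++is) {
                        const double t = t0 + (is + 0.5) * dl;
                        const double gx = (sx + t * rx - ox) / voxel - 0.5;
                        const double gy = (sy + t * ry - oy) / voxel - 0.5;
                        const double gz = (t * rz - oz) / voxel - 0.5;
                        s += trilinear(m, nx, ny, nz, gx, gy, gz);
                    }
                    val = s * dl;
                }
                o[(R_xlen_t)iu + (R_xlen_t)nu * ((R_xlen_t)iv + (R_xlen_t)nv * ia)] = val;
            }
        }
    }
    return out;
}

// FDK back-projection of ramp-filtered projections resampled/expressed on the
// virtual detector through the isocentre (spacing du, dv). Includes the
// distance weight (SOD/(SOD - x.r))^2 and the delta-theta/2 scaling for a
// full 360-degree circular scan.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector filt, int nu, int nv,
                                  NumericVector angles_rad,
                                  double du, double dv, double sod,
                                  IntegerVector dim, double voxel,
                                  NumericVector origin) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int na = angles_rad.size();
    NumericVector out((R_xlen_t)nx * ny * nz);
    double* vol = REAL(out);
    const double* f = REAL(filt);
    const double ox = origin[0], oy = origin[1], oz = origin[2];
    const double cu = (nu - 1) / 2.0, cv = (nv - 1) / 2.0;
    const double dth = (na > 1) ? std::fabs(angles_rad[1] - angles_rad[0])
                                : 2.0 * M_PI;
    const double scale = 0.5 * dth;

    for (int ia = 0; ia < na; ++ia) {
        const double th = angles_rad[ia];
        const double ct = std::cos(th), st = std::sin(th);
        const double* pa = f + (R_xlen_t)nu * nv * ia;
        for (int iy = 0; iy < ny; ++iy) {
            const double y = oy + (iy + 0.5) * voxel;
            for (int ix = 0; ix < nx; ++ix) {
                const double x = ox + (ix + 0.5) * voxel;
                const double xr = x * ct + y * st;
                const double denom = sod - xr;
                if (denom < 1e-6) continue;
                const double w = sod / denom;
                const double fu = (-x * st + y * ct) * w / du + cu;
                if (fu < 0.0 || fu > nu - 1) continue;
                int u0 = (int)std::floor(fu);
                if (u0 == nu - 1) u0 = nu - 2;
                const double au = fu - u0;
                const double w2s = w * w * scale;
                const double fv0 = (oz + 0.5 * voxel) * w / dv + cv;
                const double dfv = voxel * w / dv;
                R_xlen_t vidx = (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy);
                for (int iz = 0; iz < nz; ++iz) {
                    const double fv = fv0 + iz * dfv;
                    if (fv < 0.0 || fv > nv - 1) continue;
                    int v0 = (int)std::floor(fv);
                    if (v0 == nv - 1) v0 = nv - 2;
                    const double av = fv - v0;
                    const double* r0 = pa + (R_xlen_t)nu * v0;
                    const double* r1 = r0 + nu;
                    const double val =
                        (1.0 - av) * ((1.0 - au) * r0[u0] + au * r0[u0 + 1]) +
                        av * ((1.0 - au) * r1[u0] + au * r1[u0 + 1]);
                    vol[vidx + (R_xlen_t)nx * ny * iz] += w2s * val;
                }
            }
        }
    }
    return out;
}
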
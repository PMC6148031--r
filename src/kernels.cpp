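// Voxel-level kernels for chondroquant.
//
// All 3D arrays use R's column-major layout with dim = (nz, ny, nx):
// linear index of voxel (iz, iy, ix) is iz + nz*(iy + ny*ix), i.e. z is
// the fastest-varying axis ("slices-first").  Coordinates are 0-based.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <deque>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef R_xlen_t xlen;

// reflect index into [0, n-1] (symmetric about the border sample,
// no edge duplication: -1 -> 1, n -> n-2)
static inline int reflect_idx(int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) {
        if (i < 0) i = -i;
        if (i >= n) i = 2 * n - 2 - i;
    }
    return i;
}

struct Off3 { int dz, dy, dx; };

// offsets of the axis-aligned ellipsoid with radii (rz, ry, rx);
// a zero radius collapses that axis
static std::vector<Off3> ellipsoid_offsets(int rz, int ry, int rx) {
    std::vector<Off3> off;
    for (int dz = -rz; dz <= rz; ++dz)
        for (int dy = -ry; dy <= ry; ++dy)
            for (int dx = -rx; dx <= rx; ++dx) {
                double s = 0.0;
                if (rz > 0) s += (double)dz * dz / ((double)rz * rz);
                else if (dz != 0) continue;
                if (ry > 0) s += (double)dy * dy / ((double)ry * ry);
                else if (dy != 0) continue;
                if (rx > 0) s += (double)dx * dx / ((double)rx * rx);
                else if (dx != 0) continue;
                if (s <= 1.0 + 1e-12) off.push_back({dz, dy, dx});
            }
    return off;
}

// [[Rcpp::export]]
IntegerVector cq_median3d(IntegerVector vol, IntegerVector dim, IntegerVector radii) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const int rz = radii[0], ry = radii[1], rx = radii[2];
    std::vector<Off3> off = ellipsoid_offsets(rz, ry, rx);
    const size_t m = off.size();
    const size_t med = (m - 1) / 2;   // lower median for even m
    IntegerVector out(vol.size());
    std::vector<int> buf(m);
    const int* v = INTEGER(vol);
    int* o = INTEGER(out);
    for (int ix = 0; ix < nx; ++ix) {
        for (int iy = 0; iy < ny; ++iy) {
            const bool y_in = (iy - ry >= 0 && iy + ry < ny);
            const bool x_in = (ix - rx >= 0 && ix + rx < nx);
            for (int iz = 0; iz < nz; ++iz) {
                const bool interior = y_in && x_in && (iz - rz >= 0 && iz + rz < nz);
                if (interior) {
                    for (size_t k = 0; k < m; ++k) {
                        const Off3& q = off[k];
                        buf[k] = v[(xlen)(iz + q.dz) +
                                   (xlen)nz * ((iy + q.dy) + (xlen)ny * (ix + q.dx))];
                    }
                } else {
                    for (size_t k = 0; k < m; ++k) {
                        const Off3& q = off[k];
                        const int z = reflect_idx(iz + q.dz, nz);
                        const int y = reflect_idx(iy + q.dy, ny);
                        const int x = reflect_idx(ix + q.dx, nx);
                        buf[k] = v[(xlen)z + (xlen)nz * (y + (xlen)ny * x)];
                    }
                }
                std::nth_element(buf.begin(), buf.begin() + med, buf.end());
                o[(xlen)iz + (xlen)nz * (iy + (xlen)ny * ix)] = buf[med];
            }
        }
    }
    return out;
}

static std::vector<Off3> se_offsets(const std::string& se) {
    std::vector<Off3> off;
    if (se == "cube3") {
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx)
                    off.push_back({dz, dy, dx});
    } else { // cross3: centre + 6-neighbourhood
        off.push_back({0, 0, 0});
        off.push_back({-1, 0, 0}); off.push_back({1, 0, 0});
        off.push_back({0, -1, 0}); off.push_back({0, 1, 0});
        off.push_back({0, 0, -1}); off.push_back({0, 0, 1});
    }
    return off;
}

// binary erosion; voxels outside the volume count as background
// [[Rcpp::export]]
IntegerVector cq_erode(IntegerVector mask, IntegerVector dim,
                       std::string se, int iterations) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<Off3> off = se_offsets(se);
    IntegerVector cur = clone(mask);
    if (iterations <= 0) return cur;
    IntegerVector nxt(mask.size());
    for (int it = 0; it < iterations; ++it) {
        const int* c = INTEGER(cur);
        int* n = INTEGER(nxt);
        for (int ix = 0; ix < nx; ++ix)
            for (int iy = 0; iy < ny; ++iy)
                for (int iz = 0; iz < nz; ++iz) {
                    const xlen i = (xlen)iz + (xlen)nz * (iy + (xlen)ny * ix);
                    int keep = c[i] != 0;
                    if (keep) {
                        for (size_t k = 0; k < off.size(); ++k) {
                            const int z = iz + off[k].dz, y = iy + off[k].dy,
                                      x = ix + off[k].dx;
                            if (z < 0 || z >= nz || y < 0 || y >= ny ||
                                x < 0 || x >= nx ||
                                c[(xlen)z + (xlen)nz * (y + (xlen)ny * x)] == 0) {
                                keep = 0; break;
                            }
                        }
                    }
                    n[i] = keep;
                }
        std::swap(cur, nxt);
    }
    return cur;
}

// binary dilation; voxels outside the volume stay background
// [[Rcpp::export]]
IntegerVector cq_dilate(IntegerVector mask, IntegerVector dim,
                        std::string se, int iterations) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<Off3> off = se_offsets(se);
    IntegerVector cur = clone(mask);
    if (iterations <= 0) return cur;
    IntegerVector nxt(mask.size());
    for (int it = 0; it < iterations; ++it) {
        const int* c = INTEGER(cur);
        int* n = INTEGER(nxt);
        for (int ix = 0; ix < nx; ++ix)
            for (int iy = 0; iy < ny; ++iy)
                for (int iz = 0; iz < nz; ++iz) {
                    const xlen i = (xlen)iz + (xlen)nz * (iy + (xlen)ny * ix);
                    int hit = 0;
                    for (size_t k = 0; k < off.size() && !hit; ++k) {
                        const int z = iz + off[k].dz, y = iy + off[k].dy,
                                  x = ix + off[k].dx;
                        if (z >= 0 && z < nz && y >= 0 && y < ny &&
                            x >= 0 && x < nx &&
                            c[(xlen)z + (xlen)nz * (y + (xlen)ny * x)] != 0)
                            hit = 1;
                    }
                    n[i] = hit;
                }
        std::swap(cur, nxt);
    }
    return cur;
}

static std::vector<Off3> conn_offsets(int connectivity) {
    std::vector<Off3> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                const int ad = std::abs(dz) + std::abs(dy) + std::abs(dx);
                if (ad == 0) continue;
                if (connectivity == 6 && ad > 1) continue;
                if (connectivity == 18 && ad > 2) continue;
                off.push_back({dz, dy, dx});
            }
    return off;
}

// connected components; ids 1..N in order of first-encountered voxel in
// linear (z fastest, then y, then x) scan order
// [[Rcpp::export]]
IntegerVector cq_label(IntegerVector mask, IntegerVector dim, int connectivity) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<Off3> off = conn_offsets(connectivity);
    IntegerVector lab(mask.size());
    const int* m = INTEGER(mask);
    int* L = INTEGER(lab);
    int next_id = 0;
    std::vector<xlen> stack;
    for (xlen i = 0; i < mask.size(); ++i) {
        if (m[i] == 0 || L[i] != 0) continue;
        ++next_id;
        L[i] = next_id;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            const xlen cur = stack.back(); stack.pop_back();
            const int iz = (int)(cur % nz);
            const int iy = (int)((cur / nz) % ny);
            const int ix = (int)(cur / ((xlen)nz * ny));
            for (size_t k = 0; k < off.size(); ++k) {
                const int z = iz + off[k].dz, y = iy + off[k].dy, x = ix + off[k].dx;
                if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
                    continue;
                const xlen j = (xlen)z + (xlen)nz * (y + (xlen)ny * x);
                if (m[j] != 0 && L[j] == 0) { L[j] = next_id; stack.push_back(j); }
            }
        }
    }
    return lab;
}

// multi-source BFS: grow eroded-component labels back over the original
// mask (geodesic reconstruction); unreached mask voxels stay 0
// [[Rcpp::export]]
IntegerVector cq_restore_labels(IntegerVector markers, IntegerVector mask,
                                IntegerVector dim, int connectivity) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<Off3> off = conn_offsets(connectivity);
    IntegerVector lab = clone(markers);
    const int* m = INTEGER(mask);
    int* L = INTEGER(lab);
    std::deque<xlen> queue;
    for (xlen i = 0; i < lab.size(); ++i)
        if (L[i] != 0) queue.push_back(i);
    while (!queue.empty()) {
        const xlen cur = queue.front(); queue.pop_front();
        const int id = L[cur];
        const int iz = (int)(cur % nz);
        const int iy = (int)((cur / nz) % ny);
        const int ix = (int)(cur / ((xlen)nz * ny));
        for (size_t k = 0; k < off.size(); ++k) {
            const int z = iz + off[k].dz, y = iy + off[k].dy, x = ix + off[k].dx;
            if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
                continue;
            const xlen j = (xlen)z + (xlen)nz * (y + (xlen)ny * x);
            if (m[j] != 0 && L[j] == 0) { L[j] = id; queue.push_back(j); }
        }
    }
    return lab;
}

// separable Gaussian blur with reflect boundary; dim = (nz, ny, nx),
// any of which may be 1
// [[Rcpp::export]]
NumericVector cq_gauss3d(NumericVector vol, IntegerVector dim, double sigma) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    if (sigma <= 0) return clone(vol);
    const int K = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * K + 1);
    double s = 0.0;
    for (int k = -K; k <= K; ++k) {
        w[k + K] = std::exp(-0.5 * k * k / (sigma * sigma));
        s += w[k + K];
    }
    for (size_t k = 0; k < w.size(); ++k) w[k] /= s;

    NumericVector a = clone(vol);
    NumericVector b(vol.size());
    const int n[3] = {nz, ny, nx};
    const xlen stride[3] = {1, (xlen)nz, (xlen)nz * ny};
    for (int ax = 0; ax < 3; ++ax) {
        if (n[ax] == 1) continue;
        double* src = REAL(a);
        double* dst = REAL(b);
        const int n0 = n[ax];
        const xlen st = stride[ax];
        // iterate over all lines along axis `ax`
        const int nA = n[(ax + 1) % 3], nB = n[(ax + 2) % 3];
        const xlen stA = stride[(ax + 1) % 3], stB = stride[(ax + 2) % 3];
        for (int ib = 0; ib < nB; ++ib)
            for (int ia = 0; ia < nA; ++ia) {
                const xlen base = (xlen)ia * stA + (xlen)ib * stB;
                for (int i = 0; i < n0; ++i) {
                    double acc = 0.0;
                    for (int k = -K; k <= K; ++k)
                        acc += w[k + K] * src[base + (xlen)reflect_idx(i + k, n0) * st];
                    dst[base + (xlen)i * st] = acc;
                }
            }
        std::swap(a, b);
    }
    return a;
}

static inline double bilinear(const double* f, int ny, int nx, double y, double x) {
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    const int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    const int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
    const double fy = y - y0, fx = x - x0;
    // field stored as (ny, nx) column-major: index y + ny*x
    const double v00 = f[y0 + (xlen)ny * x0], v01 = f[y0 + (xlen)ny * x1];
    const double v10 = f[y1 + (xlen)ny * x0], v11 = f[y1 + (xlen)ny * x1];
    return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// [[Rcpp::export]]
NumericVector cq_bilinear(NumericMatrix field, NumericMatrix pts) {
    const int ny = field.nrow(), nx = field.ncol();
    NumericVector out(pts.nrow());
    for (int i = 0; i < pts.nrow(); ++i)
        out[i] = bilinear(REAL(field), ny, nx, pts(i, 0), pts(i, 1));
    return out;
}

static void resample_closed(std::vector<double>& y, std::vector<double>& x,
                            double spacing) {
    const size_t n = y.size();
    std::vector<double> cum(n + 1, 0.0);
    for (size_t i = 0; i < n; ++i) {
        const size_t j = (i + 1) % n;
        cum[i + 1] = cum[i] + std::hypot(y[j] - y[i], x[j] - x[i]);
    }
    const double L = cum[n];
    if (L <= 0) return;
    int m = (int)std::lround(L / spacing);
    if (m < 3) m = 3;
    std::vector<double> ny2(m), nx2(m);
    size_t seg = 0;
    for (int k = 0; k < m; ++k) {
        const double t = L * k / m;
        while (seg + 1 < n + 1 && cum[seg + 1] < t) ++seg;
        const size_t i = seg % n, j = (seg + 1) % n;
        const double dl = cum[seg + 1] - cum[seg];
        const double f = dl > 0 ? (t - cum[seg]) / dl : 0.0;
        ny2[k] = y[i] + f * (y[j] - y[i]);
        nx2[k] = x[i] + f * (x[j] - x[i]);
    }
    y.swap(ny2); x.swap(nx2);
}

// Greedy discrete snake on a precomputed edge-attraction field (values in
// [0,1], stored (ny, nx) column-major).  Sequential strict-descent moves:
// total energy E = sum_i alpha*((d_i - s)/s)^2 + beta*|d2p_i|^2/(32 s^2)
//                  - edge(p_i)
// is non-increasing between resampling events by construction.
// [[Rcpp::export]]
List cq_snake(NumericMatrix edge, NumericMatrix init, int iterations,
              double alpha, double beta, int search_radius,
              double spacing, int resample_every) {
    const int ny_f = edge.nrow(), nx_f = edge.ncol();
    const double* F = REAL(edge);
    std::vector<double> y, x;
    for (int i = 0; i < init.nrow(); ++i) {
        y.push_back(init(i, 0));
        x.push_back(init(i, 1));
    }
    const double s2 = spacing * spacing;
    bool collapsed = false;
    std::vector<double> energy(iterations, NA_REAL);
    std::vector<int> npts(iterations, 0);
    std::vector<int> resampled(iterations, 0);

    for (int it = 0; it < iterations; ++it) {
        const int n = (int)y.size();
        for (int i = 0; i < n; ++i) {
            const int im1 = (i + n - 1) % n, ip1 = (i + 1) % n;
            const int im2 = (i + n - 2) % n, ip2 = (i + 2) % n;
            double bestE = R_PosInf;
            double bestY = y[i], bestX = x[i];
            double curE = 0.0;
            bool haveCur = false;
            for (int dy = -search_radius; dy <= search_radius; ++dy)
                for (int dx = -search_radius; dx <= search_radius; ++dx) {
                    const double py = y[i] + dy, px = x[i] + dx;
                    if (py < 0 || py > ny_f - 1 || px < 0 || px > nx_f - 1)
                        continue;
                    const double d_i = std::hypot(py - y[im1], px - x[im1]);
                    const double d_ip1 = std::hypot(y[ip1] - py, x[ip1] - px);
                    double E = alpha * ((d_i - spacing) * (d_i - spacing) +
                                        (d_ip1 - spacing) * (d_ip1 - spacing)) / s2;
                    // curvature terms touched by moving point i
                    const double c1y = y[im2] - 2 * y[im1] + py;
                    const double c1x = x[im2] - 2 * x[im1] + px;
                    const double c2y = y[im1] - 2 * py + y[ip1];
                    const double c2x = x[im1] - 2 * px + x[ip1];
                    const double c3y = py - 2 * y[ip1] + y[ip2];
                    const double c3x = px - 2 * x[ip1] + x[ip2];
                    E += beta * (c1y * c1y + c1x * c1x + c2y * c2y + c2x * c2x +
                                 c3y * c3y + c3x * c3x) / (32.0 * s2);
                    E -= bilinear(F, ny_f, nx_f, py, px);
                    if (dy == 0 && dx == 0) { curE = E; haveCur = true; }
                    if (E < bestE) { bestE = E; bestY = py; bestX = px; }
                }
            if (haveCur && bestE < curE - 1e-12) { y[i] = bestY; x[i] = bestX; }
        }
        // total energy after this iteration's moves
        double E = 0.0;
        for (int i = 0; i < n; ++i) {
            const int im1 = (i + n - 1) % n, ip1 = (i + 1) % n;
            const double d_i = std::hypot(y[i] - y[im1], x[i] - x[im1]);
            const double cy = y[im1] - 2 * y[i] + y[ip1];
            const double cx = x[im1] - 2 * x[i] + x[ip1];
            E += alpha * (d_i - spacing) * (d_i - spacing) / s2;
            E += beta * (cy * cy + cx * cx) / (32.0 * s2);
            E -= bilinear(F, ny_f, nx_f, y[i], x[i]);
        }
        energy[it] = E;
        npts[it] = n;
        if (resample_every > 0 && (it + 1) % resample_every == 0 &&
            it + 1 < iterations) {
            resample_closed(y, x, spacing);
            resampled[it] = 1;
            if ((int)y.size() < 8) { collapsed = true; break; }
        }
    }
    if ((int)y.size() < 8) collapsed = true;
    NumericMatrix out((int)y.size(), 2);
    for (size_t i = 0; i < y.size(); ++i) { out(i, 0) = y[i]; out(i, 1) = x[i]; }
    return List::create(_["points"] = out,
                        _["energy"] = wrap(energy),
                        _["n_points"] = wrap(npts),
                        _["resampled"] = wrap(resampled),
                        _["collapsed"] = collapsed);
}

// even-odd polygon rasterisation; pixel (y, x) is inside iff its centre
// (integer coordinates) is inside; returns (ny, nx) logical
// [[Rcpp::export]]
LogicalMatrix cq_fill_polygon(NumericMatrix pts, int ny, int nx) {
    LogicalMatrix out(ny, nx);
    const int n = pts.nrow();
    std::vector<double> xs;
    for (int y = 0; y < ny; ++y) {
        xs.clear();
        for (int i = 0; i < n; ++i) {
            const int j = (i + 1) % n;
            const double y1 = pts(i, 0), y2 = pts(j, 0);
            const double x1 = pts(i, 1), x2 = pts(j, 1);
            if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
                xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
            }
        }
        std::sort(xs.begin(), xs.end());
        for (size_t k = 0; k + 1 < xs.size(); k += 2) {
            int x0 = (int)std::ceil(xs[k]);
            int x1 = (int)std::ceil(xs[k + 1]) - 1;
            if (x0 < 0) x0 = 0;
            if (x1 > nx - 1) x1 = nx - 1;
            for (int xx = x0; xx <= x1; ++xx) out(y, xx) = true;
        }
    }
    return out;
}

// for each query point (rows of pts, same units as targets), index (1-based)
// of and distance to the nearest target point
// [[Rcpp::export]]
List cq_nearest(NumericMatrix pts, NumericMatrix targets) {
    IntegerVector idx(pts.nrow());
    NumericVector dist(pts.nrow());
    for (int i = 0; i < pts.nrow(); ++i) {
        double best = R_PosInf; int bj = NA_INTEGER;
        for (int j = 0; j < targets.nrow(); ++j) {
            double d = 0.0;
            for (int k = 0; k < pts.ncol(); ++k) {
                const double t = pts(i, k) - targets(j, k);
                d += t * t;
            }
            if (d < best) { best = d; bj = j + 1; }
        }
        idx[i] = bj;
        dist[i] = std::sqrt(best);
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}
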
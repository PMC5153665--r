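#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = (nz, ny, nx), column-major:
// linear index (0-based) i = z + nz * (y + ny * x).

static void neighbour_offsets(int connectivity, std::vector<int>& dz,
                              std::vector<int>& dy, std::vector<int>& dx) {
    dz.clear(); dy.clear(); dx.clear();
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                int m = std::abs(a) + std::abs(b) + std::abs(c);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                dz.push_back(a); dy.push_back(b); dx.push_back(c);
            }
}

// Label connected foreground voxels. Objects are numbered 1..K in the order
// of each object's first voxel in linear (z-fastest) scan order.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dims");
    std::vector<int> dz, dy, dx;
    neighbour_offsets(connectivity, dz, dy, dx);
    const int nn = (int)dz.size();

    IntegerVector labels(n, 0);
    std::vector<R_xlen_t> queue;
    queue.reserve(1024);
    int k = 0;
    for (R_xlen_t start = 0; start < n; ++start) {
        if (!mask[start] || labels[start] != 0) continue;
        ++k;
        labels[start] = k;
        queue.clear();
        queue.push_back(start);
        size_t head = 0;
        while (head < queue.size()) {
            R_xlen_t cur = queue[head++];
            int z = (int)(cur % nz);
            R_xlen_t rest = cur / nz;
            int y = (int)(rest % ny);
            int x = (int)(rest / ny);
            for (int j = 0; j < nn; ++j) {
                int zz = z + dz[j], yy = y + dy[j], xx = x + dx[j];
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                if (mask[idx] && labels[idx] == 0) {
                    labels[idx] = k;
                    queue.push_back(idx);
                }
            }
        }
    }
    labels.attr("n_objects") = k;
    return labels;
}

// FIFO flood fill from a seed voxel, constrained to lo <= value <= hi.
// [[Rcpp::export]]
LogicalVector flood_seed_cpp(NumericVector vol, IntegerVector dims,
                             double seed_idx0, double lo, double hi,
                             int connectivity) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (vol.size() != n) stop("volume length does not match dims");
    const R_xlen_t seed = (R_xlen_t)seed_idx0;
    if (seed < 0 || seed >= n) stop("seed index out of bounds");
    std::vector<int> dz, dy, dx;
    neighbour_offsets(connectivity, dz, dy, dx);
    const int nn = (int)dz.size();

    LogicalVector roi(n, false);
    if (vol[seed] < lo || vol[seed] > hi)
        stop("seed intensity outside range");
    std::vector<R_xlen_t> queue;
    queue.reserve(1024);
    roi[seed] = true;
    queue.push_back(seed);
    size_t head = 0;
    while (head < queue.size()) {
        R_xlen_t cur = queue[head++];
        int z = (int)(cur % nz);
        R_xlen_t rest = cur / nz;
        int y = (int)(rest % ny);
        int x = (int)(rest / ny);
        for (int j = 0; j < nn; ++j) {
            int zz = z + dz[j], yy = y + dy[j], xx = x + dx[j];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                xx < 0 || xx >= nx) continue;
            R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (!roi[idx] && vol[idx] >= lo && vol[idx] <= hi) {
                roi[idx] = true;
                queue.push_back(idx);
            }
        }
    }
    return roi;
}

static inline int reflect_idx(int i, int n) {
    // half-sample symmetric reflection: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
}

// 1D convolution along one axis (0 = z, 1 = y, 2 = x) with a centred
// odd-length kernel and reflecting boundary. Symmetric normalised kernels
// conserve the total intensity under this boundary handling.
// [[Rcpp::export]]
NumericVector conv1d_reflect_cpp(NumericVector vol, IntegerVector dims,
                                 NumericVector kernel, int axis) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (vol.size() != n) stop("volume length does not match dims");
    const int klen = kernel.size();
    if (klen % 2 != 1) stop("kernel must have odd length");
    const int r = klen / 2;

    int len, stride_a;
    if (axis == 0)      { len = nz; stride_a = 1; }
    else if (axis == 1) { len = ny; stride_a = nz; }
    else if (axis == 2) { len = nx; stride_a = nz * ny; }
    else stop("axis must be 0, 1 or 2");

    NumericVector out(n);
    // enumerate all 1D lines along the chosen axis
    int d1, d2, s1, s2;
    if (axis == 0)      { d1 = ny; d2 = nx; s1 = nz; s2 = nz * ny; }
    else if (axis == 1) { d1 = nz; d2 = nx; s1 = 1;  s2 = nz * ny; }
    else                { d1 = nz; d2 = ny; s1 = 1;  s2 = nz; }

    std::vector<double> line(len);
    for (int j2 = 0; j2 < d2; ++j2) {
        for (int j1 = 0; j1 < d1; ++j1) {
            R_xlen_t base = (R_xlen_t)j1 * s1 + (R_xlen_t)j2 * s2;
            for (int i = 0; i < len; ++i)
                line[i] = vol[base + (R_xlen_t)i * stride_a];
            for (int i = 0; i < len; ++i) {
                double acc = 0.0;
                for (int t = -r; t <= r; ++t)
                    acc += kernel[t + r] * line[reflect_idx(i + t, len)];
                out[base + (R_xlen_t)i * stride_a] = acc;
            }
        }
    }
    return out;
}

static inline int clampi(int i, int lo, int hi) {
    return i < lo ? lo : (i > hi ? hi : i);
}

// 3D non-local means with cubic patch and search window (radii in voxels).
// Weight of candidate j for voxel i: exp(-max(d2 - 2*sigma^2, 0)/h^2) where
// d2 is the mean squared difference between the two patches; patches are
// clamped at the volume boundary.
// [[Rcpp::export]]
NumericVector nlm3_cpp(NumericVector vol, IntegerVector dims, double sigma,
                       double h, int patch_r, int search_r) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (vol.size() != n) stop("volume length does not match dims");
    NumericVector out(n);
    const double two_s2 = 2.0 * sigma * sigma;
    const double inv_h2 = 1.0 / (h * h);
    const int pn = (2 * patch_r + 1);
    const double np = (double)pn * pn * pn;

    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
            double wsum = 0.0, vsum = 0.0;
            for (int sx = -search_r; sx <= search_r; ++sx)
              for (int sy = -search_r; sy <= search_r; ++sy)
                for (int sz = -search_r; sz <= search_r; ++sz) {
                    int cx = x + sx, cy = y + sy, cz = z + sz;
                    if (cx < 0 || cx >= nx || cy < 0 || cy >= ny ||
                        cz < 0 || cz >= nz) continue;
                    double d2 = 0.0;
                    for (int px = -patch_r; px <= patch_r; ++px)
                      for (int py = -patch_r; py <= patch_r; ++py)
                        for (int pz = -patch_r; pz <= patch_r; ++pz) {
                            int az = clampi(z + pz, 0, nz - 1);
                            int ay = clampi(y + py, 0, ny - 1);
                            int ax = clampi(x + px, 0, nx - 1);
                            int bz = clampi(cz + pz, 0, nz - 1);
                            int by = clampi(cy + py, 0, ny - 1);
                            int bx = clampi(cx + px, 0, nx - 1);
                            double diff =
                                vol[az + (R_xlen_t)nz * (ay + (R_xlen_t)ny * ax)] -
                                vol[bz + (R_xlen_t)nz * (by + (R_xlen_t)ny * bx)];
                            d2 += diff * diff;
                        }
                    d2 /= np;
                    double e = d2 - two_s2;
                    if (e < 0) e = 0;
                    double w = std::exp(-e * inv_h2);
                    wsum += w;
                    vsum += w * vol[cz + (R_xlen_t)nz * (cy + (R_xlen_t)ny * cx)];
                }
            out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = vsum / wsum;
        }
    return out;
}
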
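// Low-level voxel kernels for the radiomics feature bank.
// All arrays arrive as R column-major vectors with an explicit dim triple;
// gray-level arrays use 0 for "outside the mask" and 1..G inside.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-axial-slice co-occurrence counts at in-plane displacement
// (dx, dy) * step, accumulated over all slices (2.5D convention).
// The raw (asymmetric) count matrix is returned; symmetrisation and
// normalisation happen in R.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector lev, IntegerVector dim, int G,
                       int dx, int dy, int step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(G, G);
  int ox = dx * step, oy = dy * step;
  for (int z = 0; z < nz; ++z) {
    int zoff = nx * ny * z;
    for (int y = 0; y < ny; ++y) {
      int y2 = y + oy;
      if (y2 < 0 || y2 >= ny) continue;
      for (int x = 0; x < nx; ++x) {
        int x2 = x + ox;
        if (x2 < 0 || x2 >= nx) continue;
        int a = lev[zoff + y * nx + x];
        if (a == 0) continue;
        int b = lev[zoff + y2 * nx + x2];
        if (b == 0) continue;
        M(a - 1, b - 1) += 1.0;
      }
    }
  }
  return M;
}

// Gray-level run-length counts along in-plane direction (dx, dy),
// accumulated over axial slices. Out-of-mask voxels break runs.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector lev, IntegerVector dim, int G,
                        int dx, int dy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, ny);
  NumericMatrix M(G, maxlen);
  for (int z = 0; z < nz; ++z) {
    int zoff = nx * ny * z;
    for (int y0 = 0; y0 < ny; ++y0) {
      for (int x0 = 0; x0 < nx; ++x0) {
        // only start walking from cells with no predecessor along (dx,dy)
        int xp = x0 - dx, yp = y0 - dy;
        if (xp >= 0 && xp < nx && yp >= 0 && yp < ny) continue;
        int cur = 0, len = 0;
        int x = x0, y = y0;
        while (x >= 0 && x < nx && y >= 0 && y < ny) {
          int v = lev[zoff + y * nx + x];
          if (v == cur) {
            if (v != 0) ++len;
          } else {
            if (cur != 0) M(cur - 1, len - 1) += 1.0;
            cur = v;
            len = (v != 0) ? 1 : 0;
          }
          x += dx;
          y += dy;
        }
        if (cur != 0) M(cur - 1, len - 1) += 1.0;
      }
    }
  }
  return M;
}

// Neighbourhood gray-tone difference tables (in-slice 8-neighbourhoods).
// s[i] accumulates |i - mean(neighbours)|, n[i] counts contributing voxels;
// voxels with no in-mask neighbour are excluded.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector lev, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector s(G), n(G);
  for (int z = 0; z < nz; ++z) {
    int zoff = nx * ny * z;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int v = lev[zoff + y * nx + x];
        if (v == 0) continue;
        double sum = 0;
        int cnt = 0;
        for (int dy = -1; dy <= 1; ++dy) {
          int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            int w = lev[zoff + y2 * nx + x2];
            if (w == 0) continue;
            sum += w;
            ++cnt;
          }
        }
        if (cnt == 0) continue;
        s[v - 1] += std::fabs((double)v - sum / cnt);
        n[v - 1] += 1.0;
      }
    }
  }
  return List::create(_["s"] = s, _["n"] = n);
}

// Per-voxel local statistics on the in-mask (2r+1)^3 window.
// Columns: mean, std, range, entropy, median, min, max, in the column-major
// order of in-mask voxels. Entropy is computed on the supplied gray levels.
// [[Rcpp::export]]
NumericMatrix cpp_local_stats(NumericVector img, IntegerVector lev,
                              IntegerVector dim, int G, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> idx;
  for (int i = 0; i < lev.size(); ++i)
    if (lev[i] > 0) idx.push_back(i);
  int nin = (int)idx.size();
  NumericMatrix out(nin, 7);
  std::vector<double> vals;
  vals.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  std::vector<int> counts(G, 0);
  for (int t = 0; t < nin; ++t) {
    int id = idx[t];
    int z = id / (nx * ny), rem = id % (nx * ny), y = rem / nx, x = rem % nx;
    vals.clear();
    std::fill(counts.begin(), counts.end(), 0);
    double sum = 0, sum2 = 0;
    for (int dz = -radius; dz <= radius; ++dz) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int dy = -radius; dy <= radius; ++dy) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          int id2 = z2 * nx * ny + y2 * nx + x2;
          if (lev[id2] == 0) continue;
          double v = img[id2];
          vals.push_back(v);
          sum += v;
          sum2 += v * v;
          counts[lev[id2] - 1]++;
        }
      }
    }
    int m = (int)vals.size();
    double mean = sum / m;
    double var = m > 1 ? (sum2 - sum * sum / m) / (m - 1) : 0.0;
    if (var < 0) var = 0;
    std::sort(vals.begin(), vals.end());
    double med = (m % 2 == 1) ? vals[m / 2]
                              : 0.5 * (vals[m / 2 - 1] + vals[m / 2]);
    double ent = 0;
    for (int g = 0; g < G; ++g) {
      if (counts[g] > 0) {
        double p = (double)counts[g] / m;
        ent -= p * std::log2(p);
      }
    }
    out(t, 0) = mean;
    out(t, 1) = std::sqrt(var);
    out(t, 2) = vals[m - 1] - vals[0];
    out(t, 3) = ent;
    out(t, 4) = med;
    out(t, 5) = vals[0];
    out(t, 6) = vals[m - 1];
  }
  return out;
}

// Separable Gaussian smoothing, sigma given in voxels per axis,
// kernel truncated at 3 sigma. mode 0 = zero padding (fields that vanish
// outside the grid, e.g. mask indicators), mode 1 = replicate edges
// (stationary noise fields).
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector arr, IntegerVector dim,
                          NumericVector sigma, int mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(arr);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3 * s);
    std::vector<double> k(2 * r + 1);
    double ks = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ks += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= ks;
    NumericVector nxt(cur.size());
    int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    for (int z = 0; z < nz; ++z) {
      if (axis == 2 && z != 0) continue;
      for (int y = 0; y < ny; ++y) {
        if (axis == 1 && y != 0) continue;
        for (int x = 0; x < nx; ++x) {
          if (axis == 0 && x != 0) continue;
          int base = z * nx * ny + y * nx + x;
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int q = -r; q <= r; ++q) {
              int pp = p + q;
              if (pp < 0 || pp >= len) {
                if (mode == 0) continue;  // zero padding
                pp = pp < 0 ? 0 : len - 1;
              }
              acc += k[q + r] * cur[base + pp * stride];
            }
            nxt[base + p * stride] = acc;
          }
        }
      }
    }
    cur = nxt;
  }
  return cur;
}

// Number of 26-connected foreground components.
// [[Rcpp::export]]
int cpp_components26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> labels(mask.size(), 0);
  int comp = 0;
  std::vector<int> stack;
  for (int i = 0; i < mask.size(); ++i) {
    if (!mask[i] || labels[i]) continue;
    ++comp;
    labels[i] = comp;
    stack.push_back(i);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      int z = id / (nx * ny), rem = id % (nx * ny), y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = z + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            int id2 = z2 * nx * ny + y2 * nx + x2;
            if (mask[id2] && !labels[id2]) {
              labels[id2] = comp;
              stack.push_back(id2);
            }
          }
        }
      }
    }
  }
  return comp;
}
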
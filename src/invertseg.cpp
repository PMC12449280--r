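#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Index helpers for column-major 3-D arrays.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Trilinear resampling onto a coarser/finer grid. Output voxel (i,j,k)
// samples the input at continuous index i * step[axis] (voxel-centre
// alignment at the origin); coordinates are clamped at the faces.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector data, IntegerVector dIn,
                                     IntegerVector dOut, NumericVector step) {
  const int nx = dIn[0], ny = dIn[1], nz = dIn[2];
  const int ox = dOut[0], oy = dOut[1], oz = dOut[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double w = k * step[2];
    if (w > nz - 1) w = nz - 1;
    int k0 = (int)std::floor(w); if (k0 > nz - 2) k0 = nz >= 2 ? nz - 2 : 0;
    double fk = nz >= 2 ? w - k0 : 0.0;
    int k1 = nz >= 2 ? k0 + 1 : 0;
    for (int j = 0; j < oy; ++j) {
      double vcoord = j * step[1];
      if (vcoord > ny - 1) vcoord = ny - 1;
      int j0 = (int)std::floor(vcoord);
      if (j0 > ny - 2) j0 = ny >= 2 ? ny - 2 : 0;
      double fj = ny >= 2 ? vcoord - j0 : 0.0;
      int j1 = ny >= 2 ? j0 + 1 : 0;
      for (int i = 0; i < ox; ++i) {
        double u = i * step[0];
        if (u > nx - 1) u = nx - 1;
        int i0 = (int)std::floor(u);
        if (i0 > nx - 2) i0 = nx >= 2 ? nx - 2 : 0;
        double fi = nx >= 2 ? u - i0 : 0.0;
        int i1 = nx >= 2 ? i0 + 1 : 0;
        double c00 = data[idx3(i0, j0, k0, nx, ny)] * (1 - fi) +
                     data[idx3(i1, j0, k0, nx, ny)] * fi;
        double c10 = data[idx3(i0, j1, k0, nx, ny)] * (1 - fi) +
                     data[idx3(i1, j1, k0, nx, ny)] * fi;
        double c01 = data[idx3(i0, j0, k1, nx, ny)] * (1 - fi) +
                     data[idx3(i1, j0, k1, nx, ny)] * fi;
        double c11 = data[idx3(i0, j1, k1, nx, ny)] * (1 - fi) +
                     data[idx3(i1, j1, k1, nx, ny)] * fi;
        double c0 = c00 * (1 - fj) + c10 * fj;
        double c1 = c01 * (1 - fj) + c11 * fj;
        out[idx3(i, j, k, ox, oy)] = c0 * (1 - fk) + c1 * fk;
      }
    }
  }
  return out;
}

// Nearest-neighbour resampling (label maps): never invents new ids.
// [[Rcpp::export]]
IntegerVector resample_nearest_cpp(IntegerVector data, IntegerVector dIn,
                                   IntegerVector dOut, NumericVector step) {
  const int nx = dIn[0], ny = dIn[1], nz = dIn[2];
  const int ox = dOut[0], oy = dOut[1], oz = dOut[2];
  IntegerVector out((R_xlen_t)ox * oy * oz);
  std::vector<int> mi(ox), mj(oy), mk(oz);
  for (int i = 0; i < ox; ++i) {
    int v = (int)std::lround(i * step[0]);
    mi[i] = v < 0 ? 0 : (v > nx - 1 ? nx - 1 : v);
  }
  for (int j = 0; j < oy; ++j) {
    int v = (int)std::lround(j * step[1]);
    mj[j] = v < 0 ? 0 : (v > ny - 1 ? ny - 1 : v);
  }
  for (int k = 0; k < oz; ++k) {
    int v = (int)std::lround(k * step[2]);
    mk[k] = v < 0 ? 0 : (v > nz - 1 ? nz - 1 : v);
  }
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i)
        out[idx3(i, j, k, ox, oy)] = data[idx3(mi[i], mj[j], mk[k], nx, ny)];
  return out;
}

// 26-connectivity connected components of a binary mask.
// Returns component labels (1..n, 0 outside the mask).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++current;
    lab[s] = current;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) {
              lab[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = current;
  return lab;
}

// Full window-assignment pass: for each window (already ordered by
// descending priority), build the candidate mask, drop 26-connected
// components below the voxel-count threshold, and assign the window's id
// to surviving voxels not yet claimed. side: 0 none, 1 left of midline
// (low x), 2 right of midline (high x).
// [[Rcpp::export]]
IntegerVector window_assign_cpp(NumericVector x, IntegerVector dims,
                                NumericVector lo, NumericVector hi,
                                IntegerVector side, NumericVector minVox,
                                IntegerVector ids) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double mid = (nx - 1) / 2.0;   // 0-based middle sagittal plane
  IntegerVector out(n, 0);
  std::vector<int> comp(n);
  std::vector<char> cand(n);
  std::vector<R_xlen_t> stack;
  for (int w = 0; w < lo.size(); ++w) {
    const double wlo = lo[w], whi = hi[w];
    const int ws = side[w];
    bool any = false;
    for (R_xlen_t s = 0; s < n; ++s) {
      bool c = x[s] >= wlo && x[s] <= whi;
      if (c && ws != 0) {
        int i = (int)(s % nx);
        if (ws == 1) c = i < mid;
        else c = i > mid;
      }
      cand[s] = c;
      any = any || c;
    }
    if (!any) continue;
    if (minVox[w] > 0) {
      // label components and collect sizes
      std::fill(comp.begin(), comp.end(), 0);
      std::vector<double> sizes(1, 0.0);
      int current = 0;
      for (R_xlen_t s = 0; s < n; ++s) {
        if (!cand[s] || comp[s]) continue;
        ++current;
        sizes.push_back(0.0);
        comp[s] = current;
        stack.push_back(s);
        while (!stack.empty()) {
          R_xlen_t v = stack.back();
          stack.pop_back();
          sizes[current] += 1.0;
          int i = (int)(v % nx);
          int j = (int)((v / nx) % ny);
          int k = (int)(v / ((R_xlen_t)nx * ny));
          for (int dk = -1; dk <= 1; ++dk) {
            int kk = k + dk;
            if (kk < 0 || kk >= nz) continue;
            for (int dj = -1; dj <= 1; ++dj) {
              int jj = j + dj;
              if (jj < 0 || jj >= ny) continue;
              for (int di = -1; di <= 1; ++di) {
                int ii = i + di;
                if (ii < 0 || ii >= nx) continue;
                if (di == 0 && dj == 0 && dk == 0) continue;
                R_xlen_t t = idx3(ii, jj, kk, nx, ny);
                if (cand[t] && !comp[t]) {
                  comp[t] = current;
                  stack.push_back(t);
                }
              }
            }
          }
        }
      }
      for (R_xlen_t s = 0; s < n; ++s)
        if (cand[s] && sizes[comp[s]] < minVox[w]) cand[s] = false;
    }
    const int id = ids[w];
    for (R_xlen_t s = 0; s < n; ++s)
      if (cand[s] && out[s] == 0) out[s] = id;
  }
  return out;
}
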
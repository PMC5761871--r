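#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel grids arrive as R logical/numeric vectors in column-major order with
// dims (n1, n2, n3). All connectivity here is 6-connectivity (face
// neighbours), matching the conservative "magic wand" growth the package
// documents.

static inline int lin(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// [[Rcpp::export(name = ".cpp_flood_fill6")]]
LogicalVector cpp_flood_fill6(const LogicalVector& in_range,
                              const IntegerVector& dim,
                              const int seed) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n, false);
  if (seed < 0 || seed >= n)
    stop("seed index out of bounds");
  if (!in_range[seed])
    return out;                      // seed voxel outside the HU range
  std::vector<int> stack;
  stack.push_back(seed);
  out[seed] = true;
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    const int i = v % n1;
    const int j = (v / n1) % n2;
    const int k = v / (n1 * n2);
    const int nb[6][3] = {{i - 1, j, k}, {i + 1, j, k}, {i, j - 1, k},
                          {i, j + 1, k}, {i, j, k - 1}, {i, j, k + 1}};
    for (int q = 0; q < 6; ++q) {
      const int ii = nb[q][0], jj = nb[q][1], kk = nb[q][2];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      const int w = lin(ii, jj, kk, n1, n2);
      if (in_range[w] && !out[w]) {
        out[w] = true;
        stack.push_back(w);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_label_components6")]]
IntegerVector cpp_label_components6(const LogicalVector& mask,
                                    const IntegerVector& dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int i = v % n1;
      const int j = (v / n1) % n2;
      const int k = v / (n1 * n2);
      const int nb[6][3] = {{i - 1, j, k}, {i + 1, j, k}, {i, j - 1, k},
                            {i, j + 1, k}, {i, j, k - 1}, {i, j, k + 1}};
      for (int q = 0; q < 6; ++q) {
        const int ii = nb[q][0], jj = nb[q][1], kk = nb[q][2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const int w = lin(ii, jj, kk, n1, n2);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// One-dimensional squared distance transform (lower envelope of parabolas).
// Unreachable voxels carry BIG rather than Inf so the parabola
// intersections stay finite.
static const double BIG = 1e20;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (k > 0 && s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in voxel units) from every foreground voxel to
// the nearest background voxel *centre*. Out-of-grid space counts as
// foreground (no phantom background beyond the grid edge).
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(const LogicalVector& mask, const IntegerVector& dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along dim 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) f[i] = g[lin(i, j, k, n1, n2)];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) g[lin(i, j, k, n1, n2)] = d[i];
    }
  // pass along dim 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) f[j] = g[lin(i, j, k, n1, n2)];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) g[lin(i, j, k, n1, n2)] = d[j];
    }
  // pass along dim 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k) f[k] = g[lin(i, j, k, n1, n2)];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) g[lin(i, j, k, n1, n2)] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// Local thickness: for each foreground voxel, the largest `value` among
// spheres that cover it, where sphere c covers voxels within `radius[c]`
// and carries `value[c]` (its diameter). Radius and painted value are
// separate so the caller controls the centre-to-background-centre vs
// wall-to-wall conventions independently.
// [[Rcpp::export(name = ".cpp_local_thickness")]]
NumericVector cpp_local_thickness(const LogicalVector& mask,
                                  const NumericVector& radius,
                                  const NumericVector& value,
                                  const IntegerVector& dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector th(n, 0.0);

  std::vector<int> idx;
  idx.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) idx.push_back((int)i);
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return value[a] > value[b];
  });

  for (size_t s = 0; s < idx.size(); ++s) {
    const int c = idx[s];
    const double r = radius[c];
    if (r <= 0) continue;
    const double dia = value[c];
    if (th[c] >= dia && r < 1.0) {
      // already inside a larger sphere and too small to extend past it
      continue;
    }
    const int ci = c % n1;
    const int cj = (c / n1) % n2;
    const int ck = c / (n1 * n2);
    const int R = (int)std::floor(r);
    const double r2 = r * r;
    for (int dk = -R; dk <= R; ++dk) {
      const int kk = ck + dk;
      if (kk < 0 || kk >= n3) continue;
      for (int dj = -R; dj <= R; ++dj) {
        const int jj = cj + dj;
        if (jj < 0 || jj >= n2) continue;
        const double dd = (double)dk * dk + (double)dj * dj;
        if (dd > r2) continue;
        for (int di = -R; di <= R; ++di) {
          const int ii = ci + di;
          if (ii < 0 || ii >= n1) continue;
          if (dd + (double)di * di > r2) continue;
          const int w = lin(ii, jj, kk, n1, n2);
          if (mask[w] && th[w] < dia) th[w] = dia;
        }
      }
    }
  }
  return th;
}
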
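#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are column-major with dim = (d1, d2, d3) = (Z, Y, X).

static const double BIG = 1e30;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing `step`. f: input costs, d: output, n: length.
static void dt1d(const double *f, double *d, int n, double step,
                 int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    while (true) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance (per-axis step weights) from every TRUE voxel to
// the nearest FALSE voxel centre. FALSE voxels get 0. The caller is
// responsible for padding if out-of-volume space should count as background.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector fg, IntegerVector dim, NumericVector step) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = fg[i] ? BIG : 0.0;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (int i3 = 0; i3 < d3; i3++)
    for (int i2 = 0; i2 < d2; i2++) {
      double *line = &out[(R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3)];
      for (int i = 0; i < d1; i++) f[i] = line[i];
      dt1d(f.data(), dbuf.data(), d1, step[0], v.data(), z.data());
      for (int i = 0; i < d1; i++) line[i] = dbuf[i];
    }
  // pass along axis 2 (stride d1)
  for (int i3 = 0; i3 < d3; i3++)
    for (int i1 = 0; i1 < d1; i1++) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * d2 * i3;
      for (int i = 0; i < d2; i++) f[i] = out[base + (R_xlen_t)d1 * i];
      dt1d(f.data(), dbuf.data(), d2, step[1], v.data(), z.data());
      for (int i = 0; i < d2; i++) out[base + (R_xlen_t)d1 * i] = dbuf[i];
    }
  // pass along axis 3 (stride d1*d2)
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  for (int i2 = 0; i2 < d2; i2++)
    for (int i1 = 0; i1 < d1; i1++) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * i2;
      for (int i = 0; i < d3; i++) f[i] = out[base + s3 * i];
      dt1d(f.data(), dbuf.data(), d3, step[2], v.data(), z.data());
      for (int i = 0; i < d3; i++) out[base + s3 * i] = dbuf[i];
    }

  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}

// Connected-component labelling of a binary volume; connectivity 6 (faces)
// or 26 (full neighbourhood). Labels are assigned in raster scan order.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector fg, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);  // zero-initialised

  std::vector<int> off1, off2, off3;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        off1.push_back(a);
        off2.push_back(b);
        off3.push_back(c);
      }
  const int noff = (int)off1.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; seed++) {
    if (!fg[seed] || lab[seed] != 0) continue;
    next++;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i1 = (int)(cur % d1);
      int i2 = (int)((cur / d1) % d2);
      int i3 = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int k = 0; k < noff; k++) {
        int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
          continue;
        R_xlen_t j = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
        if (fg[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static inline int reflect_idx(int i, int n) {
  // symmetric half-sample reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable Gaussian convolution with per-axis sigma in voxel units and
// reflective boundary handling. sigma == 0 skips that axis.
// [[Rcpp::export(name = ".sepgauss")]]
NumericVector sepgauss(NumericVector img, IntegerVector dim,
                       NumericVector sigma) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out = clone(img);

  const int dims[3] = {d1, d2, d3};
  const R_xlen_t strides[3] = {1, d1, (R_xlen_t)d1 * d2};

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; i++) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; i++) k[i] /= ksum;

    const int len = dims[ax];
    const R_xlen_t str = strides[ax];
    std::vector<double> line(len), res(len);
    // iterate over all lines along axis ax
    const int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int ib = 0; ib < dims[ob]; ib++)
      for (int ia = 0; ia < dims[oa]; ia++) {
        R_xlen_t base = (R_xlen_t)ia * strides[oa] + (R_xlen_t)ib * strides[ob];
        for (int i = 0; i < len; i++) line[i] = out[base + str * i];
        for (int i = 0; i < len; i++) {
          double acc = 0;
          for (int j = -r; j <= r; j++)
            acc += k[j + r] * line[reflect_idx(i + j, len)];
          res[i] = acc;
        }
        for (int i = 0; i < len; i++) out[base + str * i] = res[i];
      }
  }
  (void)n;
  out.attr("dim") = dim;
  return out;
}
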
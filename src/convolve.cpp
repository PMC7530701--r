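#include <Rcpp.h>
using namespace Rcpp;

// Boundary codes shared with R/convolve.R: 0 mirror, 1 replicate, 2 periodic,
// 3 zero.  "mirror" is half-sample symmetric extension (the edge sample is
// repeated), applied recursively so the pad may exceed the signal extent.

static inline int fold_index(int i, int n, int boundary) {
  if (i >= 0 && i < n) return i;
  switch (boundary) {
  case 0: { // mirror
    int p = 2 * n;
    int j = i % p;
    if (j < 0) j += p;
    return (j < n) ? j : p - 1 - j;
  }
  case 1: // replicate
    return (i < 0) ? 0 : n - 1;
  case 2: { // periodic
    int j = i % n;
    if (j < 0) j += n;
    return j;
  }
  default: // zero: caller must skip
    return -1;
  }
}

// Centered same-size 1D convolution with a symmetric-orientation kernel:
// out[x] = sum_t k[t] * x[x + t - r], r = (len(k)-1)/2.
// [[Rcpp::export(name = ".conv1d_fold")]]
NumericVector conv1d_fold(NumericVector x, NumericVector k, int boundary) {
  const int n = x.size(), m = k.size(), r = (m - 1) / 2;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < m; ++t) {
      int j = i + t - r;
      if (j < 0 || j >= n) {
        j = fold_index(j, n, boundary);
        if (j < 0) continue; // zero boundary
      }
      acc += k[t] * x[j];
    }
    out[i] = acc;
  }
  return out;
}

// Separable 2D convolution: 1D kernel kr along rows (i.e. down each column)
// then kc along columns (across each row).
// [[Rcpp::export(name = ".conv2d_sep_fold")]]
NumericMatrix conv2d_sep_fold(NumericMatrix X, NumericVector kr,
                              NumericVector kc, int boundary) {
  const int nr = X.nrow(), nc = X.ncol();
  const int mr = kr.size(), rr = (mr - 1) / 2;
  const int mc = kc.size(), rc = (mc - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // row pass: accumulate shifted copies of each column, folding only
  // the out-of-range head/tail so the bulk stays contiguous
  for (int c = 0; c < nc; ++c) {
    const double *src = &X(0, c);
    double *dst = &tmp(0, c);
    for (int t = 0; t < mr; ++t) {
      const double kv = kr[t];
      const int off = t - rr;
      int lo = off < 0 ? -off : 0;        // first i with i+off >= 0
      int hi = nr - (off > 0 ? off : 0);  // first i with i+off >= nr
      if (lo > nr) lo = nr;
      if (hi < 0) hi = 0;
      for (int i = 0; i < lo; ++i) {
        int j = fold_index(i + off, nr, boundary);
        if (j >= 0) dst[i] += kv * src[j];
      }
      for (int i = lo; i < hi; ++i) dst[i] += kv * src[i + off];
      for (int i = hi; i < nr; ++i) {
        int j = fold_index(i + off, nr, boundary);
        if (j >= 0) dst[i] += kv * src[j];
      }
    }
  }
  // column pass accumulates whole columns so memory access stays
  // contiguous (per-element tap loops here would stride by nr)
  for (int c = 0; c < nc; ++c) {
    double *dst = &out(0, c);
    for (int t = 0; t < mc; ++t) {
      int j = c + t - rc;
      if (j < 0 || j >= nc) {
        j = fold_index(j, nc, boundary);
        if (j < 0) continue;
      }
      const double kv = kc[t];
      const double *src = &tmp(0, j);
      for (int i = 0; i < nr; ++i) dst[i] += kv * src[i];
    }
  }
  return out;
}

// Dense 2D convolution with an arbitrary centered kernel grid.
// [[Rcpp::export(name = ".conv2d_full_fold")]]
NumericMatrix conv2d_full_fold(NumericMatrix X, NumericMatrix K, int boundary) {
  const int nr = X.nrow(), nc = X.ncol();
  const int kr = K.nrow(), kc = K.ncol();
  const int rr = (kr - 1) / 2, rc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int tc = 0; tc < kc; ++tc) {
        int jc = c + tc - rc;
        if (jc < 0 || jc >= nc) {
          jc = fold_index(jc, nc, boundary);
          if (jc < 0) continue;
        }
        for (int tr = 0; tr < kr; ++tr) {
          int jr = i + tr - rr;
          if (jr < 0 || jr >= nr) {
            jr = fold_index(jr, nr, boundary);
            if (jr < 0) continue;
          }
          acc += K(tr, tc) * X(jr, jc);
        }
      }
      out(i, c) = acc;
    }
  }
  return out;
}
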
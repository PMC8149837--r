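#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a binary matrix (column-major, as R
// stores it). Labels are assigned in column-major scan order of each
// component's first-encountered pixel, so the result is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Gather image-to-column matrix for a batch of samples stored
// back-to-back in x. idx0 holds 1-based indices into a single sample
// (npos x K); output stacks samples row-wise: row s*npos + p.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerMatrix idx0,
                         int sample_len, int n) {
  int npos = idx0.nrow(), K = idx0.ncol();
  NumericMatrix out((R_xlen_t)npos * n, K);
  const double *px = x.begin();
  double *po = out.begin();
  const int *pi = idx0.begin();
  R_xlen_t nrow_out = (R_xlen_t)npos * n;
  for (int k = 0; k < K; ++k) {
    const int *col_idx = pi + (R_xlen_t)k * npos;
    double *col_out = po + (R_xlen_t)k * nrow_out;
    for (int s = 0; s < n; ++s) {
      const double *xs = px + (R_xlen_t)s * sample_len;
      double *os = col_out + (R_xlen_t)s * npos;
      for (int p = 0; p < npos; ++p) os[p] = xs[col_idx[p] - 1];
    }
  }
  return out;
}

// Scatter-add transpose of cpp_im2col: accumulate column gradients back
// onto the input layout. Returns a vector of length sample_len * n.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerMatrix idx0,
                         int sample_len, int n) {
  int npos = idx0.nrow(), K = idx0.ncol();
  NumericVector out((R_xlen_t)sample_len * n);
  double *po = out.begin();
  const double *pc = cols.begin();
  const int *pi = idx0.begin();
  R_xlen_t nrow_cols = (R_xlen_t)npos * n;
  for (int k = 0; k < K; ++k) {
    const int *col_idx = pi + (R_xlen_t)k * npos;
    const double *col_in = pc + (R_xlen_t)k * nrow_cols;
    for (int s = 0; s < n; ++s) {
      double *os = po + (R_xlen_t)s * sample_len;
      const double *cs = col_in + (R_xlen_t)s * npos;
      for (int p = 0; p < npos; ++p) os[col_idx[p] - 1] += cs[p];
    }
  }
  return out;
}

// Non-overlapping 2x2 max-pooling over nmaps stacked H x W maps.
// Returns the pooled values and the 1-based argmax index into x so the
// backward pass can scatter gradients.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, int H, int W, int nmaps) {
  int oH = H / 2, oW = W / 2;
  R_xlen_t olen = (R_xlen_t)oH * oW * nmaps;
  NumericVector out(olen);
  IntegerVector amax(olen);
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int m = 0; m < nmaps; ++m) {
    R_xlen_t base = (R_xlen_t)m * H * W;
    for (int oj = 0; oj < oW; ++oj) {
      for (int oi = 0; oi < oH; ++oi) {
        R_xlen_t p00 = base + 2 * oi + (R_xlen_t)(2 * oj) * H;
        R_xlen_t best = p00;
        double v = px[p00];
        if (px[p00 + 1] > v) { v = px[p00 + 1]; best = p00 + 1; }
        if (px[p00 + H] > v) { v = px[p00 + H]; best = p00 + H; }
        if (px[p00 + H + 1] > v) { v = px[p00 + H + 1]; best = p00 + H + 1; }
        out[o] = v;
        amax[o] = (int)(best + 1);
        ++o;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dout, IntegerVector argmax,
                               R_xlen_t xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  return dx;
}
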
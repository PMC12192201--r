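// Hot loops for the 3D network: same-size 3x3x3 convolution (pad 1) via
// im2col + BLAS, and 2x2x2 stride-2 max pooling with argmax bookkeeping.
//
// Tensor layout (matches R): a feature map is a column-major array with
// dims (d1, d2, d3, C), i.e. channel slices are contiguous. A convolution
// weight is a matrix (Cout x 27*Cin); column index r for input channel c
// and kernel offset (o1, o2, o3) in {-1,0,1}^3 is
//   r = c*27 + ((o1+1)*3 + (o2+1))*3 + (o3+1)      (0-based).
//
// The patch matrix is kept transposed (nv x 27*Cin) so both the gather
// and the output of the GEMM are contiguous in memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kt(v, r) = x[neighbour of voxel v at offset r], zero outside the volume
static arma::mat im2colT(const double* x, int d1, int d2, int d3, int C) {
  const int nv = d1 * d2 * d3;
  arma::mat Kt(nv, 27 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * nv;
    for (int o1 = -1; o1 <= 1; ++o1)
      for (int o2 = -1; o2 <= 1; ++o2)
        for (int o3 = -1; o3 <= 1; ++o3) {
          const int r = c * 27 + ((o1 + 1) * 3 + (o2 + 1)) * 3 + (o3 + 1);
          double* col = Kt.colptr(r);
          for (int i3 = 0; i3 < d3; ++i3) {
            const int j3 = i3 + o3;
            if (j3 < 0 || j3 >= d3) continue;
            for (int i2 = 0; i2 < d2; ++i2) {
              const int j2 = i2 + o2;
              if (j2 < 0 || j2 >= d2) continue;
              const int lo = (o1 < 0) ? 1 : 0;
              const int hi = (o1 > 0) ? d1 - 1 : d1;
              const double* src = xc + (std::size_t)(j2 + (std::size_t)d2 * j3) * d1 + o1;
              double* dst = col + (std::size_t)(i2 + (std::size_t)d2 * i3) * d1;
              for (int i1 = lo; i1 < hi; ++i1) dst[i1] = src[i1];
            }
          }
        }
  }
  return Kt;
}

// scatter-add transpose: gx += col2im(gKt)
static void col2imT(const arma::mat& gKt, double* gx, int d1, int d2, int d3, int C) {
  const int nv = d1 * d2 * d3;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (std::size_t)c * nv;
    for (int o1 = -1; o1 <= 1; ++o1)
      for (int o2 = -1; o2 <= 1; ++o2)
        for (int o3 = -1; o3 <= 1; ++o3) {
          const int r = c * 27 + ((o1 + 1) * 3 + (o2 + 1)) * 3 + (o3 + 1);
          const double* col = gKt.colptr(r);
          for (int i3 = 0; i3 < d3; ++i3) {
            const int j3 = i3 + o3;
            if (j3 < 0 || j3 >= d3) continue;
            for (int i2 = 0; i2 < d2; ++i2) {
              const int j2 = i2 + o2;
              if (j2 < 0 || j2 >= d2) continue;
              const int lo = (o1 < 0) ? 1 : 0;
              const int hi = (o1 > 0) ? d1 - 1 : d1;
              double* dst = xc + (std::size_t)(j2 + (std::size_t)d2 * j3) * d1 + o1;
              const double* src = col + (std::size_t)(i2 + (std::size_t)d2 * i3) * d1;
              for (int i1 = lo; i1 < hi; ++i1) dst[i1] += src[i1];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dim,
                             NumericMatrix W, NumericVector b) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2], Cin = dim[3];
  const int nv = d1 * d2 * d3;
  const int Cout = W.nrow();
  if (W.ncol() != 27 * Cin) stop("conv weight has %d columns, expected %d", W.ncol(), 27 * Cin);
  if (b.size() != Cout) stop("conv bias length mismatch");
  const arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  arma::mat Kt = im2colT(x.begin(), d1, d2, d3, Cin);
  NumericVector out((std::size_t)nv * Cout);
  arma::mat Y(out.begin(), nv, Cout, false, true);
  Y = Kt * Wm.t();
  for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  out.attr("dim") = IntegerVector::create(d1, d2, d3, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dim,
                    NumericMatrix W, NumericVector gy) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2], Cin = dim[3];
  const int nv = d1 * d2 * d3;
  const int Cout = W.nrow();
  const arma::mat Wm(W.begin(), Cout, W.ncol(), false);
  const arma::mat gY((double*)gy.begin(), nv, Cout, false);  // alias, layout matches
  arma::mat Kt = im2colT(x.begin(), d1, d2, d3, Cin);
  arma::mat gWt = Kt.t() * gY;          // 27*Cin x Cout
  arma::vec gb = arma::sum(gY, 0).t();
  arma::mat gKt = gY * Wm;              // nv x 27*Cin
  NumericVector gx((std::size_t)nv * Cin);  // zero-initialised
  col2imT(gKt, gx.begin(), d1, d2, d3, Cin);
  gx.attr("dim") = IntegerVector::create(d1, d2, d3, Cin);
  return List::create(_["gx"] = gx,
                      _["gW"] = wrap(arma::mat(gWt.t())),
                      _["gb"] = wrap(gb));
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2], C = dim[3];
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  if (e1 < 1 || e2 < 1 || e3 < 1) stop("input too small for 2x2x2 pooling");
  const std::size_t nv = (std::size_t)d1 * d2 * d3;
  const std::size_t ne = (std::size_t)e1 * e2 * e3;
  NumericVector y(ne * C);
  IntegerVector idx(ne * C);  // 0-based linear index into x
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + c * nv;
    for (int k = 0; k < e3; ++k)
      for (int j = 0; j < e2; ++j)
        for (int i = 0; i < e1; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bestix = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const std::size_t ix =
                    (2 * i + di) + (std::size_t)d1 * ((2 * j + dj) + (std::size_t)d2 * (2 * k + dk));
                if (xc[ix] > best) { best = xc[ix]; bestix = ix; }
              }
          const std::size_t o = i + (std::size_t)e1 * (j + (std::size_t)e2 * k);
          y[c * ne + o] = best;
          idx[c * ne + o] = (int)(c * nv + bestix);
        }
  }
  y.attr("dim") = IntegerVector::create(e1, e2, e3, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  const std::size_t nv = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nv);
  for (int t = 0; t < gy.size(); ++t) gx[idx[t]] += gy[t];
  gx.attr("dim") = xdim;
  return gx;
}
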
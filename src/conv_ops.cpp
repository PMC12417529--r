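// Dense 3D convolution and max-pooling kernels used by the network's imaging
// branches.  Feature maps are R arrays with dim = c(B, C, D, H, W) (column
// major, batch fastest); convolution weights have dim = c(k, k, k, Cin, Cout)
// so that, viewed as a matrix, rows run over (kd, kh, kw, cin).  The
// convolution is computed by chunked im2col: blocks of output voxels are
// gathered into a [k^3*Cin, chunk] patch matrix and handled with one BLAS
// gemm each, which bounds memory while keeping the arithmetic in large
// matrix products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static inline R_xlen_t pick_chunk(R_xlen_t rows, R_xlen_t total) {
  R_xlen_t c = 4000000 / rows;  // cap the patch matrix near 32 MB
  if (c < 256) c = 256;
  if (c > total) c = total;
  return c;
}

// fill columns [j0, j0+n) of the patch matrix; output voxel j is decoded as
// b + B*(od + Do*(oh + Ho*ow)); out-of-range input positions contribute 0
static void gather_cols(arma::mat &col, const double *xp, R_xlen_t j0,
                        R_xlen_t n, int B, int C, int D, int H, int W,
                        int K, int stride, int pad, int Do, int Ho) {
  const R_xlen_t BD = (R_xlen_t)B * Do;
  const R_xlen_t BDH = BD * Ho;
  for (R_xlen_t jj = 0; jj < n; ++jj) {
    const R_xlen_t j = j0 + jj;
    const int b = (int)(j % B);
    const int od = (int)((j / B) % Do);
    const int oh = (int)((j / BD) % Ho);
    const int ow = (int)(j / BDH);
    double *cp = col.colptr(jj);
    R_xlen_t r = 0;
    const int id0 = od * stride - pad, ih0 = oh * stride - pad,
              iw0 = ow * stride - pad;
    for (int ci = 0; ci < C; ++ci) {
      const double *xc = xp + (R_xlen_t)B * ci + b;
      for (int kw = 0; kw < K; ++kw) {
        const int iw = iw0 + kw;
        const bool wok = iw >= 0 && iw < W;
        for (int kh = 0; kh < K; ++kh) {
          const int ih = ih0 + kh;
          const bool hok = wok && ih >= 0 && ih < H;
          const R_xlen_t base = (R_xlen_t)B * C * ((R_xlen_t)D * (ih + (R_xlen_t)H * iw));
          for (int kd = 0; kd < K; ++kd, ++r) {
            const int id = id0 + kd;
            if (hok && id >= 0 && id < D)
              cp[r] = xc[base + (R_xlen_t)B * C * id];
            else cp[r] = 0.0;
          }
        }
      }
    }
  }
}

// weight matrix [K^3*Cin, Cout] with rows ordered (kd, kh, kw, cin) to match
// gather_cols; the R array is (kd, kh, kw, cin, cout), i.e. the same order,
// so this is a plain reinterpretation
static arma::mat weight_matrix(const NumericVector &w, int K, int Cin,
                               int Cout) {
  return arma::mat(const_cast<double *>(w.begin()),
                   (R_xlen_t)K * K * K * Cin, Cout, false, true);
}

// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int B = xd[0], C = xd[1], D = xd[2], H = xd[3], W = xd[4];
  const int K = wd[0], Cin = wd[3], Cout = wd[4];
  if (Cin != C) stop("conv3d: channel mismatch");
  const int Do = out_size(D, K, stride, pad), Ho = out_size(H, K, stride, pad),
            Wo = out_size(W, K, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("conv3d: input smaller than kernel/stride");
  NumericVector out((R_xlen_t)B * Cout * Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(B, Cout, Do, Ho, Wo);
  const double *xp = x.begin();
  double *op = out.begin();
  arma::mat Wm = weight_matrix(w, K, Cin, Cout);
  const R_xlen_t rows = (R_xlen_t)K * K * K * Cin;
  const R_xlen_t total = (R_xlen_t)B * Do * Ho * Wo;
  const R_xlen_t chunk = pick_chunk(rows, total);
  arma::mat col(rows, chunk), Y;
  const bool has_b = bias.size() == Cout;
  const double *bp = bias.begin();
  const R_xlen_t BD = (R_xlen_t)B * Do, BDH = BD * Ho;
  for (R_xlen_t j0 = 0; j0 < total; j0 += chunk) {
    const R_xlen_t n = std::min(chunk, total - j0);
    gather_cols(col, xp, j0, n, B, C, D, H, W, K, stride, pad, Do, Ho);
    Y = Wm.t() * col.cols(0, n - 1);          // [Cout, n]
    for (R_xlen_t jj = 0; jj < n; ++jj) {
      const R_xlen_t j = j0 + jj;
      const int b = (int)(j % B);
      const int od = (int)((j / B) % Do);
      const int oh = (int)((j / BD) % Ho);
      const int ow = (int)(j / BDH);
      double *dst = op + b + (R_xlen_t)B *
        ((R_xlen_t)Cout * (od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow)));
      const double *yc = Y.colptr(jj);
      if (has_b)
        for (int co = 0; co < Cout; ++co) dst[(R_xlen_t)B * co] = yc[co] + bp[co];
      else
        for (int co = 0; co < Cout; ++co) dst[(R_xlen_t)B * co] = yc[co];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_cpp")]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  const int B = xd[0], C = xd[1], D = xd[2], H = xd[3], W = xd[4];
  const int K = wd[0], Cin = wd[3], Cout = wd[4];
  const int Do = od[2], Ho = od[3], Wo = od[4];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  const double *xp = x.begin(), *gp = dout.begin();
  double *dxp = dx.begin(), *dbp = db.begin();
  arma::mat Wm = weight_matrix(w, K, Cin, Cout);
  arma::mat dWm(const_cast<double *>(dw.begin()),
                (R_xlen_t)K * K * K * Cin, Cout, false, true);
  const R_xlen_t rows = (R_xlen_t)K * K * K * Cin;
  const R_xlen_t total = (R_xlen_t)B * Do * Ho * Wo;
  const R_xlen_t chunk = pick_chunk(rows, total);
  arma::mat col(rows, chunk), G(Cout, chunk), dcol;
  const R_xlen_t BD = (R_xlen_t)B * Do, BDH = BD * Ho;
  for (R_xlen_t j0 = 0; j0 < total; j0 += chunk) {
    const R_xlen_t n = std::min(chunk, total - j0);
    gather_cols(col, xp, j0, n, B, C, D, H, W, K, stride, pad, Do, Ho);
    for (R_xlen_t jj = 0; jj < n; ++jj) {
      const R_xlen_t j = j0 + jj;
      const int b = (int)(j % B);
      const int od2 = (int)((j / B) % Do);
      const int oh = (int)((j / BD) % Ho);
      const int ow = (int)(j / BDH);
      const double *src = gp + b + (R_xlen_t)B *
        ((R_xlen_t)Cout * (od2 + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow)));
      double *gc = G.colptr(jj);
      for (int co = 0; co < Cout; ++co) gc[co] = src[(R_xlen_t)B * co];
      if (has_bias) for (int co = 0; co < Cout; ++co) dbp[co] += gc[co];
    }
    dWm += col.cols(0, n - 1) * G.cols(0, n - 1).t();
    dcol = Wm * G.cols(0, n - 1);             // [rows, n]
    // scatter-add patch gradients back to input positions
    for (R_xlen_t jj = 0; jj < n; ++jj) {
      const R_xlen_t j = j0 + jj;
      const int b = (int)(j % B);
      const int od2 = (int)((j / B) % Do);
      const int oh = (int)((j / BD) % Ho);
      const int ow = (int)(j / BDH);
      const int id0 = od2 * stride - pad, ih0 = oh * stride - pad,
                iw0 = ow * stride - pad;
      const double *cp = dcol.colptr(jj);
      R_xlen_t r = 0;
      for (int ci = 0; ci < C; ++ci) {
        double *xc = dxp + (R_xlen_t)B * ci + b;
        for (int kw = 0; kw < K; ++kw) {
          const int iw = iw0 + kw;
          const bool wok = iw >= 0 && iw < W;
          for (int kh = 0; kh < K; ++kh) {
            const int ih = ih0 + kh;
            const bool hok = wok && ih >= 0 && ih < H;
            const R_xlen_t base = (R_xlen_t)B * C * ((R_xlen_t)D * (ih + (R_xlen_t)H * iw));
            for (int kd = 0; kd < K; ++kd, ++r) {
              const int id = id0 + kd;
              if (hok && id >= 0 && id < D)
                xc[base + (R_xlen_t)B * C * id] += cp[r];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool3d_fwd_cpp")]]
List maxpool3d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int B = xd[0], C = xd[1], D = xd[2], H = xd[3], W = xd[4];
  const int Do = out_size(D, k, stride, pad), Ho = out_size(H, k, stride, pad),
            Wo = out_size(W, k, stride, pad);
  NumericVector out((R_xlen_t)B * C * Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(B, C, Do, Ho, Wo);
  IntegerVector amax(out.size());  // 0-based linear index into x
  const double *xp = x.begin();
  double *op = out.begin();
  int *ap = amax.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od)
        for (int c = 0; c < C; ++c)
          for (int b = 0; b < B; ++b) {
            double best = R_NegInf; R_xlen_t bi = -1;
            for (int kw = 0; kw < k; ++kw) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  const int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  const R_xlen_t xi = b + (R_xlen_t)B * (c + (R_xlen_t)C * (id + (R_xlen_t)D * (ih + (R_xlen_t)H * iw)));
                  if (xp[xi] > best) { best = xp[xi]; bi = xi; }
                }
              }
            }
            const R_xlen_t oi = b + (R_xlen_t)B * (c + (R_xlen_t)C * (od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow)));
            op[oi] = best; ap[oi] = (int)bi;
          }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool3d_bwd_cpp")]]
NumericVector maxpool3d_bwd_cpp(IntegerVector argmax, NumericVector dout,
                                IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n); dx.attr("dim") = xdim;
  double *dxp = dx.begin();
  const double *gp = dout.begin();
  const int *ap = argmax.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) dxp[ap[i]] += gp[i];
  return dx;
}
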
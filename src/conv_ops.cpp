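// Minimal CPU engine for the convolutional feature extractors.
// Tensors are arma::cube with layout (row, col, channel); weights arrive as a
// flat vector with dim attribute (k, k, in_per_group, out_channels).
// Forward uses im2col + BLAS GEMM; backward w.r.t. the input is the direct
// scatter of the chain rule (used by the ERF probe, not on a training path).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d (row, col, channel) array");
  arma::cube out(REAL(x), d[0], d[1], d[2]);
  return out;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x_, NumericVector w_, NumericVector bias,
                         int stride, int pad, int groups) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (k, k, in_per_group, out)");
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  if (wd[1] != k) stop("kernels must be square");
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  if (Cin != cin_g * groups) stop("input channels do not match weight shape/groups");
  if (cout % groups != 0) stop("out channels not divisible by groups");
  const int cout_g = cout / groups;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::cube wt(REAL(w_), k * k * cin_g, cout, 1, false);
  arma::cube out(Ho, Wo, cout, arma::fill::zeros);
  arma::mat col(Ho * Wo, k * k * cin_g);

  for (int g = 0; g < groups; ++g) {
    // im2col for this group's input slab
    for (int c = 0; c < cin_g; ++c) {
      const arma::mat& xs = x.slice(g * cin_g + c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int colidx = c * k * k + kj * k + ki;
          double* dst = col.colptr(colidx);
          for (int oj = 0; oj < Wo; ++oj) {
            const int ij = oj * stride - pad + kj;
            const bool jok = (ij >= 0 && ij < W);
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride - pad + ki;
              dst[oj * Ho + oi] =
                  (jok && ii >= 0 && ii < H) ? xs(ii, ij) : 0.0;
            }
          }
        }
      }
    }
    arma::mat wg(wt.slice(0).colptr(g * cout_g), k * k * cin_g, cout_g, false);
    arma::mat y = col * wg;  // (Ho*Wo) x cout_g
    for (int c = 0; c < cout_g; ++c) {
      arma::mat ys(y.colptr(c), Ho, Wo, false);
      out.slice(g * cout_g + c) = ys + bias[g * cout_g + c];
    }
  }

  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  return res;
}

// [[Rcpp::export(name = ".conv2d_bwd_input")]]
NumericVector conv2d_bwd_input(NumericVector g_, NumericVector w_, int stride,
                               int pad, int groups, int Hin, int Win) {
  arma::cube gout = as_cube(g_);
  IntegerVector wd = w_.attr("dim");
  const int k = wd[0], cin_g = wd[2], cout = wd[3];
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  if ((int)gout.n_slices != cout) stop("gradient channels do not match weights");
  const int cout_g = cout / groups;
  arma::cube w(REAL(w_), (size_t)(k * k * cin_g), (size_t)cout, 1, false);
  arma::cube gin(Hin, Win, cin_g * groups, arma::fill::zeros);

  for (int g = 0; g < groups; ++g) {
    for (int co = 0; co < cout_g; ++co) {
      const arma::mat& gs = gout.slice(g * cout_g + co);
      const double* wcol = w.slice(0).colptr(g * cout_g + co);
      for (int c = 0; c < cin_g; ++c) {
        arma::mat& gi = gin.slice(g * cin_g + c);
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const double wv = wcol[c * k * k + kj * k + ki];
            if (wv == 0.0) continue;
            for (int oj = 0; oj < Wo; ++oj) {
              const int ij = oj * stride - pad + kj;
              if (ij < 0 || ij >= Win) continue;
              for (int oi = 0; oi < Ho; ++oi) {
                const int ii = oi * stride - pad + ki;
                if (ii < 0 || ii >= Hin) continue;
                gi(ii, ij) += wv * gs(oi, oj);
              }
            }
          }
        }
      }
    }
  }
  NumericVector res(gin.begin(), gin.end());
  res.attr("dim") = IntegerVector::create(Hin, Win, cin_g * groups);
  return res;
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x_, int k, int stride) {
  arma::cube x = as_cube(x_);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("pool window larger than input");
  arma::cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);  // 0-based linear index into x
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -std::numeric_limits<double>::infinity();
        int besti = 0, bestj = 0;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int ii = oi * stride + ki, ij = oj * stride + kj;
            const double v = xs(ii, ij);
            if (v > best) { best = v; besti = ii; bestj = ij; }
          }
        }
        out(oi, oj, c) = best;
        idx[c * Ho * Wo + oj * Ho + oi] = c * H * W + bestj * H + besti;
      }
    }
  }
  NumericVector o(out.begin(), out.end());
  o.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = o, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector g_, IntegerVector idx, int Hin,
                          int Win, int C) {
  NumericVector gin(Hin * Win * C);
  const int n = g_.size();
  for (int i = 0; i < n; ++i) gin[idx[i]] += g_[i];
  gin.attr("dim") = IntegerVector::create(Hin, Win, C);
  return gin;
}
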
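// Numerical kernels for the density-map network. Arrays follow R's
// column-major layout: images/feature maps are (H, W, C, B), conv weights
// are (k, k, Cin, Cout). Everything is deterministic (no threading).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dim4(const NumericVector& x, int& H, int& W, int& C, int& B) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, B)");
  H = d[0]; W = d[1]; C = d[2]; B = d[3];
}

// Column q of the patch matrix corresponds to (ci, dx, dy) with dy fastest,
// matching the layout of an R weight array of dim (k, k, Cin, Cout).
static arma::mat im2col(const double* xp, int H, int W, int Ci, int k) {
  int pad = k / 2;
  arma::mat M(H * W, (size_t)k * k * Ci);
  int q = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy, ++q) {
        double* col = M.colptr(q);
        int oy = dy - pad, ox = dx - pad;
        for (int c = 0; c < W; ++c) {
          int sc = c + ox;
          double* dst = col + (size_t)c * H;
          if (sc < 0 || sc >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xp + ((size_t)ci * W + sc) * H;
          for (int r = 0; r < H; ++r) {
            int sr = r + oy;
            dst[r] = (sr >= 0 && sr < H) ? src[sr] : 0.0;
          }
        }
      }
    }
  }
  return M;
}

static void col2im_acc(const arma::mat& M, double* xp, int H, int W, int Ci,
                       int k) {
  int pad = k / 2;
  int q = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy, ++q) {
        const double* col = M.colptr(q);
        int oy = dy - pad, ox = dx - pad;
        for (int c = 0; c < W; ++c) {
          int sc = c + ox;
          if (sc < 0 || sc >= W) continue;
          double* dst = xp + ((size_t)ci * W + sc) * H;
          const double* src = col + (size_t)c * H;
          for (int r = 0; r < H; ++r) {
            int sr = r + oy;
            if (sr >= 0 && sr < H) dst[sr] += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b) {
  int H, W, Ci, B;
  get_dim4(x, H, W, Ci, B);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Co = wd[3];
  if (wd[2] != Ci) stop("weight Cin does not match input");
  arma::mat Wm(w.begin(), (size_t)k * k * Ci, Co, false);
  arma::rowvec bv(b.begin(), Co);
  NumericVector y((size_t)H * W * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  for (int s = 0; s < B; ++s) {
    arma::mat M = im2col(x.begin() + (size_t)s * H * W * Ci, H, W, Ci, k);
    arma::mat Y = M * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)s * H * W * Co);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Ci, B;
  get_dim4(x, H, W, Ci, B);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Co = wd[3];
  arma::mat Wm(w.begin(), (size_t)k * k * Ci, Co, false);
  NumericVector dx((size_t)H * W * Ci * B);
  dx.attr("dim") = IntegerVector::create(H, W, Ci, B);
  arma::mat dW((size_t)k * k * Ci, Co, arma::fill::zeros);
  arma::rowvec db(Co, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    arma::mat M = im2col(x.begin() + (size_t)s * H * W * Ci, H, W, Ci, k);
    arma::mat dY(dy.begin() + (size_t)s * H * W * Co, H * W, Co, false);
    dW += M.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();
    col2im_acc(dM, dx.begin() + (size_t)s * H * W * Ci, H, W, Ci, k);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Batch normalization over (H, W, B) per channel. In training mode returns
// batch statistics and momentum-updated running statistics; in eval mode
// normalizes with the supplied running statistics.
// [[Rcpp::export]]
List bn_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector running_mean, NumericVector running_var,
                    bool training, double eps, double momentum) {
  int H, W, C, B;
  get_dim4(x, H, W, C, B);
  size_t plane = (size_t)H * W;
  double n = (double)plane * B;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  NumericVector mean(C), invstd(C), new_rm(clone(running_mean)),
      new_rv(clone(running_var));
  for (int c = 0; c < C; ++c) {
    double m = 0, v = 0;
    if (training) {
      for (int s = 0; s < B; ++s) {
        const double* p = x.begin() + ((size_t)s * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) m += p[i];
      }
      m /= n;
      for (int s = 0; s < B; ++s) {
        const double* p = x.begin() + ((size_t)s * C + c) * plane;
        for (size_t i = 0; i < plane; ++i) {
          double d = p[i] - m;
          v += d * d;
        }
      }
      v /= n;
      new_rm[c] = (1 - momentum) * running_mean[c] + momentum * m;
      double vu = (n > 1) ? v * n / (n - 1) : v;
      new_rv[c] = (1 - momentum) * running_var[c] + momentum * vu;
    } else {
      m = running_mean[c];
      v = running_var[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m;
    invstd[c] = is;
    double g = gamma[c], bt = beta[c];
    for (int s = 0; s < B; ++s) {
      const double* p = x.begin() + ((size_t)s * C + c) * plane;
      double* q = y.begin() + ((size_t)s * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) q[i] = g * (p[i] - m) * is + bt;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector x, NumericVector gamma, NumericVector mean,
                     NumericVector invstd, NumericVector dy) {
  int H, W, C, B;
  get_dim4(x, H, W, C, B);
  size_t plane = (size_t)H * W;
  double n = (double)plane * B;
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double m = mean[c], is = invstd[c], g = gamma[c];
    double sdy = 0, sdyx = 0;
    for (int s = 0; s < B; ++s) {
      const double* px = x.begin() + ((size_t)s * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)s * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - m) * is;
        sdy += pd[i];
        sdyx += pd[i] * xh;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    double f = g * is / n;
    for (int s = 0; s < B; ++s) {
      const double* px = x.begin() + ((size_t)s * C + c) * plane;
      const double* pd = dy.begin() + ((size_t)s * C + c) * plane;
      double* q = dx.begin() + ((size_t)s * C + c) * plane;
      for (size_t i = 0; i < plane; ++i) {
        double xh = (px[i] - m) * is;
        q[i] = f * (n * pd[i] - sdy - xh * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 max pooling, stride 2; ties resolved toward the earliest candidate in
// scan order so the backward pass is deterministic.
// [[Rcpp::export]]
List maxpool2_forward_cpp(NumericVector x) {
  int H, W, C, B;
  get_dim4(x, H, W, C, B);
  if (H % 2 || W % 2) stop("maxpool2 requires even H and W");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(y.size());
  size_t o = 0;
  for (int s = 0; s < B; ++s) {
    for (int c = 0; c < C; ++c) {
      size_t base = ((size_t)s * C + c) * H * W;
      for (int co = 0; co < Wo; ++co) {
        for (int ro = 0; ro < Ho; ++ro, ++o) {
          size_t i00 = base + (size_t)(2 * co) * H + 2 * ro;
          size_t cand[4] = {i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          size_t best = cand[0];
          double bv = x[cand[0]];
          for (int t = 1; t < 4; ++t)
            if (x[cand[t]] > bv) {
              bv = x[cand[t]];
              best = cand[t];
            }
          y[o] = bv;
          idx[o] = (int)best;  // safe: desk-scale arrays < 2^31
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward_cpp(IntegerVector idx, NumericVector dy,
                                    IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2_forward_cpp(NumericVector x) {
  int H, W, C, B;
  get_dim4(x, H, W, C, B);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)s * C + c) * H * W;
      double* q = y.begin() + ((size_t)s * C + c) * Ho * Wo;
      for (int cc = 0; cc < W; ++cc)
        for (int r = 0; r < H; ++r) {
          double v = p[(size_t)cc * H + r];
          size_t o = (size_t)(2 * cc) * Ho + 2 * r;
          q[o] = v;
          q[o + 1] = v;
          q[o + Ho] = v;
          q[o + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward_cpp(NumericVector dy) {
  int Ho, Wo, C, B;
  get_dim4(dy, Ho, Wo, C, B);
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* q = dy.begin() + ((size_t)s * C + c) * Ho * Wo;
      double* p = dx.begin() + ((size_t)s * C + c) * H * W;
      for (int cc = 0; cc < W; ++cc)
        for (int r = 0; r < H; ++r) {
          size_t o = (size_t)(2 * cc) * Ho + 2 * r;
          p[(size_t)cc * H + r] = q[o] + q[o + 1] + q[o + Ho] + q[o + Ho + 1];
        }
    }
  return dx;
}
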
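// Compact convolutional network for single-cell phase crops.
//
// Architecture: 3 x [3x3 conv (pad 1) -> ReLU -> 2x2 max-pool], channel
// widths given by `channels`, global average pool, single linear output,
// sigmoid. Trained with Adam on binary cross-entropy. All randomness
// (weight init, shuffling) is supplied by the caller so training is a
// deterministic function of its arguments.
//
// Activations are stored as (C, H*W*B) matrices: column index =
// b * H*W + position, position in column-major (row fastest) order of the
// H x W grid. Convolution = GEMM of (C_out, C_in*9) weights with an
// im2col matrix (C_in*9, H*W*B).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// neighbour map for a 3x3 window with pad 1 on an H x W grid:
// nbr(k, pos) = source position for tap k, or -1 outside the grid.
static imat make_nbr(int H, int W) {
  imat nbr(9, H * W);
  for (int cw = 0; cw < W; ++cw) {
    for (int rh = 0; rh < H; ++rh) {
      int pos = cw * H + rh;
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr, ++k) {
          int r2 = rh + dr, c2 = cw + dc;
          nbr(k, pos) =
              (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) ? -1 : c2 * H + r2;
        }
      }
    }
  }
  return nbr;
}

static mat im2col(const mat& A, int C, int HW, int B, const imat& nbr) {
  mat out(C * 9, HW * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    int off = b * HW;
    for (int pos = 0; pos < HW; ++pos) {
      int col = off + pos;
      for (int k = 0; k < 9; ++k) {
        long sp = nbr(k, pos);
        if (sp >= 0) {
          for (int c = 0; c < C; ++c) out(c * 9 + k, col) = A(c, off + sp);
        }
      }
    }
  }
  return out;
}

static mat col2im(const mat& dcol, int C, int HW, int B, const imat& nbr) {
  mat dA(C, HW * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    int off = b * HW;
    for (int pos = 0; pos < HW; ++pos) {
      int col = off + pos;
      for (int k = 0; k < 9; ++k) {
        long sp = nbr(k, pos);
        if (sp >= 0) {
          for (int c = 0; c < C; ++c) dA(c, off + sp) += dcol(c * 9 + k, col);
        }
      }
    }
  }
  return dA;
}

// 2x2 max-pool H x W -> H/2 x W/2; records argmax for backward.
static mat maxpool(const mat& A, int C, int H, int W, int B, umat& arg) {
  int Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  mat out(C, HWo * B);
  arg.set_size(C, HWo * B);
  for (int b = 0; b < B; ++b) {
    for (int cw = 0; cw < Wo; ++cw) {
      for (int rh = 0; rh < Ho; ++rh) {
        int opos = b * HWo + cw * Ho + rh;
        int base = b * HW + (2 * cw) * H + 2 * rh;
        int cand[4] = {base, base + 1, base + H, base + H + 1};
        for (int c = 0; c < C; ++c) {
          int best = cand[0];
          double bv = A(c, cand[0]);
          for (int k = 1; k < 4; ++k) {
            if (A(c, cand[k]) > bv) { bv = A(c, cand[k]); best = cand[k]; }
          }
          out(c, opos) = bv;
          arg(c, opos) = best;
        }
      }
    }
  }
  return out;
}

struct Net {
  mat W1, W2, W3;
  vec b1, b2, b3, w4;
  double b4;
  int C1, C2, C3, side;
};

static Net net_from_list(const Rcpp::List& wts, int side) {
  Net n;
  n.W1 = Rcpp::as<mat>(wts["W1"]);
  n.b1 = Rcpp::as<vec>(wts["b1"]);
  n.W2 = Rcpp::as<mat>(wts["W2"]);
  n.b2 = Rcpp::as<vec>(wts["b2"]);
  n.W3 = Rcpp::as<mat>(wts["W3"]);
  n.b3 = Rcpp::as<vec>(wts["b3"]);
  n.w4 = Rcpp::as<vec>(wts["w4"]);
  n.b4 = Rcpp::as<double>(wts["b4"]);
  n.C1 = n.W1.n_rows; n.C2 = n.W2.n_rows; n.C3 = n.W3.n_rows;
  n.side = side;
  return n;
}

struct Cache {
  mat col1, col2, col3;       // im2col inputs of each conv
  mat a1, a2, a3;             // post-ReLU activations
  mat p1, p2, p3;             // post-pool activations
  umat arg1, arg2, arg3;
  mat gap;                    // (C3, B)
  vec z;                      // logits (B)
};

static vec forward(const Net& n, const mat& X0, int B, const imat& nbr1,
                   const imat& nbr2, const imat& nbr3, Cache* cache) {
  int S = n.side, HW1 = S * S;
  int S2 = S / 2, HW2 = S2 * S2;
  int S3 = S / 4, HW3 = S3 * S3;
  int S4 = S / 8, HW4 = S4 * S4;

  mat col1 = im2col(X0, 1, HW1, B, nbr1);
  mat a1 = n.W1 * col1;
  a1.each_col() += n.b1;
  a1.transform([](double v) { return v > 0 ? v : 0.0; });
  umat arg1;
  mat p1 = maxpool(a1, n.C1, S, S, B, arg1);

  mat col2 = im2col(p1, n.C1, HW2, B, nbr2);
  mat a2 = n.W2 * col2;
  a2.each_col() += n.b2;
  a2.transform([](double v) { return v > 0 ? v : 0.0; });
  umat arg2;
  mat p2 = maxpool(a2, n.C2, S2, S2, B, arg2);

  mat col3 = im2col(p2, n.C2, HW3, B, nbr3);
  mat a3 = n.W3 * col3;
  a3.each_col() += n.b3;
  a3.transform([](double v) { return v > 0 ? v : 0.0; });
  umat arg3;
  mat p3 = maxpool(a3, n.C3, S3, S3, B, arg3);

  mat gap(n.C3, B);
  for (int b = 0; b < B; ++b) {
    gap.col(b) = mean(p3.cols(b * HW4, (b + 1) * HW4 - 1), 1);
  }
  vec z = gap.t() * n.w4 + n.b4;

  if (cache) {
    cache->col1 = std::move(col1); cache->col2 = std::move(col2);
    cache->col3 = std::move(col3);
    cache->a1 = std::move(a1); cache->a2 = std::move(a2);
    cache->a3 = std::move(a3);
    cache->p1 = std::move(p1); cache->p2 = std::move(p2);
    cache->p3 = std::move(p3);
    cache->arg1 = std::move(arg1); cache->arg2 = std::move(arg2);
    cache->arg3 = std::move(arg3);
    cache->gap = std::move(gap);
    cache->z = z;
  }
  return z;
}

struct Grads {
  mat W1, W2, W3;
  vec b1, b2, b3, w4;
  double b4;
};

static Grads backward(const Net& n, const Cache& c, const vec& y, int B,
                      const imat& nbr2, const imat& nbr3) {
  int S = n.side;
  int S2 = S / 2, HW2 = S2 * S2;
  int S3 = S / 4, HW3 = S3 * S3;
  int S4 = S / 8, HW4 = S4 * S4;
  Grads g;

  // dL/dz for sigmoid + BCE, mean over batch
  vec p = 1.0 / (1.0 + exp(-c.z));
  vec dz = (p - y) / (double)B;

  g.w4 = c.gap * dz;
  g.b4 = accu(dz);
  mat dgap = n.w4 * dz.t();  // (C3, B)

  mat dp3(n.C3, HW4 * B);
  for (int b = 0; b < B; ++b) {
    for (int pos = 0; pos < HW4; ++pos) {
      dp3.col(b * HW4 + pos) = dgap.col(b) / (double)HW4;
    }
  }
  mat da3(n.C3, HW3 * B, fill::zeros);
  for (uword j = 0; j < dp3.n_cols; ++j) {
    for (int ch = 0; ch < n.C3; ++ch) {
      da3(ch, c.arg3(ch, j)) += dp3(ch, j);
    }
  }
  da3 %= conv_to<mat>::from(c.a3 > 0);
  g.W3 = da3 * c.col3.t();
  g.b3 = sum(da3, 1);
  mat dp2 = col2im(n.W3.t() * da3, n.C2, HW3, B, nbr3);

  mat da2(n.C2, HW2 * B, fill::zeros);
  for (uword j = 0; j < dp2.n_cols; ++j) {
    for (int ch = 0; ch < n.C2; ++ch) {
      da2(ch, c.arg2(ch, j)) += dp2(ch, j);
    }
  }
  da2 %= conv_to<mat>::from(c.a2 > 0);
  g.W2 = da2 * c.col2.t();
  g.b2 = sum(da2, 1);
  mat dp1 = col2im(n.W2.t() * da2, n.C1, HW2, B, nbr2);

  int HW1s = S * S;
  mat da1(n.C1, HW1s * B, fill::zeros);
  for (uword j = 0; j < dp1.n_cols; ++j) {
    for (int ch = 0; ch < n.C1; ++ch) {
      da1(ch, c.arg1(ch, j)) += dp1(ch, j);
    }
  }
  da1 %= conv_to<mat>::from(c.a1 > 0);
  g.W1 = da1 * c.col1.t();
  g.b1 = sum(da1, 1);
  return g;
}

struct AdamState {
  mat mW1, vW1, mW2, vW2, mW3, vW3;
  vec mb1, vb1, mb2, vb2, mb3, vb3, mw4, vw4;
  double mb4 = 0, vb4 = 0;
  long t = 0;
};

static void adam_update(mat& w, mat& m, mat& v, const mat& g, double lr,
                        double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * square(g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}

static void adam_update(vec& w, vec& m, vec& v, const vec& g, double lr,
                        double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * square(g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}

// Loss and analytic gradients on one batch; used for gradient checking.
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List weights, const arma::mat& X,
                             const arma::vec& y, int side) {
  Net n = net_from_list(weights, side);
  int B = X.n_rows, HW = side * side;
  imat nbr1 = make_nbr(side, side);
  imat nbr2 = make_nbr(side / 2, side / 2);
  imat nbr3 = make_nbr(side / 4, side / 4);
  mat X0(1, HW * B);
  for (int b = 0; b < B; ++b) {
    X0.cols(b * HW, (b + 1) * HW - 1) = X.row(b);
  }
  Cache cache;
  vec z = forward(n, X0, B, nbr1, nbr2, nbr3, &cache);
  double loss = 0;
  for (int b = 0; b < B; ++b) {
    double zz = z(b);
    loss += std::max(zz, 0.0) - zz * y(b) +
            std::log1p(std::exp(-std::fabs(zz)));
  }
  loss /= (double)B;
  Grads g = backward(n, cache, y, B, nbr2, nbr3);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("W1") = g.W1, Rcpp::Named("b1") = g.b1,
      Rcpp::Named("W2") = g.W2, Rcpp::Named("b2") = g.b2,
      Rcpp::Named("W3") = g.W3, Rcpp::Named("b3") = g.b3,
      Rcpp::Named("w4") = g.w4, Rcpp::Named("b4") = g.b4);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::vec& y, int side,
                         Rcpp::List weights, int epochs, int batch,
                         double lr, const arma::imat& perm) {
  Net n = net_from_list(weights, side);
  int N = X.n_rows;
  imat nbr1 = make_nbr(side, side);
  imat nbr2 = make_nbr(side / 2, side / 2);
  imat nbr3 = make_nbr(side / 4, side / 4);

  AdamState st;
  st.mW1 = zeros(size(n.W1)); st.vW1 = st.mW1;
  st.mW2 = zeros(size(n.W2)); st.vW2 = st.mW2;
  st.mW3 = zeros(size(n.W3)); st.vW3 = st.mW3;
  st.mb1 = zeros(size(n.b1)); st.vb1 = st.mb1;
  st.mb2 = zeros(size(n.b2)); st.vb2 = st.mb2;
  st.mb3 = zeros(size(n.b3)); st.vb3 = st.mb3;
  st.mw4 = zeros(size(n.w4)); st.vw4 = st.mw4;

  vec epoch_loss(epochs, fill::zeros);
  int HW = side * side;

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0;
    long seen = 0;
    for (int start = 0; start < N; start += batch) {
      int B = std::min(batch, N - start);
      mat X0(1, HW * B);
      vec yb(B);
      for (int b = 0; b < B; ++b) {
        int i = perm(e, start + b);
        X0.cols(b * HW, (b + 1) * HW - 1) = X.row(i);
        yb(b) = y(i);
      }
      Cache cache;
      vec z = forward(n, X0, B, nbr1, nbr2, nbr3, &cache);
      // numerically safe BCE-with-logits
      for (int b = 0; b < B; ++b) {
        double zz = z(b);
        loss_sum += std::max(zz, 0.0) - zz * yb(b) + std::log1p(std::exp(-std::fabs(zz)));
      }
      seen += B;
      Grads g = backward(n, cache, yb, B, nbr2, nbr3);

      st.t += 1;
      double bc1 = 1.0 - std::pow(0.9, (double)st.t);
      double bc2 = 1.0 - std::pow(0.999, (double)st.t);
      adam_update(n.W1, st.mW1, st.vW1, g.W1, lr, bc1, bc2);
      adam_update(n.W2, st.mW2, st.vW2, g.W2, lr, bc1, bc2);
      adam_update(n.W3, st.mW3, st.vW3, g.W3, lr, bc1, bc2);
      adam_update(n.b1, st.mb1, st.vb1, g.b1, lr, bc1, bc2);
      adam_update(n.b2, st.mb2, st.vb2, g.b2, lr, bc1, bc2);
      adam_update(n.b3, st.mb3, st.vb3, g.b3, lr, bc1, bc2);
      adam_update(n.w4, st.mw4, st.vw4, g.w4, lr, bc1, bc2);
      st.mb4 = 0.9 * st.mb4 + 0.1 * g.b4;
      st.vb4 = 0.999 * st.vb4 + 0.001 * g.b4 * g.b4;
      n.b4 -= lr * (st.mb4 / bc1) / (std::sqrt(st.vb4 / bc2) + 1e-8);
    }
    epoch_loss(e) = loss_sum / (double)seen;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
      Rcpp::Named("w4") = n.w4, Rcpp::Named("b4") = n.b4,
      Rcpp::Named("epoch_loss") = epoch_loss);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(Rcpp::List weights, const arma::mat& X, int side,
                          int batch) {
  Net n = net_from_list(weights, side);
  int N = X.n_rows, HW = side * side;
  imat nbr1 = make_nbr(side, side);
  imat nbr2 = make_nbr(side / 2, side / 2);
  imat nbr3 = make_nbr(side / 4, side / 4);
  vec out(N);
  for (int start = 0; start < N; start += batch) {
    int B = std::min(batch, N - start);
    mat X0(1, HW * B);
    for (int b = 0; b < B; ++b) {
      X0.cols(b * HW, (b + 1) * HW - 1) = X.row(start + b);
    }
    vec z = forward(n, X0, B, nbr1, nbr2, nbr3, nullptr);
    out.subvec(start, start + B - 1) = 1.0 / (1.0 + exp(-z));
    Rcpp::checkUserInterrupt();
  }
  return out;
}
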
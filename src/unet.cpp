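// Encoder-decoder residual segmentation network: forward pass,
// reverse-mode gradients and Adam updates. Tensors are arma::mat with
// one pixel per row (column-major pixel index p = i + j*h) and one
// channel per column. Convolutions are im2col + BLAS GEMM.
// The graph is built in R (see R/unet.R) as a flat op tape; ops:
//   1 conv (k=1|3, same zero padding)   2 relu   3 add
//   4 maxpool 2x2   5 upsample nearest 2x   6 concat channels
//   7 sigmoid
// All computation is double precision and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Op {
  int type;
  int in1, in2;    // 0-based tensor ids (tensor 0 = network input)
  int k, cin, cout;
  int h, w;        // spatial size of the op's OUTPUT
  int poff;        // 0-based offset of weights in the flat parameter vector
};

std::vector<Op> parse_graph(const List& graph) {
  List ops = graph["ops"];
  std::vector<Op> out(ops.size());
  for (int i = 0; i < ops.size(); ++i) {
    List o = ops[i];
    Op& p = out[i];
    p.type = as<int>(o["type"]);
    p.in1  = as<int>(o["in1"]);
    p.in2  = o.containsElementNamed("in2") && !Rf_isNull(o["in2"]) ? as<int>(o["in2"]) : -1;
    p.k    = o.containsElementNamed("k")    ? as<int>(o["k"])    : 0;
    p.cin  = o.containsElementNamed("cin")  ? as<int>(o["cin"])  : 0;
    p.cout = o.containsElementNamed("cout") ? as<int>(o["cout"]) : 0;
    p.h    = as<int>(o["h"]);
    p.w    = as<int>(o["w"]);
    p.poff = o.containsElementNamed("poff") ? as<int>(o["poff"]) : 0;
  }
  return out;
}

// offsets for a k x k kernel, row-major over (di, dj)
inline void kernel_offset(int k, int o, int& di, int& dj) {
  int r = k / 2;
  di = o % k - r;
  dj = o / k - r;
}

// X: (h*w, cin) -> col: (h*w, cin*k*k), zero padded
arma::mat im2col(const arma::mat& X, int h, int w, int cin, int k) {
  arma::mat col(static_cast<arma::uword>(h) * w, static_cast<arma::uword>(cin) * k * k,
                arma::fill::zeros);
  if (k == 1) { col = X; return col; }
  for (int c = 0; c < cin; ++c) {
    for (int o = 0; o < k * k; ++o) {
      int di, dj; kernel_offset(k, o, di, dj);
      arma::uword tc = static_cast<arma::uword>(c) * k * k + o;
      int i0 = std::max(0, -di), i1 = std::min(h - 1, h - 1 - di);
      if (i0 > i1) continue;
      for (int j = 0; j < w; ++j) {
        int jj = j + dj;
        if (jj < 0 || jj >= w) continue;
        arma::uword tbase = static_cast<arma::uword>(j) * h;
        arma::uword sbase = static_cast<arma::uword>(jj) * h;
        col.col(tc).subvec(tbase + i0, tbase + i1) =
          X.col(c).subvec(sbase + i0 + di, sbase + i1 + di);
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col: dcol (h*w, cin*k*k) -> dX (h*w, cin)
void col2im_add(const arma::mat& dcol, int h, int w, int cin, int k, arma::mat& dX) {
  if (k == 1) { dX += dcol; return; }
  for (int c = 0; c < cin; ++c) {
    for (int o = 0; o < k * k; ++o) {
      int di, dj; kernel_offset(k, o, di, dj);
      arma::uword tc = static_cast<arma::uword>(c) * k * k + o;
      int i0 = std::max(0, -di), i1 = std::min(h - 1, h - 1 - di);
      if (i0 > i1) continue;
      for (int j = 0; j < w; ++j) {
        int jj = j + dj;
        if (jj < 0 || jj >= w) continue;
        arma::uword tbase = static_cast<arma::uword>(j) * h;
        arma::uword sbase = static_cast<arma::uword>(jj) * h;
        dX.col(c).subvec(sbase + i0 + di, sbase + i1 + di) +=
          dcol.col(tc).subvec(tbase + i0, tbase + i1);
      }
    }
  }
}

struct Workspace {
  std::vector<arma::mat>  acts;   // acts[t] = tensor t (t = op index + 1)
  std::vector<arma::mat>  cols;   // cached im2col per conv op
  std::vector<arma::umat> amax;   // argmax rows per maxpool op
};

// forward pass; X is (h0*w0, 1)
void forward(const std::vector<Op>& ops, const double* par, const arma::mat& X,
             int h0, int w0, Workspace& ws, bool keep_cols) {
  size_t n = ops.size();
  ws.acts.assign(n + 1, arma::mat());
  ws.cols.assign(n, arma::mat());
  ws.amax.assign(n, arma::umat());
  ws.acts[0] = X;
  for (size_t i = 0; i < n; ++i) {
    const Op& op = ops[i];
    const arma::mat& A = ws.acts[op.in1];
    arma::mat& Y = ws.acts[i + 1];
    switch (op.type) {
      case 1: {  // conv
        arma::mat col = im2col(A, op.h, op.w, op.cin, op.k);
        const arma::mat W(const_cast<double*>(par + op.poff),
                          static_cast<arma::uword>(op.cin) * op.k * op.k, op.cout,
                          false, true);
        const arma::rowvec b(const_cast<double*>(par + op.poff +
                             static_cast<long>(op.cin) * op.k * op.k * op.cout),
                             op.cout, false, true);
        Y = col * W;
        Y.each_row() += b;
        if (keep_cols) ws.cols[i] = std::move(col);
        break;
      }
      case 2: Y = arma::clamp(A, 0.0, arma::datum::inf); break;
      case 3: Y = A + ws.acts[op.in2]; break;
      case 4: {  // maxpool 2x2
        int h2 = op.h, w2 = op.w, h = 2 * h2;
        Y.set_size(static_cast<arma::uword>(h2) * w2, A.n_cols);
        ws.amax[i].set_size(Y.n_rows, A.n_cols);
        for (arma::uword c = 0; c < A.n_cols; ++c) {
          for (int j2 = 0; j2 < w2; ++j2) {
            for (int i2 = 0; i2 < h2; ++i2) {
              arma::uword p00 = 2 * i2 + static_cast<arma::uword>(2 * j2) * h;
              arma::uword idx[4] = {p00, p00 + 1, p00 + h, p00 + h + 1};
              double best = A(idx[0], c); arma::uword bi = idx[0];
              for (int q = 1; q < 4; ++q)
                if (A(idx[q], c) > best) { best = A(idx[q], c); bi = idx[q]; }
              arma::uword po = i2 + static_cast<arma::uword>(j2) * h2;
              Y(po, c) = best;
              ws.amax[i](po, c) = bi;
            }
          }
        }
        break;
      }
      case 5: {  // nearest-neighbour upsample 2x
        int h2 = op.h, w2 = op.w, h = h2 / 2;
        Y.set_size(static_cast<arma::uword>(h2) * w2, A.n_cols);
        for (arma::uword c = 0; c < A.n_cols; ++c)
          for (int j2 = 0; j2 < w2; ++j2)
            for (int i2 = 0; i2 < h2; ++i2)
              Y(i2 + static_cast<arma::uword>(j2) * h2, c) =
                A(i2 / 2 + static_cast<arma::uword>(j2 / 2) * h, c);
        break;
      }
      case 6: Y = arma::join_rows(A, ws.acts[op.in2]); break;
      case 7: Y = 1.0 / (1.0 + arma::exp(-A)); break;
      default: stop("unknown op type");
    }
  }
}

// reverse pass; dLast = dL/d(final output); accumulates into gpar
void backward(const std::vector<Op>& ops, const double* par, Workspace& ws,
              const arma::mat& dLast, double* gpar) {
  size_t n = ops.size();
  std::vector<arma::mat> grads(n + 1);
  grads[n] = dLast;
  for (size_t ii = n; ii-- > 0;) {
    const Op& op = ops[ii];
    arma::mat& dY = grads[ii + 1];
    if (dY.is_empty()) continue;
    auto acc = [&](int t, const arma::mat& g) {
      if (grads[t].is_empty()) grads[t] = g; else grads[t] += g;
    };
    switch (op.type) {
      case 1: {
        const arma::mat& col = ws.cols[ii];
        arma::uword kr = static_cast<arma::uword>(op.cin) * op.k * op.k;
        const arma::mat W(const_cast<double*>(par + op.poff), kr, op.cout, false, true);
        arma::mat dW_m(gpar + op.poff, kr, op.cout, false, true);
        arma::rowvec db_m(gpar + op.poff + kr * op.cout, op.cout, false, true);
        dW_m += col.t() * dY;
        db_m += arma::sum(dY, 0);
        arma::mat dcol = dY * W.t();
        arma::mat dX(col.n_rows, op.cin, arma::fill::zeros);
        col2im_add(dcol, op.h, op.w, op.cin, op.k, dX);
        acc(op.in1, dX);
        break;
      }
      case 2: acc(op.in1, dY % (ws.acts[ii + 1] > 0)); break;
      case 3: acc(op.in1, dY); acc(op.in2, dY); break;
      case 4: {
        const arma::mat& A = ws.acts[op.in1];
        arma::mat dX(A.n_rows, A.n_cols, arma::fill::zeros);
        const arma::umat& am = ws.amax[ii];
        for (arma::uword c = 0; c < dY.n_cols; ++c)
          for (arma::uword p = 0; p < dY.n_rows; ++p)
            dX(am(p, c), c) += dY(p, c);
        acc(op.in1, dX);
        break;
      }
      case 5: {
        int h2 = op.h, w2 = op.w, h = h2 / 2;
        const arma::mat& A = ws.acts[op.in1];
        arma::mat dX(A.n_rows, A.n_cols, arma::fill::zeros);
        for (arma::uword c = 0; c < dY.n_cols; ++c)
          for (int j2 = 0; j2 < w2; ++j2)
            for (int i2 = 0; i2 < h2; ++i2)
              dX(i2 / 2 + static_cast<arma::uword>(j2 / 2) * h, c) +=
                dY(i2 + static_cast<arma::uword>(j2) * h2, c);
        acc(op.in1, dX);
        break;
      }
      case 6: {
        arma::uword c1 = ws.acts[op.in1].n_cols;
        acc(op.in1, dY.cols(0, c1 - 1));
        acc(op.in2, dY.cols(c1, dY.n_cols - 1));
        break;
      }
      case 7: {
        const arma::mat& P = ws.acts[ii + 1];
        acc(op.in1, dY % P % (1.0 - P));
        break;
      }
    }
    dY.reset();  // free as we go
  }
}

// combined loss on probabilities: w_bce * BCE + w_dice * (1 - soft Dice)
double loss_grad(const arma::vec& p_raw, const arma::vec& q,
                 double w_bce, double w_dice, arma::vec& dp) {
  const double lo = 1e-7;
  arma::vec p = arma::clamp(p_raw, lo, 1.0 - lo);
  double N = static_cast<double>(p.n_elem);
  double bce = -arma::mean(q % arma::log(p) + (1.0 - q) % arma::log(1.0 - p));
  const double eps = 1.0;
  double I = arma::dot(p, q);
  double S = arma::accu(p) + arma::accu(q) + eps;
  double dice_loss = 1.0 - (2.0 * I + eps) / S;
  dp = w_bce * (p - q) / (p % (1.0 - p)) / N
     - w_dice * (2.0 * q * S - (2.0 * I + eps)) / (S * S);
  return w_bce * bce + w_dice * dice_loss;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List graph, NumericVector params, NumericVector x) {
  std::vector<Op> ops = parse_graph(graph);
  int h0 = as<int>(graph["in_h"]), w0 = as<int>(graph["in_w"]);
  if (x.size() != static_cast<R_xlen_t>(h0) * w0)
    stop("input size does not match the graph's input grid");
  arma::mat X(x.begin(), static_cast<arma::uword>(h0) * w0, 1, true);
  Workspace ws;
  forward(ops, params.begin(), X, h0, w0, ws, false);
  const arma::mat& out = ws.acts.back();
  return NumericVector(out.begin(), out.end());
}

// Loss and full parameter gradient for one sample (used by the
// finite-difference gradient tests).
// [[Rcpp::export]]
List cpp_unet_loss_grad(List graph, NumericVector params,
                        NumericVector x, NumericVector y,
                        double w_bce, double w_dice) {
  std::vector<Op> ops = parse_graph(graph);
  int h0 = as<int>(graph["in_h"]), w0 = as<int>(graph["in_w"]);
  arma::mat X(x.begin(), static_cast<arma::uword>(h0) * w0, 1, true);
  arma::vec q(y.begin(), y.size(), true);
  Workspace ws;
  forward(ops, params.begin(), X, h0, w0, ws, true);
  arma::vec p = ws.acts.back().col(0);
  arma::vec dp;
  double loss = loss_grad(p, q, w_bce, w_dice, dp);
  NumericVector g(params.size());
  arma::mat dLast(p.n_elem, 1);
  dLast.col(0) = dp;
  backward(ops, params.begin(), ws, dLast, g.begin());
  return List::create(_["loss"] = loss, _["grad"] = g);
}

// One optimizer step on a mini-batch. Returns updated parameter and Adam
// state vectors plus the batch loss and mean hard-threshold Dice.
// [[Rcpp::export]]
List cpp_unet_train_batch(List graph, NumericVector params,
                          NumericVector adam_m, NumericVector adam_v, int t,
                          List xs, List ys, double lr,
                          double beta1, double beta2, double adam_eps,
                          double w_bce, double w_dice) {
  std::vector<Op> ops = parse_graph(graph);
  int h0 = as<int>(graph["in_h"]), w0 = as<int>(graph["in_w"]);
  R_xlen_t np = params.size();
  NumericVector par = clone(params), m = clone(adam_m), v = clone(adam_v);
  std::vector<double> g(np, 0.0);
  double loss = 0.0, dice = 0.0;
  int B = xs.size();
  if (B == 0) stop("empty batch");
  Workspace ws;
  for (int b = 0; b < B; ++b) {
    NumericVector xb = xs[b], yb = ys[b];
    arma::mat X(xb.begin(), static_cast<arma::uword>(h0) * w0, 1, true);
    arma::vec q(yb.begin(), yb.size(), true);
    forward(ops, par.begin(), X, h0, w0, ws, true);
    arma::vec p = ws.acts.back().col(0);
    arma::vec dp;
    loss += loss_grad(p, q, w_bce, w_dice, dp) / B;
    // hard Dice at threshold 0.5 (monitoring only)
    double inter = 0, sa = 0, sb = 0;
    for (arma::uword i = 0; i < p.n_elem; ++i) {
      bool a = p[i] >= 0.5, bq = q[i] >= 0.5;
      inter += a && bq; sa += a; sb += bq;
    }
    dice += (sa + sb > 0 ? 2.0 * inter / (sa + sb) : 1.0) / B;
    arma::mat dLast(p.n_elem, 1);
    dLast.col(0) = dp / B;
    backward(ops, par.begin(), ws, dLast, g.data());
  }
  if (!std::isfinite(loss)) stop("non-finite training loss");
  double bc1 = 1.0 - std::pow(beta1, t), bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < np; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    par[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + adam_eps);
  }
  return List::create(_["params"] = par, _["m"] = m, _["v"] = v,
                      _["loss"] = loss, _["dice"] = dice);
}
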
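// Point-wise 1D convolutional classifier/regressor: forward pass,
// backpropagation and full-batch Adam training.
//
// Activations for a batch of B spectra of common length N are stored as
// (depth x N*B) float matrices with columns grouped per example
// (global column = b*N + i).  Convolutions are stride 1 with
// length-preserving zero padding, realised as im2col + sgemm so the heavy
// lifting goes through BLAS.  Max pooling is window 3, stride 1, same
// padding, depth preserving.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using Rcpp::List;

namespace {

struct Net {
  std::vector<int> kind;    // 0 = conv+ReLU, 1 = maxpool
  std::vector<int> kernel;  // kernel size per hidden layer
  std::vector<fmat> W;      // (d_out x d_in*k), empty for pool layers
  std::vector<fvec> b;
  fmat Wc; fvec bc;         // classifier head (3 x d_last)
  fmat Wr; fvec br;         // regressor head  (8 x d_last)
};

Net net_from_r(const List& rnet) {
  Net net;
  List layers = rnet["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List lay = layers[l];
    std::string kind = Rcpp::as<std::string>(lay["kind"]);
    net.kind.push_back(kind == "maxpool" ? 1 : 0);
    net.kernel.push_back(Rcpp::as<int>(lay["kernel"]));
    if (kind == "maxpool") {
      net.W.push_back(fmat());
      net.b.push_back(fvec());
    } else {
      net.W.push_back(arma::conv_to<fmat>::from(
          Rcpp::as<arma::mat>(lay["W"])));
      net.b.push_back(arma::conv_to<fvec>::from(
          Rcpp::as<arma::vec>(lay["b"])));
    }
  }
  List cls = rnet["classifier"], reg = rnet["regressor"];
  net.Wc = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(cls["W"]));
  net.bc = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(cls["b"]));
  net.Wr = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(reg["W"]));
  net.br = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(reg["b"]));
  return net;
}

List net_to_r(const Net& net, const List& proto) {
  List layers = Rcpp::clone(Rcpp::as<List>(proto["layers"]));
  for (int l = 0; l < layers.size(); ++l) {
    if (net.kind[l] == 1) continue;
    List lay = layers[l];
    lay["W"] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.W[l]));
    lay["b"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.b[l]));
    layers[l] = lay;
  }
  return List::create(
      Rcpp::Named("layers") = layers,
      Rcpp::Named("classifier") = List::create(
          Rcpp::Named("W") = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.Wc)),
          Rcpp::Named("b") = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.bc))),
      Rcpp::Named("regressor") = List::create(
          Rcpp::Named("W") = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.Wr)),
          Rcpp::Named("b") = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.br))));
}

// Max pool, window 3, stride 1, same (zero) padding.  Out-of-range
// neighbours are skipped, which for non-negative ReLU inputs matches
// zero padding.  arg[] records the winning shift (-1, 0, +1).
void maxpool_fwd(const fmat& A, fmat& P, arma::Mat<short>& arg,
                 int N, int B) {
  const int d = A.n_rows;
  P.set_size(d, A.n_cols);
  P = A;
  arg.zeros(d, A.n_cols);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * N;
    for (int i = 0; i < N; ++i) {
      for (int s = -1; s <= 1; s += 2) {
        const int j = i + s;
        if (j < 0 || j >= N) continue;
        for (int r = 0; r < d; ++r) {
          const float v = A(r, off + j);
          if (v > P(r, off + i)) { P(r, off + i) = v; arg(r, off + i) = (short)s; }
        }
      }
    }
  }
}

void maxpool_bwd(const fmat& dP, const arma::Mat<short>& arg,
                 fmat& dA, int N, int B) {
  const int d = dP.n_rows;
  dA.set_size(d, dP.n_cols);
  dA.zeros();
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * N;
    for (int i = 0; i < N; ++i)
      for (int r = 0; r < d; ++r)
        dA(r, off + i + arg(r, off + i)) += dP(r, off + i);
  }
}

struct Cache {
  std::vector<fmat> act;   // post-ReLU activation per hidden layer (+input)
  std::vector<fmat> col;   // im2col matrices for conv layers with k > 1
  std::vector<arma::Mat<short>> poolArg;
  fmat scores;             // softmax output, 3 x NB
  fmat reg;                // regressor output, 8 x NB
};

// im2col into a caller-provided (persistent) buffer
void im2col_into(const fmat& A, int N, int B, int k, fmat& C) {
  const int d = A.n_rows, pad = (k - 1) / 2;
  C.set_size(d * k, (size_t)N * B);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * N;
    for (int dk = 0; dk < k; ++dk) {
      const int shift = dk - pad;
      const int i0 = std::max(0, -shift), i1 = std::min(N, N - shift);
      if (i0 > 0)
        C.submat(dk * d, off, dk * d + d - 1, off + i0 - 1).zeros();
      if (i1 < N)
        C.submat(dk * d, off + i1, dk * d + d - 1, off + N - 1).zeros();
      if (i1 <= i0) continue;
      C.submat(dk * d, off + i0, dk * d + d - 1, off + i1 - 1) =
          A.cols(off + i0 + shift, off + i1 - 1 + shift);
    }
  }
}

void forward(const Net& net, const fmat& X, int N, int B, Cache& cc,
             bool keep) {
  const int L = (int)net.kind.size();
  if ((int)cc.act.size() != L + 1) {
    cc.act.assign(L + 1, fmat());
    cc.col.assign(L, fmat());
    cc.poolArg.assign(L, arma::Mat<short>());
  }
  // input as 1 x NB (buffers keep their storage when sizes repeat)
  cc.act[0].set_size(1, (size_t)N * B);
  {
    float* ap = cc.act[0].memptr();
    const float* xp = X.memptr();
    const size_t ne = (size_t)N * B;
    for (size_t t = 0; t < ne; ++t) ap[t] = xp[t];
  }
  for (int l = 0; l < L; ++l) {
    const fmat& Ain = cc.act[l];
    if (net.kind[l] == 1) {
      maxpool_fwd(Ain, cc.act[l + 1], cc.poolArg[l], N, B);
    } else {
      const int k = net.kernel[l];
      fmat& Z = cc.act[l + 1];
      if (k == 1) {
        Z = net.W[l] * Ain;
      } else {
        im2col_into(Ain, N, B, k, cc.col[l]);
        Z = net.W[l] * cc.col[l];
      }
      Z.each_col() += net.b[l];
      float* zp = Z.memptr();
      const size_t nz = Z.n_elem;
      for (size_t t = 0; t < nz; ++t) zp[t] = zp[t] > 0.0f ? zp[t] : 0.0f;
    }
  }
  (void)keep;
  const fmat& Alast = cc.act[L];
  fmat& S = cc.scores;
  S = net.Wc * Alast;
  S.each_col() += net.bc;
  // column-wise softmax over the 3 class channels
  {
    float* sp = S.memptr();
    const size_t nc = S.n_cols;
    for (size_t j = 0; j < nc; ++j, sp += 3) {
      const float m = std::max(sp[0], std::max(sp[1], sp[2]));
      sp[0] = std::exp(sp[0] - m);
      sp[1] = std::exp(sp[1] - m);
      sp[2] = std::exp(sp[2] - m);
      const float z = sp[0] + sp[1] + sp[2];
      sp[0] /= z; sp[1] /= z; sp[2] /= z;
    }
  }
  cc.reg = net.Wr * Alast;
  cc.reg.each_col() += net.br;
}

struct LossOut { double total = 0.0, ce = 0.0, mse = 0.0; };

// labels: length NB ints in {0,1,2}; targets 4 x NB (offset, amp, fwhh, eta)
// valid only where labels > 0.  Gradients dS (pre-softmax), dR filled when
// grad = true.
LossOut loss_and_grad(const Cache& cc, const arma::ivec& labels,
                      const fmat& targets, const arma::vec& cw,
                      const arma::vec& rw, fmat* dS, fmat* dR, bool grad) {
  const size_t NB = cc.scores.n_cols;
  LossOut out;
  if (grad) { dS->zeros(3, NB); dR->zeros(8, NB); }
  size_t cnt[3] = {0, 0, 0};
  for (size_t j = 0; j < NB; ++j) cnt[labels(j)]++;
  const double nPer[3] = {0.0, 4.0 * cnt[1], 4.0 * cnt[2]};
  double ce = 0.0, mse = 0.0;
  for (size_t j = 0; j < NB; ++j) {
    const int y = labels(j);
    const double w = cw(y);
    const double p = std::max((double)cc.scores(y, j), 1e-12);
    ce += -w * std::log(p);
    if (grad) {
      for (int r = 0; r < 3; ++r)
        (*dS)(r, j) = (float)(w * (cc.scores(r, j) - (r == y ? 1.0 : 0.0)) / NB);
    }
    if (y > 0) {
      const int base = (y == 2) ? 0 : 4;  // Class-2 block first
      const double wr = rw(y - 1) / nPer[y];
      // per-channel characteristic scales (offset, amplitude, fwhh, eta)
      // keep the four error terms commensurate; fwhh is in points
      static const double chScale[4] = {1.0, 1.0, 10.0, 1.0};
      for (int chn = 0; chn < 4; ++chn) {
        const double err = ((double)cc.reg(base + chn, j) -
                            (double)targets(chn, j)) / chScale[chn];
        mse += wr * err * err;
        if (grad)
          (*dR)(base + chn, j) = (float)(2.0 * wr * err / chScale[chn]);
      }
    }
  }
  out.ce = ce / NB;
  out.mse = mse;
  out.total = out.ce + out.mse;
  return out;
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
  fmat dWc; fvec dbc; fmat dWr; fvec dbr;
  std::vector<fmat> dact;   // persistent gradient buffers per layer
};

void backward(const Net& net, Cache& cc, const fmat& dS, const fmat& dR,
              int N, int B, Grads& g) {
  const int L = (int)net.kind.size();
  if ((int)g.dW.size() != L) {
    g.dW.assign(L, fmat());
    g.db.assign(L, fvec());
    g.dact.assign(L + 1, fmat());
  }
  const fmat& Alast = cc.act[L];
  g.dWc = dS * Alast.t();
  g.dbc = arma::sum(dS, 1);
  g.dWr = dR * Alast.t();
  g.dbr = arma::sum(dR, 1);
  g.dact[L] = net.Wc.t() * dS + net.Wr.t() * dR;
  for (int l = L - 1; l >= 0; --l) {
    fmat& dA = g.dact[l + 1];
    if (net.kind[l] == 1) {
      maxpool_bwd(dA, cc.poolArg[l], g.dact[l], N, B);
      continue;
    }
    // ReLU gate: act[l+1] is post-ReLU
    {
      float* dp = dA.memptr();
      const float* ap = cc.act[l + 1].memptr();
      const size_t ne = dA.n_elem;
      for (size_t t = 0; t < ne; ++t) if (ap[t] <= 0.0f) dp[t] = 0.0f;
    }
    const int k = net.kernel[l];
    if (k == 1) {
      g.dW[l] = dA * cc.act[l].t();
      g.db[l] = arma::sum(dA, 1);
      if (l > 0) g.dact[l] = net.W[l].t() * dA;
    } else {
      g.dW[l] = dA * cc.col[l].t();
      g.db[l] = arma::sum(dA, 1);
      if (l == 0) continue;
      // reuse the im2col buffer for dC: cc.col[l] is no longer needed
      fmat& dC = cc.col[l];
      dC = net.W[l].t() * dA;
      const int d = cc.act[l].n_rows, pad = (k - 1) / 2;
      fmat& dPrev = g.dact[l];
      dPrev = dC.rows(pad * d, pad * d + d - 1);  // shift 0: full copy
      for (int b = 0; b < B; ++b) {
        const size_t off = (size_t)b * N;
        for (int dk = 0; dk < k; ++dk) {
          if (dk == pad) continue;
          const int shift = dk - pad;
          const int i0 = std::max(0, -shift), i1 = std::min(N, N - shift);
          if (i1 <= i0) continue;
          dPrev.cols(off + i0 + shift, off + i1 - 1 + shift) +=
              dC.submat(dk * d, off + i0, dk * d + d - 1, off + i1 - 1);
        }
      }
    }
  }
}

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  fmat mWc, vWc, mWr, vWr;
  fvec mbc, vbc, mbr, vbr;
  void init(const Net& net) {
    const int L = (int)net.kind.size();
    mW.assign(L, fmat()); vW.assign(L, fmat());
    mb.assign(L, fvec()); vb.assign(L, fvec());
    for (int l = 0; l < L; ++l) {
      if (net.kind[l] == 1) continue;
      mW[l].zeros(arma::size(net.W[l])); vW[l].zeros(arma::size(net.W[l]));
      mb[l].zeros(arma::size(net.b[l])); vb[l].zeros(arma::size(net.b[l]));
    }
    mWc.zeros(arma::size(net.Wc)); vWc.zeros(arma::size(net.Wc));
    mbc.zeros(arma::size(net.bc)); vbc.zeros(arma::size(net.bc));
    mWr.zeros(arma::size(net.Wr)); vWr.zeros(arma::size(net.Wr));
    mbr.zeros(arma::size(net.br)); vbr.zeros(arma::size(net.br));
  }
};

template <typename T>
void adam_step(T& w, const T& g, T& m, T& v, float lr_t, float b1, float b2,
               float eps) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * (g % g);
  w -= lr_t * m / (arma::sqrt(v) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
List cnn_forward_cpp(List rnet, arma::mat X) {
  Net net = net_from_r(rnet);
  const int N = X.n_rows, B = X.n_cols;
  fmat Xf = arma::conv_to<fmat>::from(X);
  Cache cc;
  forward(net, Xf, N, B, cc, false);
  // return as N x 3 x B and N x 8 x B arrays (double)
  Rcpp::NumericVector sc(Rcpp::Dimension(N, 3, B)), rg(Rcpp::Dimension(N, 8, B));
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < N; ++i) {
      for (int r = 0; r < 3; ++r)
        sc[i + N * r + (size_t)N * 3 * b] = cc.scores(r, (size_t)b * N + i);
      for (int r = 0; r < 8; ++r)
        rg[i + N * r + (size_t)N * 8 * b] = cc.reg(r, (size_t)b * N + i);
    }
  return List::create(Rcpp::Named("classScores") = sc,
                      Rcpp::Named("regressor") = rg);
}

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train_cpp(List rnet, arma::mat Xtr, arma::imat labTr, arma::mat targTr,
                   arma::mat Xval, arma::imat labVal, arma::mat targVal,
                   List opts) {
  Net net = net_from_r(rnet);
  const int N = Xtr.n_rows, Btr = Xtr.n_cols;
  const int Bval = Xval.n_cols > 0 && Xval.n_rows == (arma::uword)N ? (int)Xval.n_cols : 0;
  const double lr = Rcpp::as<double>(opts["learningRate"]);
  const int epochs = Rcpp::as<int>(opts["epochs"]);
  const arma::vec cw = Rcpp::as<arma::vec>(opts["classWeights"]);
  const arma::vec rw = Rcpp::as<arma::vec>(opts["regressorWeights"]);
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  fmat Xf = arma::conv_to<fmat>::from(Xtr);
  fmat Xv = Bval > 0 ? arma::conv_to<fmat>::from(Xval) : fmat();
  // flatten labels/targets to per-column layout
  arma::ivec ltr((size_t)N * Btr), lval;
  fmat ttr(4, (size_t)N * Btr), tval;
  for (int b = 0; b < Btr; ++b)
    for (int i = 0; i < N; ++i) {
      ltr((size_t)b * N + i) = labTr(i, b);
      for (int chn = 0; chn < 4; ++chn)
        ttr(chn, (size_t)b * N + i) = (float)targTr(i + (size_t)N * chn, b);
    }
  if (Bval > 0) {
    lval.set_size((size_t)N * Bval);
    tval.set_size(4, (size_t)N * Bval);
    for (int b = 0; b < Bval; ++b)
      for (int i = 0; i < N; ++i) {
        lval((size_t)b * N + i) = labVal(i, b);
        for (int chn = 0; chn < 4; ++chn)
          tval(chn, (size_t)b * N + i) = (float)targVal(i + (size_t)N * chn, b);
      }
  }

  AdamState st;
  st.init(net);
  Net best = net;
  double bestVal = std::numeric_limits<double>::infinity();
  int bestEpoch = 0;
  arma::vec trainLoss(epochs), valLoss(epochs), trainCE(epochs), trainMSE(epochs);
  Cache cc, cv;
  Grads g;
  fmat dS, dR;
  for (int ep = 0; ep < epochs; ++ep) {
    forward(net, Xf, N, Btr, cc, true);
    LossOut lo = loss_and_grad(cc, ltr, ttr, cw, rw, &dS, &dR, true);
    if (!std::isfinite(lo.total))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
    trainLoss(ep) = lo.total; trainCE(ep) = lo.ce; trainMSE(ep) = lo.mse;
    backward(net, cc, dS, dR, N, Btr, g);
    const float lr_t = (float)(lr * std::sqrt(1.0 - std::pow((double)b2, ep + 1)) /
                               (1.0 - std::pow((double)b1, ep + 1)));
    for (size_t l = 0; l < net.kind.size(); ++l) {
      if (net.kind[l] == 1) continue;
      adam_step(net.W[l], g.dW[l], st.mW[l], st.vW[l], lr_t, b1, b2, eps);
      adam_step(net.b[l], g.db[l], st.mb[l], st.vb[l], lr_t, b1, b2, eps);
    }
    adam_step(net.Wc, g.dWc, st.mWc, st.vWc, lr_t, b1, b2, eps);
    adam_step(net.bc, g.dbc, st.mbc, st.vbc, lr_t, b1, b2, eps);
    adam_step(net.Wr, g.dWr, st.mWr, st.vWr, lr_t, b1, b2, eps);
    adam_step(net.br, g.dbr, st.mbr, st.vbr, lr_t, b1, b2, eps);
    if (Bval > 0) {
      forward(net, Xv, N, Bval, cv, false);
      LossOut lv = loss_and_grad(cv, lval, tval, cw, rw, nullptr, nullptr, false);
      valLoss(ep) = lv.total;
      if (lv.total < bestVal) { bestVal = lv.total; best = net; bestEpoch = ep + 1; }
    } else {
      valLoss(ep) = NA_REAL;
      best = net;
      bestEpoch = ep + 1;
    }
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      Rcpp::Named("final") = net_to_r(net, rnet),
      Rcpp::Named("best") = net_to_r(best, rnet),
      Rcpp::Named("bestEpoch") = bestEpoch,
      Rcpp::Named("trainLoss") = trainLoss,
      Rcpp::Named("valLoss") = valLoss,
      Rcpp::Named("trainCE") = trainCE,
      Rcpp::Named("trainMSE") = trainMSE);
}
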
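// Single-precision training and inference kernels for the compact 3D CNN.
//
// Convolutions are gather (im2col) + sgemm; the gather indices are
// precomputed in R (cnnArchitecture) and shared by both the reference R
// implementation and these kernels. Layouts match the R side exactly:
// activations are feature x batch, feature order channel-fastest, then
// spectral depth, then spatial position; im2col columns are ordered
// position-major within sample. Minibatch order is supplied by the caller
// (R's RNG), so training is deterministic given the permutation matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

struct Layer {
  bool conv;
  int Cout, TT, P, CDS, Fin, Fout;
  std::vector<int> gidx;  // length P*TT, 0 = padding (reads as 0)
  fmat W;
  fvec b;
};

std::vector<Layer> buildLayers(const List& layerMeta, const List& params) {
  const int nl = layerMeta.size();
  std::vector<Layer> layers(nl);
  for (int i = 0; i < nl; ++i) {
    List lm = layerMeta[i];
    List pr = params[i];
    Layer& L = layers[i];
    L.conv = as<std::string>(lm["type"]) == "conv";
    NumericMatrix W = pr["W"];
    L.W = arma::conv_to<fmat>::from(as<arma::mat>(W));
    L.b = arma::conv_to<fvec>::from(as<arma::vec>(pr["b"]));
    if (L.conv) {
      L.Cout = as<int>(lm["Cout"]);
      L.TT = as<int>(lm["TT"]);
      L.P = as<int>(lm["P"]);
      L.CDS = as<int>(lm["CDS"]);
      IntegerVector g = lm["gidx"];
      // R-side padding convention is index CDS+1 (an appended zero row);
      // here padding is 0
      L.gidx.resize(g.size());
      for (int j = 0; j < g.size(); ++j)
        L.gidx[j] = g[j] > L.CDS ? 0 : g[j];
    } else {
      L.Fin = as<int>(lm["Fin"]);
      L.Fout = as<int>(lm["Fout"]);
    }
  }
  return layers;
}

// gather im2col columns: cur (F x m) -> cols (TT x P*m)
void gatherCols(const fmat& cur, const Layer& L, fmat& cols) {
  const int m = cur.n_cols;
  const int PT = L.P * L.TT;
  cols.set_size(L.TT, (size_t)L.P * m);
  const int* g = L.gidx.data();
  for (int i = 0; i < m; ++i) {
    const float* xc = cur.colptr(i);
    float* dst = cols.memptr() + (size_t)i * PT;
    for (int j = 0; j < PT; ++j) {
      const int gi = g[j];
      dst[j] = gi ? xc[gi - 1] : 0.0f;
    }
  }
}

// scatter-add transpose of the gather: dcols (TT x P*m) -> dX (CDS x m)
void scatterCols(const fmat& dcols, const Layer& L, int m, fmat& dX) {
  dX.zeros(L.CDS, m);
  const int PT = L.P * L.TT;
  const int* g = L.gidx.data();
  for (int i = 0; i < m; ++i) {
    const float* src = dcols.memptr() + (size_t)i * PT;
    float* xc = dX.colptr(i);
    for (int j = 0; j < PT; ++j) {
      const int gi = g[j];
      if (gi) xc[gi - 1] += src[j];
    }
  }
}

struct Cache {
  fmat cols;  // conv: im2col matrix
  fmat A;     // post-activation output, reshaped to next layer's input
  fmat in;    // fc: input
};

// forward through all layers; returns logits (K x m).
// activations live in the caches (or a scratch slot when not training), so
// no layer output is ever copied.
fmat forwardPass(std::vector<Layer>& layers, const fmat& X,
                 std::vector<Cache>* caches) {
  const int m = X.n_cols;
  const int nl = layers.size();
  std::vector<Cache> scratch;
  if (!caches) { scratch.resize(nl); caches = &scratch; }
  const fmat* cur = &X;
  for (int i = 0; i < nl; ++i) {
    Layer& L = layers[i];
    Cache& C = (*caches)[i];
    if (L.conv) {
      gatherCols(*cur, L, C.cols);
      fmat Z = L.W * C.cols;           // Cout x (P*m)
      Z.each_col() += L.b;
      Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      Z.reshape((size_t)L.Cout * L.P, m);
      C.A = std::move(Z);
      cur = &C.A;
    } else {
      const bool last = i == nl - 1;
      C.in = *cur;   // kept for dW; shares no memory with the cache above
      fmat Z = L.W * *cur;
      Z.each_col() += L.b;
      if (!last) Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      C.A = std::move(Z);
      cur = &C.A;
    }
  }
  return (*caches)[nl - 1].A;
}

struct Grad { fmat dW; fvec db; };

void backwardPass(std::vector<Layer>& layers, std::vector<Cache>& caches,
                  fmat dCur, std::vector<Grad>& grads) {
  const int nl = layers.size();
  const int m = dCur.n_cols;
  for (int i = nl - 1; i >= 0; --i) {
    Layer& L = layers[i];
    Cache& C = caches[i];
    if (!L.conv) {
      if (i != nl - 1)  // hidden fc: ReLU gate
        dCur %= arma::conv_to<fmat>::from(C.A > 0.0f);
      grads[i].dW = dCur * C.in.t();
      grads[i].db = arma::sum(dCur, 1);
      dCur = L.W.t() * dCur;
    } else {
      // dCur arrives as (Cout*P) x m; C.A has the same shape/layout
      dCur %= arma::conv_to<fmat>::from(C.A > 0.0f);
      dCur.reshape(L.Cout, (size_t)L.P * m);
      grads[i].dW = dCur * C.cols.t();
      grads[i].db = arma::sum(dCur, 1);
      fmat dcols = L.W.t() * dCur;     // TT x (P*m)
      fmat dX;
      scatterCols(dcols, L, m, dX);
      dCur = std::move(dX);
    }
  }
}

// class-weighted softmax cross-entropy; fills dLogits, returns loss
double weightedCE(const fmat& logits, const std::vector<int>& y,
                  const std::vector<float>& w, fmat& dLogits) {
  const int K = logits.n_rows, m = logits.n_cols;
  dLogits.set_size(K, m);
  double loss = 0.0, sw = 0.0;
  for (int i = 0; i < m; ++i) sw += w[y[i] - 1];
  for (int i = 0; i < m; ++i) {
    const float* z = logits.colptr(i);
    float zmax = z[0];
    for (int k = 1; k < K; ++k) zmax = std::max(zmax, z[k]);
    double se = 0.0;
    for (int k = 0; k < K; ++k) se += std::exp((double)z[k] - zmax);
    const int yi = y[i] - 1;
    const double wi = w[yi] / sw;
    loss += wi * (std::log(se) - ((double)z[yi] - zmax));
    float* d = dLogits.colptr(i);
    for (int k = 0; k < K; ++k)
      d[k] = (float)(wi * (std::exp((double)z[k] - zmax) / se - (k == yi ? 1.0 : 0.0)));
  }
  return loss;
}

}  // namespace

// [[Rcpp::export(name = ".cnnForwardCpp")]]
NumericMatrix cnnForwardCpp(List layerMeta, List params, NumericMatrix X) {
  std::vector<Layer> layers = buildLayers(layerMeta, params);
  fmat Xf = arma::conv_to<fmat>::from(as<arma::mat>(X));
  fmat logits = forwardPass(layers, Xf, nullptr);
  return wrap(arma::conv_to<arma::mat>::from(logits));
}

// [[Rcpp::export(name = ".cnnTrainCpp")]]
List cnnTrainCpp(List layerMeta, List params, NumericMatrix X,
                 IntegerVector y, NumericVector w, IntegerMatrix perms,
                 int batchSize, double learningRate) {
  std::vector<Layer> layers = buildLayers(layerMeta, params);
  const int n = X.ncol();
  const int epochs = perms.ncol();
  const int nl = layers.size();
  fmat Xf = arma::conv_to<fmat>::from(as<arma::mat>(X));
  std::vector<int> yv(y.begin(), y.end());
  std::vector<float> wv(w.size());
  for (int k = 0; k < w.size(); ++k) wv[k] = (float)w[k];

  std::vector<Grad> mom(nl), vel(nl), grads(nl);
  for (int i = 0; i < nl; ++i) {
    mom[i].dW.zeros(layers[i].W.n_rows, layers[i].W.n_cols);
    mom[i].db.zeros(layers[i].b.n_elem);
    vel[i].dW = mom[i].dW;
    vel[i].db = mom[i].db;
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float lr = (float)learningRate;
  long step = 0;
  NumericVector losses(epochs);

  std::vector<Cache> caches(nl);
  for (int ep = 0; ep < epochs; ++ep) {
    double epLoss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batchSize) {
      const int m = std::min(batchSize, n - start);
      fmat Xb(Xf.n_rows, m);
      std::vector<int> yb(m);
      for (int i = 0; i < m; ++i) {
        const int src = perms(start + i, ep) - 1;
        Xb.col(i) = Xf.col(src);
        yb[i] = yv[src];
      }
      fmat logits = forwardPass(layers, Xb, &caches);
      fmat dLogits;
      epLoss += weightedCE(logits, yb, wv, dLogits);
      ++nb;
      backwardPass(layers, caches, std::move(dLogits), grads);
      ++step;
      const float c1 = 1.0f - std::pow(b1, (float)step);
      const float c2 = 1.0f - std::pow(b2, (float)step);
      for (int i = 0; i < nl; ++i) {
        mom[i].dW = b1 * mom[i].dW + (1.0f - b1) * grads[i].dW;
        vel[i].dW = b2 * vel[i].dW + (1.0f - b2) * arma::square(grads[i].dW);
        layers[i].W -= lr * (mom[i].dW / c1) / (arma::sqrt(vel[i].dW / c2) + eps);
        mom[i].db = b1 * mom[i].db + (1.0f - b1) * grads[i].db;
        vel[i].db = b2 * vel[i].db + (1.0f - b2) * arma::square(grads[i].db);
        layers[i].b -= lr * (mom[i].db / c1) / (arma::sqrt(vel[i].db / c2) + eps);
      }
    }
    losses[ep] = epLoss / std::max(nb, 1);
  }

  List outParams(nl);
  for (int i = 0; i < nl; ++i)
    outParams[i] = List::create(
      Named("W") = wrap(arma::conv_to<arma::mat>::from(layers[i].W)),
      Named("b") = as<NumericVector>(wrap(arma::conv_to<arma::vec>::from(layers[i].b))));
  return List::create(Named("params") = outParams, Named("losses") = losses);
}
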
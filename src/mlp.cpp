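#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Small fully-connected network trained with Adam on binary cross
// entropy.  All randomness (weight init, per-epoch shuffling) comes from
// a private xorshift generator seeded by the caller, so a fixed seed
// yields a bitwise-identical loss trajectory on re-run.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {
    // scramble so that nearby seeds decorrelate
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {            // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() {              // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int m) { return (int)(next() % (uint64_t)m); }
};

struct Layer {
  int in, out;
  std::vector<double> W, b;          // W is out x in, row-major
  std::vector<double> mW, vW, mb, vb;
  Layer(int in_, int out_) : in(in_), out(out_),
    W(in_ * out_), b(out_, 0.0),
    mW(in_ * out_, 0.0), vW(in_ * out_, 0.0),
    mb(out_, 0.0), vb(out_, 0.0) {}
  void init_uniform(double limit, Rng& rng) {
    for (size_t i = 0; i < W.size(); ++i)
      W[i] = (2.0 * rng.unif() - 1.0) * limit;
  }
};

inline void adam_step(std::vector<double>& w, std::vector<double>& m,
                      std::vector<double>& v, const std::vector<double>& g,
                      double lr, double b1, double b2, double eps, int t) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < w.size(); ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_train_mlp(NumericMatrix X, NumericVector y, IntegerVector hidden,
                   int epochs, int batch_size, double lr, double beta1,
                   double beta2, double eps, int seed) {
  const int N = X.nrow(), D = X.ncol();
  if (y.size() != N) stop("label length must match rows of X");
  if (batch_size < 1 || N % batch_size != 0)
    stop("batch size must divide the dataset size");

  Rng rng((uint32_t)seed);

  std::vector<Layer> layers;
  int prev = D;
  for (int h = 0; h < hidden.size(); ++h) {
    layers.emplace_back(prev, hidden[h]);
    // He-uniform for rectifier layers
    layers.back().init_uniform(std::sqrt(6.0 / prev), rng);
    prev = hidden[h];
  }
  layers.emplace_back(prev, 1);
  // Xavier-uniform for the sigmoid output layer
  layers.back().init_uniform(std::sqrt(6.0 / (prev + 1)), rng);

  const int L = (int)layers.size();
  const int nb = N / batch_size;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  // per-layer activations for one batch (a[0] = inputs)
  std::vector< std::vector<double> > act(L + 1), delta(L);
  act[0].resize(batch_size * D);
  for (int l = 0; l < L; ++l) {
    act[l + 1].resize(batch_size * layers[l].out);
    delta[l].resize(batch_size * layers[l].out);
  }

  NumericVector losses(epochs * nb);
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // seeded Fisher-Yates shuffle each epoch
    for (int i = N - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);

    for (int bidx = 0; bidx < nb; ++bidx) {
      const int B = batch_size;
      std::vector<double> ybatch(B);
      for (int r = 0; r < B; ++r) {
        int src = order[bidx * B + r];
        for (int c = 0; c < D; ++c) act[0][r * D + c] = X(src, c);
        ybatch[r] = y[src];
      }

      // forward: ReLU on hidden layers, logits at the output
      for (int l = 0; l < L; ++l) {
        const Layer& ly = layers[l];
        const std::vector<double>& in = act[l];
        std::vector<double>& out = act[l + 1];
        for (int r = 0; r < B; ++r) {
          for (int o = 0; o < ly.out; ++o) {
            double z = ly.b[o];
            const double* wrow = &ly.W[(size_t)o * ly.in];
            const double* xin = &in[(size_t)r * ly.in];
            for (int c = 0; c < ly.in; ++c) z += wrow[c] * xin[c];
            out[r * ly.out + o] = (l < L - 1) ? (z > 0.0 ? z : 0.0) : z;
          }
        }
      }

      // BCE from logits (numerically safe) and output delta = sigma(z)-y
      double loss = 0.0;
      for (int r = 0; r < B; ++r) {
        double z = act[L][r], yy = ybatch[r];
        loss += std::fmax(z, 0.0) - z * yy + std::log1p(std::exp(-std::fabs(z)));
        delta[L - 1][r] = (1.0 / (1.0 + std::exp(-z)) - yy) / B;
      }
      loss /= B;
      if (!std::isfinite(loss))
        stop("training diverged at step %d (non-finite loss)", t + 1);
      losses[t] = loss;

      // backward + Adam
      ++t;
      for (int l = L - 1; l >= 0; --l) {
        Layer& ly = layers[l];
        const std::vector<double>& in = act[l];
        std::vector<double> gW(ly.W.size(), 0.0), gb(ly.out, 0.0);
        for (int r = 0; r < B; ++r) {
          for (int o = 0; o < ly.out; ++o) {
            double d = delta[l][r * ly.out + o];
            gb[o] += d;
            double* gr = &gW[(size_t)o * ly.in];
            const double* xin = &in[(size_t)r * ly.in];
            for (int c = 0; c < ly.in; ++c) gr[c] += d * xin[c];
          }
        }
        if (l > 0) {
          // propagate through the ReLU of layer l-1
          for (int r = 0; r < B; ++r) {
            for (int c = 0; c < ly.in; ++c) {
              double s = 0.0;
              for (int o = 0; o < ly.out; ++o)
                s += ly.W[(size_t)o * ly.in + c] * delta[l][r * ly.out + o];
              delta[l - 1][r * ly.in + c] =
                (act[l][r * ly.in + c] > 0.0) ? s : 0.0;
            }
          }
        }
        adam_step(ly.W, ly.mW, ly.vW, gW, lr, beta1, beta2, eps, t);
        adam_step(ly.b, ly.mb, ly.vb, gb, lr, beta1, beta2, eps, t);
      }
    }
  }

  double effort = 0.0;
  for (int i = 0; i < losses.size(); ++i) effort += losses[i];
  effort /= losses.size();
  return List::create(_["effort"] = effort, _["losses"] = losses);
}
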
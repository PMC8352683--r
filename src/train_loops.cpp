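#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-sample stochastic gradient descent for the single-hidden-layer
// softmax/cross-entropy network. Thresholds live in the last row of each
// weight matrix via the constant -1 bias units, so W_in is (N+1) x Y and
// W_out is (Y+1) x G. `orders` is n x epochs, 1-based visiting orders drawn
// in R (so determinism follows the R RNG). Early stop: mean epoch loss
// improves by < tol for `patience` consecutive epochs.
// [[Rcpp::export]]
List nn_sgd_cpp(NumericMatrix W_in0, NumericMatrix W_out0,
                NumericMatrix X, NumericMatrix D, NumericVector weights,
                double eta, IntegerMatrix orders, double tol, int patience) {
  const int n = X.nrow(), N = X.ncol();
  const int Y = W_in0.ncol(), G = W_out0.ncol();
  const int epochs = orders.ncol();
  NumericMatrix W_in(clone(W_in0)), W_out(clone(W_out0));
  std::vector<double> hn(Y), ho(Y), yn(G), yo(G), delta(G), sig(Y);
  std::vector<double> loss_hist;
  loss_hist.reserve(epochs);
  double prev = R_PosInf;
  int stall = 0, diverged = 0;

  for (int e = 0; e < epochs && diverged == 0; ++e) {
    double loss_sum = 0.0;
    for (int idx = 0; idx < n; ++idx) {
      const int k = orders(idx, e) - 1;
      const double wk = weights[k];
      // hidden layer: hn_p = sum_n w_np x_n - b_p  (bias row times -1)
      for (int p = 0; p < Y; ++p) {
        double s = -W_in(N, p);
        for (int m = 0; m < N; ++m) s += W_in(m, p) * X(k, m);
        hn[p] = s;
        ho[p] = 1.0 / (1.0 + std::exp(-s));
      }
      // output layer with softmax (max-subtracted)
      double mx = R_NegInf;
      for (int q = 0; q < G; ++q) {
        double s = -W_out(Y, q);
        for (int p = 0; p < Y; ++p) s += W_out(p, q) * ho[p];
        yn[q] = s;
        if (s > mx) mx = s;
      }
      double z = 0.0;
      for (int q = 0; q < G; ++q) { yo[q] = std::exp(yn[q] - mx); z += yo[q]; }
      double loss = 0.0;
      for (int q = 0; q < G; ++q) {
        yo[q] /= z;
        delta[q] = wk * (yo[q] - D(k, q));
        if (D(k, q) > 0.5) {
          double p = yo[q] < 1e-12 ? 1e-12 : yo[q];
          loss -= wk * std::log(p);
        }
      }
      loss_sum += loss;
      if (!std::isfinite(loss)) { diverged = e + 1; break; }
      // hidden error terms use the pre-update output weights
      for (int p = 0; p < Y; ++p) {
        double s = 0.0;
        for (int q = 0; q < G; ++q) s += delta[q] * W_out(p, q);
        sig[p] = s * ho[p] * (1.0 - ho[p]);
      }
      // descent updates, thresholds updated through the -1 bias inputs
      for (int q = 0; q < G; ++q) {
        const double dq = eta * delta[q];
        for (int p = 0; p < Y; ++p) W_out(p, q) -= dq * ho[p];
        W_out(Y, q) += dq;
      }
      for (int p = 0; p < Y; ++p) {
        const double dp = eta * sig[p];
        for (int m = 0; m < N; ++m)
          if (X(k, m) != 0.0) W_in(m, p) -= dp * X(k, m);
        W_in(N, p) += dp;
      }
    }
    if (diverged) break;
    const double mean_loss = loss_sum / n;
    loss_hist.push_back(mean_loss);
    if (prev - mean_loss < tol) { if (++stall >= patience) { prev = mean_loss; break; } }
    else stall = 0;
    prev = mean_loss;
  }
  return List::create(_["W_in"] = W_in, _["W_out"] = W_out,
                      _["loss_history"] = NumericVector(loss_hist.begin(), loss_hist.end()),
                      _["diverged"] = diverged);
}

// Dual coordinate descent for the L1-loss soft-margin linear SVM with the
// intercept as an augmented constant feature (value 1, regularised):
//   min_alpha 1/2 ||w~||^2 - sum alpha_k,  w~ = sum alpha_k y_k x~_k,
//   0 <= alpha_k <= U_k.
// Coordinates are visited in a freshly shuffled order each pass, drawn from
// an internal fixed-seed xorshift generator so results are bit-reproducible
// and independent of R's RNG state. Convergence uses the projected-gradient
// spread rule: stop when max(PG) - min(PG) over a pass drops below tol.
// [[Rcpp::export]]
List svm_dcd_cpp(NumericMatrix X, NumericVector y, NumericVector U,
                 double tol, int max_passes) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    idx[i] = i;
    double s = 1.0;  // augmented bias feature
    for (int m = 0; m < d; ++m) s += X(i, m) * X(i, m);
    qii[i] = s;
  }
  uint64_t state = 0x9E3779B97F4A7C15ULL;
  auto next_rand = [&state]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  int pass = 0;
  double viol = R_PosInf;
  bool converged = false;
  for (pass = 0; pass < max_passes; ++pass) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates shuffle
      const int j = (int)(next_rand() % (uint64_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double pg_max = R_NegInf, pg_min = R_PosInf;
    for (int k = 0; k < n; ++k) {
      const int i = idx[k];
      double f = w[d];
      for (int m = 0; m < d; ++m) f += w[m] * X(i, m);
      const double G = y[i] * f - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= U[i] && G < 0.0) PG = 0.0;
      if (PG > pg_max) pg_max = PG;
      if (PG < pg_min) pg_min = PG;
      if (PG != 0.0) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > U[i]) a_new = U[i];
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          alpha[i] = a_new;
          for (int m = 0; m < d; ++m) w[m] += delta * X(i, m);
          w[d] += delta;
        }
      }
    }
    viol = pg_max - pg_min;
    if (viol < tol) { converged = true; ++pass; break; }
  }
  NumericVector wv(d);
  for (int m = 0; m < d; ++m) wv[m] = w[m];
  return List::create(_["w"] = wv, _["c"] = w[d],
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass, _["converged"] = converged,
                      _["violation"] = viol);
}
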
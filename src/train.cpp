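// Gradient-descent training loop for the one-hidden-layer bottleneck network.
// The input patterns are always the N one-hot command vectors, i.e. the input
// matrix is the N x N identity; this lets the first linear layer be evaluated
// as a row-selection of W1, which the hot loop exploits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& a) {
  return 1.0 / (1.0 + exp(-a));
}

// [[Rcpp::export]]
Rcpp::List cpp_train_bottleneck(const arma::mat& target,
                                arma::mat W1, arma::vec B1,
                                arma::mat W2, arma::vec B2,
                                const int epochs,
                                const double lr,
                                const double momentum,
                                const int batch_size,
                                const unsigned int shuffle_seed,
                                const int trace_every,
                                const bool sigmoid_output) {
  const uword N = target.n_rows;
  const uword M = target.n_cols;
  const uword R = W1.n_cols;
  const double scale = 1.0 / double(N * M);

  mat vW1(N, R, fill::zeros), vW2(R, M, fill::zeros);
  vec vB1(R, fill::zeros), vB2(M, fill::zeros);

  std::mt19937 rng(shuffle_seed);
  uvec order = regspace<uvec>(0, N - 1);

  std::vector<double> trace_loss;
  std::vector<int> trace_epoch;
  int diverged_at = -1;

  const bool full_batch = (batch_size <= 0 || uword(batch_size) >= N);

  for (int ep = 0; ep < epochs; ++ep) {
    if (full_batch) {
      mat A1 = W1;
      A1.each_row() -= B1.t();
      mat H = sigmoid(A1);
      mat Y = H * W2;
      Y.each_row() -= B2.t();
      mat G2;
      if (sigmoid_output) {
        mat Ys = sigmoid(Y);
        G2 = (2.0 * scale) * (Ys - target) % Ys % (1.0 - Ys);
      } else {
        G2 = (2.0 * scale) * (Y - target);
      }
      mat GA1 = (G2 * W2.t()) % H % (1.0 - H);

      vW2 = momentum * vW2 - lr * (H.t() * G2);
      vB2 = momentum * vB2 + lr * sum(G2, 0).t();
      vW1 = momentum * vW1 - lr * GA1;
      vB1 = momentum * vB1 + lr * sum(GA1, 0).t();
      W2 += vW2; B2 += vB2; W1 += vW1; B1 += vB1;
    } else {
      // mini-batch pass over a fresh shuffle of the N one-hot inputs
      std::shuffle(order.begin(), order.end(), rng);
      for (uword start = 0; start < N; start += uword(batch_size)) {
        const uword stop = std::min(start + uword(batch_size), N) - 1;
        const uvec idx = order.subvec(start, stop);
        const double bscale = 1.0 / double(idx.n_elem * M);
        mat A1 = W1.rows(idx);
        A1.each_row() -= B1.t();
        mat H = sigmoid(A1);
        mat Y = H * W2;
        Y.each_row() -= B2.t();
        mat G2;
        if (sigmoid_output) {
          mat Ys = sigmoid(Y);
          G2 = (2.0 * bscale) * (Ys - target.rows(idx)) % Ys % (1.0 - Ys);
        } else {
          G2 = (2.0 * bscale) * (Y - target.rows(idx));
        }
        mat GA1 = (G2 * W2.t()) % H % (1.0 - H);

        vW2 = momentum * vW2 - lr * (H.t() * G2);
        vB2 = momentum * vB2 + lr * sum(G2, 0).t();
        mat vW1rows = momentum * vW1.rows(idx) - lr * GA1;
        vB1 = momentum * vB1 + lr * sum(GA1, 0).t();
        W2 += vW2; B2 += vB2;
        vW1.rows(idx) = vW1rows;
        W1.rows(idx) += vW1rows;
        B1 += vB1;
      }
    }

    if ((ep + 1) % trace_every == 0 || ep == epochs - 1) {
      mat A1 = W1;
      A1.each_row() -= B1.t();
      mat Y = sigmoid(A1) * W2;
      Y.each_row() -= B2.t();
      if (sigmoid_output) Y = sigmoid(Y);
      const double loss = accu(square(Y - target)) * scale;
      trace_epoch.push_back(ep + 1);
      trace_loss.push_back(loss);
      if (!std::isfinite(loss)) { diverged_at = ep + 1; break; }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("B1") = B1,
    Rcpp::Named("W2") = W2, Rcpp::Named("B2") = B2,
    Rcpp::Named("trace_epoch") = trace_epoch,
    Rcpp::Named("trace_loss") = trace_loss,
    Rcpp::Named("diverged_at") = diverged_at);
}
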
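#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fully connected MLP trainer (regression, linear last layer) with Adam.
//
// Loss: mean((pred + offset - y)^2) + lambda * mean((pred - y2)^2)
//   offset = 0, lambda = 0      -> plain MSE (naive NN, bias correction,
//                                  domain adaptation phases)
//   offset = y_PHY, lambda = 0  -> parallel physics (network learns the
//                                  residual; prediction = net + y_PHY)
//   offset = 0, y2 = y_PHY      -> physics regularisation (consistency term
//                                  weighted by lambda)
//
// Hidden activation: ReLU or tanh. Deterministic per seed: minibatch
// shuffling uses a private mt19937; weights are initialised in R.

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
  std::string act;
};

static arma::mat activate(const arma::mat &z, const std::string &act) {
  if (act == "relu") return arma::clamp(z, 0.0, arma::datum::inf);
  return arma::tanh(z);
}

static arma::mat activate_grad(const arma::mat &z, const std::string &act) {
  if (act == "relu") return arma::conv_to<arma::mat>::from(z > 0.0);
  arma::mat t = arma::tanh(z);
  return 1.0 - t % t;
}

// forward pass keeping pre-activations; X is n x d, returns layer outputs
static void forward(const Net &net, const arma::mat &X,
                    std::vector<arma::mat> &Z, std::vector<arma::mat> &A) {
  size_t L = net.W.size();
  Z.resize(L); A.resize(L);
  const arma::mat *in = &X;
  for (size_t l = 0; l < L; ++l) {
    Z[l] = (*in) * net.W[l];
    Z[l].each_row() += net.b[l].t();
    A[l] = (l + 1 < L) ? activate(Z[l], net.act) : Z[l];  // linear last layer
    in = &A[l];
  }
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat &X, const arma::vec &y,
                   const arma::vec &offset, const arma::vec &y2,
                   double lambda, List W0, List b0, std::string act,
                   int epochs, double lr, int batch_size, int seed,
                   double beta1, double beta2, double eps) {
  int n = X.n_rows;
  Net net; net.act = act;
  size_t L = W0.size();
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(W0[l]));
    net.b.push_back(as<arma::vec>(b0[l]));
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }
  if (net.W[L - 1].n_cols != 1) stop("last layer must have a single output");

  bool full_batch = batch_size <= 0 || batch_size >= n;
  std::mt19937 rng((unsigned) seed);
  std::vector<arma::uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  arma::vec loss_curve(epochs);
  std::vector<arma::mat> Z, A;
  arma::mat Xsub; arma::vec ysub, osub, y2sub;
  long long t = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0; int n_batches = 0;
    if (!full_batch) std::shuffle(idx.begin(), idx.end(), rng);
    int start = 0;
    while (start < n) {
      int stop_i = full_batch ? n : std::min(n, start + batch_size);
      arma::uvec rows;
      if (!full_batch) {
        rows.set_size(stop_i - start);
        for (int i = start; i < stop_i; ++i) rows[i - start] = idx[i];
      }
      const arma::mat &Xb = full_batch ? X : static_cast<const arma::mat &>(Xsub = X.rows(rows));
      const arma::vec &yb = full_batch ? y : static_cast<const arma::vec &>(ysub = y(rows));
      const arma::vec &ob = full_batch ? offset : static_cast<const arma::vec &>(osub = offset(rows));
      const arma::vec &y2b = full_batch ? y2 : static_cast<const arma::vec &>(y2sub = y2(rows));
      int nb = Xb.n_rows;

      forward(net, Xb, Z, A);
      arma::vec pred = A[L - 1].col(0);
      arma::vec r1 = pred + ob - yb;
      double loss = arma::dot(r1, r1) / nb;
      arma::vec dpred = 2.0 * r1 / nb;
      if (lambda > 0.0) {
        arma::vec r2 = pred - y2b;
        loss += lambda * arma::dot(r2, r2) / nb;
        dpred += lambda * 2.0 * r2 / nb;
      }
      ep_loss += loss; ++n_batches;

      // backward
      arma::mat delta = dpred;  // n x 1, grad wrt last pre-activation
      ++t;
      double bc1 = 1.0 - std::pow(beta1, (double) t);
      double bc2 = 1.0 - std::pow(beta2, (double) t);
      for (int l = (int) L - 1; l >= 0; --l) {
        const arma::mat &input = (l == 0) ? Xb : A[l - 1];
        arma::mat gW = input.t() * delta;
        arma::vec gb = arma::sum(delta, 0).t();
        if (l > 0)
          delta = (delta * net.W[l].t()) % activate_grad(Z[l - 1], net.act);
        // fused Adam update (no temporaries)
        double *mWp = mW[l].memptr(), *vWp = vW[l].memptr(),
               *Wp = net.W[l].memptr();
        const double *gWp = gW.memptr();
        arma::uword nW = gW.n_elem;
        double s1 = std::sqrt(1.0 / bc2);
        for (arma::uword i = 0; i < nW; ++i) {
          mWp[i] = beta1 * mWp[i] + (1.0 - beta1) * gWp[i];
          vWp[i] = beta2 * vWp[i] + (1.0 - beta2) * gWp[i] * gWp[i];
          Wp[i] -= lr * (mWp[i] / bc1) / (std::sqrt(vWp[i]) * s1 + eps);
        }
        double *mbp = mb[l].memptr(), *vbp = vb[l].memptr(),
               *bp = net.b[l].memptr();
        const double *gbp = gb.memptr();
        for (arma::uword i = 0; i < gb.n_elem; ++i) {
          mbp[i] = beta1 * mbp[i] + (1.0 - beta1) * gbp[i];
          vbp[i] = beta2 * vbp[i] + (1.0 - beta2) * gbp[i] * gbp[i];
          bp[i] -= lr * (mbp[i] / bc1) / (std::sqrt(vbp[i]) * s1 + eps);
        }
      }
      if (!net.W[0].is_finite())
        stop("non-finite weights at epoch %d", ep + 1);
      start = full_batch ? n : stop_i;
    }
    loss_curve[ep] = ep_loss / n_batches;
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = net.W[l]; bout[l] = net.b[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss_curve"] = NumericVector(loss_curve.begin(), loss_curve.end()));
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const arma::mat &X, List W, List b, std::string act) {
  Net net; net.act = act;
  size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(W[l]));
    net.b.push_back(as<arma::vec>(b[l]));
  }
  std::vector<arma::mat> Z, A;
  forward(net, X, Z, A);
  return A[L - 1].col(0);
}
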
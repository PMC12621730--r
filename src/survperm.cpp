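// Numerical core: Cox partial-likelihood loss and gradient, concordance index,
// and the mini-batch Adam training loop for the feed-forward risk network.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Order of indices by time, descending. Ties keep original order (stable).
static arma::uvec order_desc(const arma::vec& time) {
  return arma::stable_sort_index(time, "descend");
}

// Risk-set denominators S_i = sum_{j: T_j >= T_i} exp(xi_j - M) for every
// subject, positions in descending-time order. Ties share the same risk set.
static void risk_denoms(const arma::vec& xi, const arma::vec& time,
                        const arma::uvec& ord, double M,
                        arma::vec& exps, arma::vec& S) {
  const arma::uword n = ord.n_elem;
  exps.set_size(n);
  S.set_size(n);
  for (arma::uword k = 0; k < n; ++k) exps[k] = std::exp(xi[ord[k]] - M);
  double run = 0.0;
  arma::uword k = 0;
  while (k < n) {
    arma::uword k2 = k;
    const double t = time[ord[k]];
    while (k2 < n && time[ord[k2]] == t) { run += exps[k2]; ++k2; }
    for (arma::uword j = k; j < k2; ++j) S[j] = run;
    k = k2;
  }
}

// Negative mean Cox partial log-likelihood (Breslow risk sets T_j >= T_i),
// averaged over events, log-sum-exp stabilized.
// [[Rcpp::export]]
double cpp_negpll(const arma::vec& xi, const arma::vec& time,
                  const arma::ivec& status) {
  const arma::uword n = xi.n_elem;
  if (time.n_elem != n || status.n_elem != n)
    stop("xi, time and status must have equal length");
  const double m = arma::accu(status == 1);
  if (m < 1) stop("partial likelihood undefined: no events");
  const double M = xi.max();
  arma::uvec ord = order_desc(time);
  arma::vec exps, S;
  risk_denoms(xi, time, ord, M, exps, S);
  double ll = 0.0;
  for (arma::uword k = 0; k < n; ++k) {
    const arma::uword i = ord[k];
    if (status[i] == 1) ll += xi[i] - M - std::log(S[k]);
  }
  return -ll / m;
}

// Gradient of cpp_negpll with respect to xi.
// [[Rcpp::export]]
arma::vec cpp_negpll_grad(const arma::vec& xi, const arma::vec& time,
                          const arma::ivec& status) {
  const arma::uword n = xi.n_elem;
  const double m = arma::accu(status == 1);
  if (m < 1) stop("partial likelihood undefined: no events");
  const double M = xi.max();
  arma::uvec ord = order_desc(time);
  arma::vec exps, S;
  risk_denoms(xi, time, ord, M, exps, S);
  arma::vec grad(n, arma::fill::zeros);
  // ascending-time sweep: cum = sum over events i with T_i <= T_k of 1/S_i
  double cum = 0.0;
  arma::sword k = (arma::sword)n - 1;
  while (k >= 0) {
    arma::sword k2 = k;
    const double t = time[ord[(arma::uword)k]];
    while (k2 >= 0 && time[ord[(arma::uword)k2]] == t) --k2;
    for (arma::sword j = k; j > k2; --j) {
      const arma::uword idx = ord[(arma::uword)j];
      if (status[idx] == 1) cum += 1.0 / S[(arma::uword)j];
    }
    for (arma::sword j = k; j > k2; --j) {
      const arma::uword idx = ord[(arma::uword)j];
      const double d = (status[idx] == 1) ? 1.0 : 0.0;
      grad[idx] = -(d - exps[(arma::uword)j] * cum) / m;
    }
    k = k2;
  }
  return grad;
}

// Concordance index, literal strict-inequality form: ordered pairs (i, j) with
// T_i > T_j and delta_j = 1 are comparable; a pair is concordant when
// xi_i < xi_j. With half_ties, prediction ties count 1/2.
// [[Rcpp::export]]
double cpp_cindex(const arma::vec& xi, const arma::vec& time,
                  const arma::ivec& status, bool half_ties) {
  const arma::uword n = xi.n_elem;
  double num = 0.0, den = 0.0;
  for (arma::uword j = 0; j < n; ++j) {
    if (status[j] != 1) continue;
    const double tj = time[j], xj = xi[j];
    for (arma::uword i = 0; i < n; ++i) {
      if (time[i] > tj) {
        den += 1.0;
        if (xi[i] < xj) num += 1.0;
        else if (half_ties && xi[i] == xj) num += 0.5;
      }
    }
  }
  if (den == 0.0) stop("concordance undefined: no comparable pairs");
  return num / den;
}

// C-index for each column of a prediction matrix (shared time/status).
// The comparable-pair list is precomputed once.
// [[Rcpp::export]]
arma::vec cpp_cindex_multi(const arma::mat& ximat, const arma::vec& time,
                           const arma::ivec& status, bool half_ties) {
  const arma::uword n = ximat.n_rows, R = ximat.n_cols;
  std::vector<arma::uword> pi, pj;
  for (arma::uword j = 0; j < n; ++j) {
    if (status[j] != 1) continue;
    for (arma::uword i = 0; i < n; ++i)
      if (time[i] > time[j]) { pi.push_back(i); pj.push_back(j); }
  }
  const double den = (double)pi.size();
  if (den == 0.0) stop("concordance undefined: no comparable pairs");
  arma::vec out(R);
  for (arma::uword r = 0; r < R; ++r) {
    const double* col = ximat.colptr(r);
    double num = 0.0;
    for (size_t k = 0; k < pi.size(); ++k) {
      const double a = col[pi[k]], b = col[pj[k]];
      if (a < b) num += 1.0;
      else if (half_ties && a == b) num += 0.5;
    }
    out[r] = num / den;
  }
  return out;
}

// Forward pass: K ReLU hidden layers, affine output, no offset subtraction.
// weights[l]: (s_{l+1} x s_l), biases[l]: length s_{l+1}; X is m x p.
// [[Rcpp::export]]
arma::vec cpp_forward(const List& weights, const List& biases,
                      const arma::mat& X) {
  const int L = weights.size();
  arma::mat A = X.t();
  for (int l = 0; l < L; ++l) {
    const arma::mat W = as<arma::mat>(weights[l]);
    const arma::vec b = as<arma::vec>(biases[l]);
    if (W.n_cols != A.n_rows) stop("layer %d: expected %d inputs, got %d",
                                   l + 1, (int)W.n_cols, (int)A.n_rows);
    A = W * A;
    A.each_col() += b;
    if (l < L - 1) A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  return arma::vectorise(A.row(0));
}

// Train the network by mini-batch Adam on the within-batch negative partial
// log-likelihood plus an L1 penalty on the weight matrices (biases excluded).
// Returns weights, biases and the number of skipped batches.
// [[Rcpp::export]]
List cpp_train_net(const arma::mat& X, const arma::vec& time,
                   const arma::ivec& status, const arma::ivec& hidden,
                   double l1, double lr, int batch_size, int epochs,
                   int seed) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const int K = hidden.n_elem;
  std::vector<arma::uword> sizes(K + 2);
  sizes[0] = p;
  for (int k = 0; k < K; ++k) sizes[k + 1] = (arma::uword)hidden[k];
  sizes[K + 1] = 1;

  std::mt19937_64 eng((uint64_t)seed);
  std::vector<arma::mat> W(K + 1), mW(K + 1), vW(K + 1);
  std::vector<arma::vec> b(K + 1), mb(K + 1), vb(K + 1);
  for (int l = 0; l <= K; ++l) {
    const double s = 1.0 / std::sqrt((double)sizes[l]);
    std::uniform_real_distribution<double> unif(-s, s);
    W[l].set_size(sizes[l + 1], sizes[l]);
    for (arma::uword c = 0; c < W[l].n_cols; ++c)
      for (arma::uword r = 0; r < W[l].n_rows; ++r) W[l](r, c) = unif(eng);
    b[l].set_size(sizes[l + 1]);
    for (arma::uword r = 0; r < b[l].n_elem; ++r) b[l][r] = unif(eng);
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(arma::size(b[l])); vb[l].zeros(arma::size(b[l]));
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  int skipped = 0;
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<arma::mat> A(K + 2), Z(K + 1);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), eng);
    for (arma::uword start = 0; start < n; start += (arma::uword)batch_size) {
      const arma::uword end = std::min(n, start + (arma::uword)batch_size);
      const arma::uword m = end - start;
      if (m < 2) { ++skipped; continue; }
      arma::uvec bidx(m);
      for (arma::uword i = 0; i < m; ++i) bidx[i] = idx[start + i];
      arma::ivec st = status.elem(bidx);
      if (arma::accu(st == 1) < 1) { ++skipped; continue; }
      arma::vec tm = time.elem(bidx);

      // forward
      A[0] = X.rows(bidx).t();
      for (int l = 0; l <= K; ++l) {
        Z[l] = W[l] * A[l];
        Z[l].each_col() += b[l];
        A[l + 1] = (l < K) ? arma::clamp(Z[l], 0.0, arma::datum::inf) : Z[l];
      }
      arma::vec xi = arma::vectorise(A[K + 1].row(0));

      // backward
      arma::vec g = cpp_negpll_grad(xi, tm, st);
      arma::mat delta = g.t();  // 1 x m
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = K; l >= 0; --l) {
        arma::mat dW = delta * A[l].t();
        if (l1 > 0.0) dW += l1 * arma::sign(W[l]);
        arma::vec db = arma::sum(delta, 1);
        if (l > 0)
          delta = (W[l].t() * delta) % arma::conv_to<arma::mat>::from(Z[l - 1] > 0.0);
        mW[l] = beta1 * mW[l] + (1 - beta1) * dW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * (dW % dW);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * db;
        vb[l] = beta2 * vb[l] + (1 - beta2) * (db % db);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
  }

  List Wl(K + 1), bl(K + 1);
  for (int l = 0; l <= K; ++l) { Wl[l] = W[l]; bl[l] = b[l]; }
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["skipped_batches"] = skipped);
}

// Concordance of ensemble risks under R permutations of one feature column.
// The first-layer pre-activations of each member are computed once; each
// permutation only shifts them by a rank-1 update w_j (x_perm - x_j)'.
// members_w / members_b: per-member lists of layer weights / biases;
// perms: m x R matrix of 1-based permutation indices.
// [[Rcpp::export]]
arma::vec cpp_ensemble_perm_cindex(const List& members_w, const List& members_b,
                                   const arma::vec& offsets, const arma::mat& X,
                                   int j, const arma::umat& perms,
                                   const arma::vec& time, const arma::ivec& status,
                                   bool half_ties) {
  const arma::uword m = X.n_rows, R = perms.n_cols, q = members_w.size();
  if (j < 1 || j > (int)X.n_cols) stop("column index out of range");
  const arma::uword j0 = (arma::uword)(j - 1);

  std::vector<std::vector<arma::mat>> W(q);
  std::vector<std::vector<arma::vec>> b(q);
  std::vector<arma::mat> zbase(q);
  std::vector<arma::vec> w1j(q);
  for (arma::uword k = 0; k < q; ++k) {
    List wk = members_w[k], bk = members_b[k];
    for (int l = 0; l < wk.size(); ++l) {
      W[k].push_back(as<arma::mat>(wk[l]));
      b[k].push_back(as<arma::vec>(bk[l]));
    }
    zbase[k] = W[k][0] * X.t();
    zbase[k].each_col() += b[k][0];
    w1j[k] = W[k][0].col(j0);
  }

  std::vector<arma::uword> pi, pj;
  for (arma::uword jj = 0; jj < m; ++jj) {
    if (status[jj] != 1) continue;
    for (arma::uword ii = 0; ii < m; ++ii)
      if (time[ii] > time[jj]) { pi.push_back(ii); pj.push_back(jj); }
  }
  const double den = (double)pi.size();
  if (den == 0.0) stop("concordance undefined: no comparable pairs");

  arma::vec out(R);
  const arma::vec xj = X.col(j0);
  for (arma::uword r = 0; r < R; ++r) {
    arma::vec dx(m);
    for (arma::uword i = 0; i < m; ++i) dx[i] = xj[perms(i, r) - 1] - xj[i];
    arma::vec ens(m, arma::fill::zeros);
    for (arma::uword k = 0; k < q; ++k) {
      arma::mat A = zbase[k] + w1j[k] * dx.t();
      A.transform([](double v) { return v > 0.0 ? v : 0.0; });
      const int L = W[k].size();
      for (int l = 1; l < L; ++l) {
        A = W[k][l] * A;
        A.each_col() += b[k][l];
        if (l < L - 1) A.transform([](double v) { return v > 0.0 ? v : 0.0; });
      }
      ens += arma::vectorise(A.row(0)) - offsets[k];
    }
    double num = 0.0;
    for (size_t t = 0; t < pi.size(); ++t) {
      const double a = ens[pi[t]], c = ens[pj[t]];
      if (a < c) num += 1.0;
      else if (half_ties && a == c) num += 0.5;
    }
    out[r] = num / den;
  }
  return out;
}

// In-place column overwrite for a matrix owned by the caller (used to reuse
// one row-stacked scratch matrix across features instead of reallocating).
// [[Rcpp::export]]
void cpp_set_column(NumericMatrix M, int j, const NumericVector& v) {
  if (j < 1 || j > M.ncol()) stop("column index out of range");
  if (v.size() != M.nrow()) stop("length mismatch");
  std::copy(v.begin(), v.end(), M.column(j - 1).begin());
}
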
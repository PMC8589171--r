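// Training core for the differential prototype network and the small MLP
// used by the KMNN baseline. Gradients are derived by hand and checked
// against central finite differences in the test suite.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Parameter order inside the flat parameter vector. Biases are 1 x n
// matrices and the classifier output weight is h x 1 so that a single
// std::vector<mat> can hold every trainable tensor.
enum ParIdx { iWe1, ibe1, iWe2, ibe2, iWd1, ibd1, iWd2, ibd2, iP,
              iWc1, ibc1, iwc2, ibc2, NPAR };

static const char* par_names[NPAR] = {
  "We1", "be1", "We2", "be2", "Wd1", "bd1", "Wd2", "bd2", "P",
  "Wc1", "bc1", "wc2", "bc2" };

struct LossParts { double total, L1, L2, L3, intra, inter; };

static std::vector<mat> pars_from_list(const Rcpp::List& params) {
  std::vector<mat> th(NPAR);
  for (int i = 0; i < NPAR; ++i)
    th[i] = Rcpp::as<mat>(params[par_names[i]]);
  return th;
}

static Rcpp::List pars_to_list(const std::vector<mat>& th) {
  Rcpp::List out;
  for (int i = 0; i < NPAR; ++i) out[par_names[i]] = th[i];
  return out;
}

// Pairwise distances between rows of A (n x q) and rows of P (l x q).
// squared = true gives squared Euclidean distances.
static mat row_distances(const mat& A, const mat& P, bool squared) {
  mat D = repmat(sum(square(A), 1), 1, P.n_rows)
        + repmat(sum(square(P), 1).t(), A.n_rows, 1)
        - 2.0 * A * P.t();
  D.clamp(0.0, datum::inf);
  if (!squared) D = sqrt(D);
  return D;
}

// Forward pass + (optionally) analytic gradients of the combined loss
//   L = L1 + lambda1 * L2 + lambda2 * L3
// on one mini-batch. When grad != nullptr the gradients of L with
// respect to every parameter are accumulated into *grad (assumed
// zero-initialised with matching shapes).
static LossParts dpnn_loss_grad_core(const std::vector<mat>& th,
                                     const mat& X, const uvec& t, const vec& y,
                                     int k, double lam1, double lam2, double alpha,
                                     bool sq_dist, bool norm_lk, bool use_protos,
                                     double eps_clamp, std::vector<mat>* grad) {
  const int B = X.n_rows;
  const mat& We1 = th[iWe1]; const mat& be1 = th[ibe1];
  const mat& We2 = th[iWe2]; const mat& be2 = th[ibe2];
  const mat& Wd1 = th[iWd1]; const mat& bd1 = th[ibd1];
  const mat& Wd2 = th[iWd2]; const mat& bd2 = th[ibd2];
  const mat& P   = th[iP];
  const mat& Wc1 = th[iWc1]; const mat& bc1 = th[ibc1];
  const mat& wc2 = th[iwc2]; const mat& bc2 = th[ibc2];
  const int ell = P.n_rows;
  const int q = P.n_cols;
  const int rep_dim = use_protos ? ell : q;

  // ----- encoder / decoder -----
  mat H1p = X * We1; H1p.each_row() += be1.row(0);
  mat H1 = clamp(H1p, 0.0, datum::inf);
  mat Z = H1 * We2; Z.each_row() += be2.row(0);
  mat G1p = Z * Wd1; G1p.each_row() += bd1.row(0);
  mat G1 = clamp(G1p, 0.0, datum::inf);
  mat Xh = G1 * Wd2; Xh.each_row() += bd2.row(0);

  // ----- prototype distances + classifier (patient path) -----
  mat D;
  mat C(B, rep_dim + k, fill::zeros);
  if (use_protos) {
    D = row_distances(Z, P, sq_dist);
    C.cols(0, ell - 1) = D;
  } else {
    C.cols(0, q - 1) = Z;
  }
  for (int i = 0; i < B; ++i) C(i, rep_dim + t(i)) = 1.0;
  mat H2p = C * Wc1; H2p.each_row() += bc1.row(0);
  mat H2 = clamp(H2p, 0.0, datum::inf);
  vec s = H2 * wc2.col(0) + bc2(0, 0);
  vec p = 1.0 / (1.0 + exp(-s));
  vec pc = clamp(p, eps_clamp, 1.0 - eps_clamp);

  LossParts out;
  out.L1 = -accu(y % log(pc) + (1.0 - y) % log(1.0 - pc)) / B;

  vec rec_norm(B);
  mat R = Xh - X;
  for (int i = 0; i < B; ++i) rec_norm(i) = norm(R.row(i), 2);
  out.L2 = accu(rec_norm) / B;

  // ----- prototype outcome matrix Y_P (l x k) -----
  mat DP, YP(ell, k), H2P_all;                 // H2P stacked per treatment
  std::vector<mat> H2Pp(k), CP(k);
  double div = norm_lk ? double(ell) * k : double(ell);
  if (use_protos) {
    DP = row_distances(P, P, sq_dist);
    DP.diag().zeros();
    for (int kk = 0; kk < k; ++kk) {
      mat Cp(ell, ell + k, fill::zeros);
      Cp.cols(0, ell - 1) = DP;
      Cp.col(ell + kk).ones();
      mat hp = Cp * Wc1; hp.each_row() += bc1.row(0);
      H2Pp[kk] = hp;
      CP[kk] = Cp;
      mat h = clamp(hp, 0.0, datum::inf);
      vec sp = h * wc2.col(0) + bc2(0, 0);
      YP.col(kk) = 1.0 / (1.0 + exp(-sp));
    }
    vec mu_row = mean(YP, 1);
    rowvec mu_col = mean(YP, 0);
    mat dev_row = YP; dev_row.each_col() -= mu_row;
    mat dev_col = YP; dev_col.each_row() -= mu_col;
    out.intra = accu(square(dev_row)) / div;
    out.inter = accu(square(dev_col)) / div;
    out.L3 = -(alpha * out.intra + (1.0 - alpha) * out.inter);
  } else {
    out.intra = out.inter = 0.0; out.L3 = 0.0;
  }

  out.total = out.L1 + lam1 * out.L2 + lam2 * out.L3;
  if (!grad) return out;
  std::vector<mat>& g = *grad;

  // ----- backward: L1 through classifier (patient path) -----
  vec ds = (p - y) / B;                       // dL1/ds
  g[iwc2].col(0) += H2.t() * ds;
  g[ibc2](0, 0) += accu(ds);
  mat dH2 = ds * wc2.col(0).t();
  mat dH2m = dH2 % (H2p > 0);
  g[iWc1] += C.t() * dH2m;
  g[ibc1].row(0) += sum(dH2m, 0);
  mat dC = dH2m * Wc1.t();

  mat dZ(B, q, fill::zeros);
  if (use_protos) {
    mat dD = dC.cols(0, ell - 1);
    if (sq_dist) {
      dZ += 2.0 * (Z.each_col() % sum(dD, 1)) - 2.0 * dD * P;
      g[iP] += 2.0 * (P.each_col() % sum(dD, 0).t()) - 2.0 * dD.t() * Z;
    } else {
      mat E = dD / clamp(D, 1e-12, datum::inf);
      dZ += (Z.each_col() % sum(E, 1)) - E * P;
      g[iP] += (P.each_col() % sum(E, 0).t()) - E.t() * Z;
    }
  } else {
    dZ += dC.cols(0, q - 1);
  }

  // ----- backward: lambda1 * L2 through decoder -----
  mat dXh = R;
  for (int i = 0; i < B; ++i)
    dXh.row(i) *= lam1 / (B * std::max(rec_norm(i), 1e-12));
  g[iWd2] += G1.t() * dXh;
  g[ibd2].row(0) += sum(dXh, 0);
  mat dG1m = (dXh * Wd2.t()) % (G1p > 0);
  g[iWd1] += Z.t() * dG1m;
  g[ibd1].row(0) += sum(dG1m, 0);
  dZ += dG1m * Wd1.t();

  // ----- backward: lambda2 * L3 through Y_P -----
  if (use_protos && lam2 != 0.0) {
    vec mu_row = mean(YP, 1);
    rowvec mu_col = mean(YP, 0);
    mat dev_row = YP; dev_row.each_col() -= mu_row;
    mat dev_col = YP; dev_col.each_row() -= mu_col;
    mat dYP = -lam2 * (alpha * (2.0 / div) * dev_row
                       + (1.0 - alpha) * (2.0 / div) * dev_col);
    mat dDP(ell, ell, fill::zeros);
    for (int kk = 0; kk < k; ++kk) {
      vec yp = YP.col(kk);
      vec dsp = dYP.col(kk) % yp % (1.0 - yp);
      mat h = clamp(H2Pp[kk], 0.0, datum::inf);
      g[iwc2].col(0) += h.t() * dsp;
      g[ibc2](0, 0) += accu(dsp);
      mat dh = (dsp * wc2.col(0).t()) % (H2Pp[kk] > 0);
      g[iWc1] += CP[kk].t() * dh;
      g[ibc1].row(0) += sum(dh, 0);
      mat dCp = dh * Wc1.t();
      dDP += dCp.cols(0, ell - 1);
    }
    dDP.diag().zeros();                      // self-distance is constant 0
    if (sq_dist) {
      g[iP] += 2.0 * (P.each_col() % sum(dDP, 1)) - 2.0 * dDP * P;   // query rows
      g[iP] += 2.0 * (P.each_col() % sum(dDP, 0).t()) - 2.0 * dDP.t() * P; // reference cols
    } else {
      mat Deuc = row_distances(P, P, false);
      mat E = dDP / clamp(Deuc, 1e-12, datum::inf);
      E.diag().zeros();
      g[iP] += (P.each_col() % sum(E, 1)) - E * P;
      g[iP] += (P.each_col() % sum(E, 0).t()) - E.t() * P;
    }
  }

  // ----- backward: encoder -----
  g[iWe2] += H1.t() * dZ;
  g[ibe2].row(0) += sum(dZ, 0);
  mat dH1m = (dZ * We2.t()) % (H1p > 0);
  g[iWe1] += X.t() * dH1m;
  g[ibe1].row(0) += sum(dH1m, 0);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_dpnn_loss_grad(Rcpp::List params, const arma::mat& X,
                              const arma::uvec& t, const arma::vec& y,
                              int k, double lambda1, double lambda2, double alpha,
                              bool sq_dist, bool norm_lk, bool use_protos,
                              double eps_clamp, bool with_grad) {
  std::vector<mat> th = pars_from_list(params);
  std::vector<mat> g(NPAR);
  if (with_grad)
    for (int i = 0; i < NPAR; ++i) g[i] = zeros<mat>(th[i].n_rows, th[i].n_cols);
  LossParts lp = dpnn_loss_grad_core(th, X, t, y, k, lambda1, lambda2, alpha,
                                     sq_dist, norm_lk, use_protos, eps_clamp,
                                     with_grad ? &g : nullptr);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = lp.total, Rcpp::Named("L1") = lp.L1,
    Rcpp::Named("L2") = lp.L2, Rcpp::Named("L3") = lp.L3,
    Rcpp::Named("intra") = lp.intra, Rcpp::Named("inter") = lp.inter);
  if (with_grad) out["grad"] = pars_to_list(g);
  return out;
}

// Adam update applied in place.
static void adam_step(std::vector<mat>& th, const std::vector<mat>& g,
                      std::vector<mat>& m, std::vector<mat>& v,
                      double lr, double b1, double b2, double eps, int step) {
  double c1 = 1.0 - std::pow(b1, step), c2 = 1.0 - std::pow(b2, step);
  for (size_t i = 0; i < th.size(); ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * square(g[i]);
    th[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_dpnn_train(Rcpp::List params, const arma::mat& X,
                          const arma::uvec& t, const arma::vec& y,
                          int k, double lambda1, double lambda2, double alpha,
                          double lr, int epochs, int batch_size,
                          bool sq_dist, bool norm_lk, bool use_protos,
                          double eps_clamp, int seed) {
  std::vector<mat> th = pars_from_list(params);
  std::vector<mat> m(NPAR), v(NPAR), g(NPAR);
  for (int i = 0; i < NPAR; ++i) {
    m[i] = zeros<mat>(th[i].n_rows, th[i].n_cols);
    v[i] = zeros<mat>(th[i].n_rows, th[i].n_cols);
    g[i] = zeros<mat>(th[i].n_rows, th[i].n_cols);
  }
  const int N = X.n_rows;
  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  vec epoch_loss(std::max(epochs, 0), fill::zeros);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double acc = 0.0; int nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      int stop = std::min(start + batch_size, N);
      uvec rows(stop - start);
      for (int i = start; i < stop; ++i) rows(i - start) = idx[i];
      mat Xb = X.rows(rows);
      uvec tb = t.elem(rows);
      vec yb = y.elem(rows);
      for (int i = 0; i < NPAR; ++i) g[i].zeros();
      LossParts lp = dpnn_loss_grad_core(th, Xb, tb, yb, k, lambda1, lambda2,
                                         alpha, sq_dist, norm_lk, use_protos,
                                         eps_clamp, &g);
      if (!std::isfinite(lp.total))
        Rcpp::stop("non-finite training loss at epoch %d (L1=%g L2=%g L3=%g)",
                   ep + 1, lp.L1, lp.L2, lp.L3);
      adam_step(th, g, m, v, lr, 0.9, 0.999, 1e-8, ++step);
      acc += lp.total; ++nb;
    }
    epoch_loss(ep) = acc / std::max(nb, 1);
    if (ep % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pars_to_list(th),
                            Rcpp::Named("epoch_loss") = epoch_loss);
}

// Forward pass of the fitted network for arbitrary treatment assignments.
// Returns an N x k matrix of remission probabilities (every treatment for
// every row).
// [[Rcpp::export]]
arma::mat cpp_dpnn_predict_all(Rcpp::List params, const arma::mat& X, int k,
                               bool sq_dist, bool use_protos) {
  std::vector<mat> th = pars_from_list(params);
  mat H1 = clamp(X * th[iWe1] + repmat(th[ibe1].row(0), X.n_rows, 1), 0.0, datum::inf);
  mat Z = H1 * th[iWe2] + repmat(th[ibe2].row(0), X.n_rows, 1);
  mat rep = use_protos ? row_distances(Z, th[iP], sq_dist) : Z;
  const int n = X.n_rows, rd = rep.n_cols;
  mat out(n, k);
  for (int kk = 0; kk < k; ++kk) {
    mat C(n, rd + k, fill::zeros);
    C.cols(0, rd - 1) = rep;
    C.col(rd + kk).ones();
    mat H2 = clamp(C * th[iWc1] + repmat(th[ibc1].row(0), n, 1), 0.0, datum::inf);
    vec s = H2 * th[iwc2].col(0) + th[ibc2](0, 0);
    out.col(kk) = 1.0 / (1.0 + exp(-s));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small fully connected binary classifier (one ReLU hidden layer, sigmoid
// output) trained with mini-batch Adam on mean binary cross-entropy.
// Used as the separately trained classification head of the KMNN baseline.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_mlp_train(Rcpp::List params, const arma::mat& X, const arma::vec& y,
                         double lr, int epochs, int batch_size, double eps_clamp,
                         int seed) {
  mat W1 = Rcpp::as<mat>(params["W1"]); mat b1 = Rcpp::as<mat>(params["b1"]);
  mat w2 = Rcpp::as<mat>(params["w2"]); mat b2 = Rcpp::as<mat>(params["b2"]);
  std::vector<mat> th = {W1, b1, w2, b2};
  std::vector<mat> m(4), v(4), g(4);
  for (int i = 0; i < 4; ++i) {
    m[i] = zeros<mat>(th[i].n_rows, th[i].n_cols);
    v[i] = m[i]; g[i] = m[i];
  }
  const int N = X.n_rows;
  std::mt19937 rng(seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  int step = 0;
  vec epoch_loss(std::max(epochs, 0), fill::zeros);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double acc = 0.0; int nb = 0;
    for (int start = 0; start < N; start += batch_size) {
      int stop = std::min(start + batch_size, N);
      uvec rows(stop - start);
      for (int i = start; i < stop; ++i) rows(i - start) = idx[i];
      mat Xb = X.rows(rows);
      vec yb = y.elem(rows);
      int B = Xb.n_rows;
      mat H1p = Xb * th[0] + repmat(th[1].row(0), B, 1);
      mat H1 = clamp(H1p, 0.0, datum::inf);
      vec s = H1 * th[2].col(0) + th[3](0, 0);
      vec p = 1.0 / (1.0 + exp(-s));
      vec pc = clamp(p, eps_clamp, 1.0 - eps_clamp);
      double loss = -accu(yb % log(pc) + (1.0 - yb) % log(1.0 - pc)) / B;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite classifier loss at epoch %d", ep + 1);
      vec ds = (p - yb) / B;
      g[2].col(0) = H1.t() * ds;
      g[3](0, 0) = accu(ds);
      mat dH1 = (ds * th[2].col(0).t()) % (H1p > 0);
      g[0] = Xb.t() * dH1;
      g[1].row(0) = sum(dH1, 0);
      adam_step(th, g, m, v, lr, 0.9, 0.999, 1e-8, ++step);
      acc += loss; ++nb;
    }
    epoch_loss(ep) = acc / std::max(nb, 1);
    if (ep % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::List::create(
      Rcpp::Named("W1") = th[0], Rcpp::Named("b1") = th[1],
      Rcpp::Named("w2") = th[2], Rcpp::Named("b2") = th[3]),
    Rcpp::Named("epoch_loss") = epoch_loss);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_forward(Rcpp::List params, const arma::mat& X) {
  mat W1 = Rcpp::as<mat>(params["W1"]); mat b1 = Rcpp::as<mat>(params["b1"]);
  mat w2 = Rcpp::as<mat>(params["w2"]); mat b2 = Rcpp::as<mat>(params["b2"]);
  mat H1 = clamp(X * W1 + repmat(b1.row(0), X.n_rows, 1), 0.0, datum::inf);
  vec s = H1 * w2.col(0) + b2(0, 0);
  return 1.0 / (1.0 + exp(-s));
}
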
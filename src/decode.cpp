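// Fast inner loops for time-resolved pairwise SVM decoding.
//
// The classifier is a soft-margin linear C-SVC solved in the dual by SMO with
// maximal-violating-pair working-set selection (the libsvm formulation, with
// the equality constraint sum(alpha_i y_i) = 0 and an explicit bias).  Problems
// here are tiny (a handful of pseudo-trials per class) but are solved millions
// of times across condition pairs, time points and sub-averaging repetitions,
// hence C++.  All randomness goes through R's RNG so set.seed() governs every
// assignment.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SMO_EPS = 1e-8;
static const int SMO_MAX_ITER = 20000;

// Solve min 1/2 a'Qa - e'a  s.t. y'a = 0, 0 <= a <= C, with Q_ij = y_i y_j K_ij.
// Returns bias b; alpha filled in place.
static double smo_solve(const arma::mat& K, const arma::ivec& y, double C,
                        arma::vec& alpha) {
  const int n = K.n_rows;
  alpha.zeros(n);
  arma::vec G(n);
  G.fill(-1.0); // gradient of dual objective at alpha = 0

  double Gmax = 0.0, Gmin = 0.0;
  for (int iter = 0; iter < SMO_MAX_ITER; ++iter) {
    int i = -1, j = -1;
    Gmax = -arma::datum::inf;
    Gmin = arma::datum::inf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (lo && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < SMO_EPS) break;

    const double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias: average -y_i G_i over free support vectors, else the midpoint
  double num = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) {
      num += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) return num / nfree;
  return 0.5 * (Gmax + Gmin);
}

// Decision values f(x) = sum_i alpha_i y_i <x_i, x> + b for test rows.
// Rows of Xtrain/Xtest are observations. Class +1 is predicted when f >= 0.
// [[Rcpp::export]]
arma::vec cpp_svm_decision(const arma::mat& Xtrain, const arma::ivec& y,
                           double C, const arma::mat& Xtest) {
  arma::mat K = Xtrain * Xtrain.t();
  arma::vec alpha;
  const double b = smo_solve(K, y, C, alpha);
  arma::vec coef = alpha % arma::conv_to<arma::vec>::from(y);
  return Xtest * (Xtrain.t() * coef) + b;
}

// 0-based group assignment: perm is a permutation of 0..(n-1); pseudo-trial p
// averages raw trials perm[p*k .. p*k+k-1].
static arma::mat pseudotrials(const arma::mat& X, const arma::uvec& perm,
                              int k, int P) {
  arma::mat out(X.n_rows, P, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    for (int q = 0; q < k; ++q) out.col(p) += X.col(perm[p * k + q]);
    out.col(p) /= k;
  }
  return out;
}

// column r of a 1-based permutation matrix -> 0-based uvec
static arma::uvec perm_col(const arma::imat& perms, int r) {
  arma::uvec out(perms.n_rows);
  for (arma::uword i = 0; i < perms.n_rows; ++i) out[i] = perms(i, r) - 1;
  return out;
}

// Leave-one-pseudotrial-out-per-class pairwise decoding accuracy over time.
// A, B: channels x trials x time cubes for the two conditions (one subject).
// permA/permB: 1-based permutation matrices (trials x repetitions) fixing the
// random sub-averaging assignment of each repetition (drawn in R).
// Returns % correct per time point, averaged over folds and repetitions.
// [[Rcpp::export]]
arma::vec cpp_pair_loo(const arma::cube& A, const arma::cube& B,
                       int k, double C,
                       const arma::imat& permA, const arma::imat& permB) {
  const int T = A.n_slices;
  const int nA = A.n_cols, nB = B.n_cols;
  const int n_rep = permA.n_cols;
  const int P = std::min(nA / k, nB / k);
  if (P < 2) stop("need at least 2 pseudo-trials per class (M >= 2k)");
  if ((int)permA.n_rows != nA || (int)permB.n_rows != nB ||
      (int)permB.n_cols != n_rep) stop("permutation matrices do not match data");

  arma::vec acc(T, arma::fill::zeros);
  const int n_tr = 2 * P - 2;
  arma::ivec ylab(n_tr);
  for (int t = 0; t < n_tr; ++t) ylab[t] = (t < P - 1) ? 1 : -1;

  arma::mat Ksub(n_tr, n_tr);
  arma::vec alpha;

  for (int rep = 0; rep < n_rep; ++rep) {
    arma::uvec pA = perm_col(permA, rep), pB = perm_col(permB, rep);
    for (int t = 0; t < T; ++t) {
      arma::mat Z(A.n_rows, 2 * P);
      Z.cols(0, P - 1) = pseudotrials(A.slice(t), pA, k, P);
      Z.cols(P, 2 * P - 1) = pseudotrials(B.slice(t), pB, k, P);
      arma::mat G = Z.t() * Z;

      for (int f = 0; f < P; ++f) {
        // training indices: all pseudo-trials except fold f of each class
        arma::uvec tr(n_tr);
        int c = 0;
        for (int p = 0; p < P; ++p) if (p != f) tr[c++] = p;
        for (int p = 0; p < P; ++p) if (p != f) tr[c++] = P + p;

        for (int a = 0; a < n_tr; ++a)
          for (int b2 = 0; b2 < n_tr; ++b2) Ksub(a, b2) = G(tr[a], tr[b2]);
        const double b = smo_solve(Ksub, ylab, C, alpha);

        double fA = b, fB = b;
        for (int a = 0; a < n_tr; ++a) {
          const double w = alpha[a] * ylab[a];
          fA += w * G(tr[a], f);
          fB += w * G(tr[a], P + f);
        }
        if (fA >= 0) acc[t] += 1.0; // ties broken toward the first class
        if (fB < 0) acc[t] += 1.0;
      }
    }
  }
  return acc * (100.0 / (2.0 * P * n_rep));
}

// Train-on-one-set / test-on-the-other decoding accuracy over time, with
// sub-averaging of both sets (cross-classification across factor levels or
// image identity).  Cubes: channels x trials x time; permutation matrices
// (trials x repetitions, 1-based) supply the sub-averaging assignments.
// [[Rcpp::export]]
arma::vec cpp_train_test(const arma::cube& trA, const arma::cube& trB,
                         const arma::cube& teA, const arma::cube& teB,
                         int k, double C,
                         const arma::imat& ptrA, const arma::imat& ptrB,
                         const arma::imat& pteA, const arma::imat& pteB) {
  const int T = trA.n_slices;
  const int n_rep = ptrA.n_cols;
  const int PtrA = trA.n_cols / k, PtrB = trB.n_cols / k;
  if (PtrA < 1 || PtrB < 1) stop("training set smaller than one sub-average group");
  // test sets smaller than k fall back to a single whole-set average
  const int kteA = std::min<int>(k, teA.n_cols), kteB = std::min<int>(k, teB.n_cols);
  const int PteA = teA.n_cols / kteA, PteB = teB.n_cols / kteB;
  const int n_tr = PtrA + PtrB, n_te = PteA + PteB;

  arma::ivec ylab(n_tr);
  for (int t = 0; t < n_tr; ++t) ylab[t] = (t < PtrA) ? 1 : -1;
  arma::vec acc(T, arma::fill::zeros);
  arma::vec alpha;

  for (int rep = 0; rep < n_rep; ++rep) {
    arma::uvec pTrA = perm_col(ptrA, rep), pTrB = perm_col(ptrB, rep);
    arma::uvec pTeA = perm_col(pteA, rep), pTeB = perm_col(pteB, rep);
    for (int t = 0; t < T; ++t) {
      arma::mat Ztr(trA.n_rows, n_tr);
      Ztr.cols(0, PtrA - 1) = pseudotrials(trA.slice(t), pTrA, k, PtrA);
      Ztr.cols(PtrA, n_tr - 1) = pseudotrials(trB.slice(t), pTrB, k, PtrB);
      arma::mat Zte(teA.n_rows, n_te);
      Zte.cols(0, PteA - 1) = pseudotrials(teA.slice(t), pTeA, kteA, PteA);
      Zte.cols(PteA, n_te - 1) = pseudotrials(teB.slice(t), pTeB, kteB, PteB);

      arma::mat G = Ztr.t() * Ztr;
      const double b = smo_solve(G, ylab, C, alpha);
      arma::vec coef = alpha % arma::conv_to<arma::vec>::from(ylab);
      arma::vec f = Zte.t() * (Ztr * coef) + b;

      double ok = 0.0;
      for (int a = 0; a < PteA; ++a) if (f[a] >= 0) ok += 1.0;
      for (int a = PteA; a < n_te; ++a) if (f[a] < 0) ok += 1.0;
      acc[t] += ok / n_te;
    }
  }
  return acc * (100.0 / n_rep);
}
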
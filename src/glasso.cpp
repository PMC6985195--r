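// Graphical lasso: L1-penalized Gaussian precision-matrix estimation by
// block coordinate descent (one lasso subproblem per column of the working
// covariance W). The diagonal is unpenalized. Supports warm starts in both
// W and the regression coefficient matrix B so a whole lambda path can be
// solved cheaply from lambda_max downwards.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Recover Theta from (W, B): theta_jj = 1/(w_jj - w12' b_j), theta_.j = -b_j theta_jj
static mat recover_theta(const mat& W, const mat& B) {
  const int p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double dot_wb = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) dot_wb += W(k, j) * B(k, j);
    double t22 = 1.0 / (W(j, j) - dot_wb);
    Theta(j, j) = t22;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * t22;
  }
  // symmetrize; keep exact zeros where both directions are zero
  mat Ts = 0.5 * (Theta + Theta.t());
  return Ts;
}

// Penalized log-likelihood:
// log det(Theta) - tr(S Theta) - sum_{i!=j} lam_ij |theta_ij|
static double glasso_objective(const mat& S, const mat& Theta,
                               const mat& Lam) {
  double ld, sign;
  bool ok = log_det(ld, sign, Theta);
  if (!ok || sign <= 0) return -datum::inf;
  mat P = Lam % abs(Theta);
  double pen = accu(P) - accu(P.diag());
  return ld - accu(S % Theta) - pen;
}

// `Lam` is the full matrix of per-edge penalties (diagonal ignored);
// the scalar-penalty case passes lam * (J - I).
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, const arma::mat& Lam, double tol,
                      int maxit,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W0,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B0,
                      bool trace_objective) {
  const int p = S.n_rows;
  mat W = W0.isNotNull() ? Rcpp::as<mat>(W0.get()) : mat(S);
  mat B = B0.isNotNull() ? Rcpp::as<mat>(B0.get()) : mat(p, p, fill::zeros);
  W.diag() = S.diag();

  // convergence threshold on the average absolute off-diagonal of S
  double s_off = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_off += std::abs(S(i, j));
  s_off /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(s_off, 1e-12);
  const double inner_thr = 0.1 * thr;

  std::vector<double> obj_trace;
  bool converged = false;
  int iter = 0;

  // scratch index vector per column
  uvec idx(p > 1 ? p - 1 : 1);

  for (iter = 0; iter < maxit && p > 1; ++iter) {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      int c = 0;
      for (int k = 0; k < p; ++k)
        if (k != j) idx(c++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      vec s12r = s12.elem(idx);
      vec b = B.col(j);
      vec br = b.elem(idx);
      vec lamr = Lam.col(j);
      lamr = lamr.elem(idx);

      for (int inner = 0; inner < 1000; ++inner) {
        double din = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double bk_old = br(k);
          double r = s12r(k) - dot(W11.col(k), br) + W11(k, k) * bk_old;
          double bk = soft_threshold(r, lamr(k)) / W11(k, k);
          br(k) = bk;
          double d = std::abs(bk - bk_old);
          if (d > din) din = d;
        }
        if (din < inner_thr) break;
      }

      vec w12 = W11 * br;
      for (int k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = br(k);
      }
      B(j, j) = 0.0;
    }
    if (trace_objective)
      obj_trace.push_back(glasso_objective(S, recover_theta(W, B), Lam));
    if (dmax < thr) {
      converged = true;
      ++iter;
      break;
    }
  }
  if (p == 1) converged = true;

  mat Theta = recover_theta(W, B);
  double obj = glasso_objective(S, Theta, Lam);

  return Rcpp::List::create(
    Rcpp::Named("Theta") = Theta,
    Rcpp::Named("W") = W,
    Rcpp::Named("B") = B,
    Rcpp::Named("objective") = obj,
    Rcpp::Named("objective_trace") = obj_trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}
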
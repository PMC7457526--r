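// Core GPGEE machinery: working-correlation moment estimators and the
// minorization-maximization Newton-Raphson path solver for the group-SCAD
// penalized estimating equations (Gaussian / identity link, A = I, phi = 1).
//
// Correlation kind codes (shared with R/correlation.R):
//   kind:  0 independence, 1 ar1, 2 cs, 3 unstructured, 4 kronecker
//   bcode (condition factor, kronecker only): 0 independence, 1 unstructured
//   scode (channel factor, kronecker only):   1 ar1, 2 cs, 3 unstructured
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EIG_FLOOR = 1e-6;   // eigenvalue floor in PD repair
static const double PD_TOL = 1e-10;     // smallest acceptable eigenvalue

static double clamp_val(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// derivative of the SCAD penalty, continuous closed form; equals lambda on
// [0, lambda], decays linearly, vanishes beyond a*lambda
static double scad_deriv_c(double theta, double lambda, double a) {
  if (lambda <= 0.0) return 0.0;
  if (theta <= lambda) return lambda;
  double num = a * lambda - theta;
  return num > 0.0 ? num / (a - 1.0) : 0.0;
}

static mat unit_diag_rescale(const mat& S) {
  vec d = sqrt(abs(S.diag()));
  d.transform([](double v) { return v > 0.0 ? v : 1.0; });
  mat R = S / (d * d.t());
  R = 0.5 * (R + R.t());
  R.diag().ones();
  return R;
}

// floor eigenvalues and rescale back to a correlation matrix
static mat pd_repair(const mat& Rin) {
  mat R = 0.5 * (Rin + Rin.t());
  vec eval;
  mat evec;
  eig_sym(eval, evec, R);
  if (eval.min() > PD_TOL) return R;
  eval.transform([](double v) { return v < EIG_FLOOR ? EIG_FLOOR : v; });
  return unit_diag_rescale(evec * diagmat(eval) * evec.t());
}

static mat ar1_mat(int m, double rho) {
  mat R(m, m);
  for (int s = 0; s < m; ++s)
    for (int t = 0; t < m; ++t) R(s, t) = std::pow(rho, std::abs(s - t));
  return R;
}

static mat cs_mat(int m, double rho) {
  mat R(m, m, fill::value(rho));
  R.diag().ones();
  return R;
}

// lag-1 moment estimate of the AR1 coefficient on residual matrix E (m x n,
// columns = subjects), pairs taken within consecutive segments of length L
// down each column; denominator pooled over all residuals
static double ar1_rho_est(const mat& E, int L) {
  int m = E.n_rows, n = E.n_cols, nseg = m / L;
  double num = 0.0;
  long npairs = 0;
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < nseg; ++s)
      for (int t = 0; t < L - 1; ++t) {
        num += E(s * L + t, i) * E(s * L + t + 1, i);
        ++npairs;
      }
  double den = accu(square(E)) / double(m * n);
  if (den <= 0.0 || npairs == 0) return 0.0;
  return clamp_val((num / double(npairs)) / den, -0.99, 0.99);
}

// exchangeable coefficient: all unordered within-segment pairs
static double cs_rho_est(const mat& E, int L) {
  int m = E.n_rows, n = E.n_cols, nseg = m / L;
  double num = 0.0;
  long npairs = 0;
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < nseg; ++s)
      for (int t = 0; t < L; ++t)
        for (int u = t + 1; u < L; ++u) {
          num += E(s * L + t, i) * E(s * L + u, i);
          ++npairs;
        }
  double den = accu(square(E)) / double(m * n);
  if (den <= 0.0 || npairs == 0) return 0.0;
  double lo = (L > 1) ? -1.0 / double(L - 1) + 1e-6 : 0.0;
  return clamp_val((num / double(npairs)) / den, lo, 0.99);
}

static mat estimate_R_c(const mat& E, int J, int K, int kind, int bcode,
                        int scode, mat* Bout = nullptr, mat* Sout = nullptr) {
  int m = E.n_rows;
  int n = E.n_cols;
  switch (kind) {
    case 0:
      return eye(m, m);
    case 1:
      return ar1_mat(m, ar1_rho_est(E, m));
    case 2:
      return cs_mat(m, cs_rho_est(E, m));
    case 3:
      return pd_repair(unit_diag_rescale(E * E.t() / double(n)));
    case 4: {
      mat Sg;
      if (scode == 1) {
        Sg = ar1_mat(K, ar1_rho_est(E, K));
      } else if (scode == 2) {
        Sg = cs_mat(K, cs_rho_est(E, K));
      } else {
        mat Sraw(K, K, fill::zeros);
        for (int j = 0; j < J; ++j) {
          mat Ej = E.rows(j * K, j * K + K - 1);
          Sraw += Ej * Ej.t();
        }
        Sg = pd_repair(unit_diag_rescale(Sraw / double(n * J)));
      }
      mat B;
      if (bcode == 0) {
        B = eye(J, J);
      } else {
        mat Braw(J, J, fill::zeros);
        for (int j = 0; j < J; ++j)
          for (int j2 = 0; j2 < J; ++j2) {
            mat Ej = E.rows(j * K, j * K + K - 1);
            mat Ej2 = E.rows(j2 * K, j2 * K + K - 1);
            Braw(j, j2) = accu(Ej % Ej2) / double(n * K);
          }
        B = pd_repair(unit_diag_rescale(Braw));
      }
      if (Bout) *Bout = B;
      if (Sout) *Sout = Sg;
      return kron(B, Sg);
    }
  }
  return eye(m, m);
}

// moment estimation of the working correlation from a residual matrix
// (m x n, condition-major rows, columns = subjects); returns R and, for the
// kronecker kind, the two factors
// [[Rcpp::export]]
Rcpp::List estimate_R_cpp(const arma::mat& E, int J, int K, int kind,
                          int bcode, int scode) {
  mat B, S;
  mat R = estimate_R_c(E, J, K, kind, bcode, scode, &B, &S);
  return Rcpp::List::create(Rcpp::Named("R") = R, Rcpp::Named("B") = B,
                            Rcpp::Named("Sigma") = S);
}

// MM Newton-Raphson path over a lambda grid.
//  X: stacked design (n*m x p), rows subject-major, condition-major within
//  gid: 1-based penalty-group id per column, 0 = unpenalized
// Every lambda starts from beta_init (the independence-GEE estimator); the
// working correlation is re-estimated from current residuals each iteration.
// [[Rcpp::export]]
Rcpp::List gpgee_path_cpp(const arma::mat& X, const arma::vec& Y, int n,
                          int J, int K, const arma::ivec& gid, int d,
                          int kind, int bcode, int scode,
                          const arma::vec& lambdas, double a, double eps,
                          double tol, int max_iter,
                          const arma::vec& beta_init, double ridge,
                          bool est_dispersion) {
  int m = J * K;
  int p = X.n_cols;
  int nl = lambdas.n_elem;

  // per-grid-row slices of the design across subjects: Xs[s] is n x p
  std::vector<mat> Xs(m);
  for (int s = 0; s < m; ++s) {
    mat Z(n, p);
    for (int i = 0; i < n; ++i) Z.row(i) = X.row(i * m + s);
    Xs[s] = Z;
  }
  // Cmat columns hold vec(sum_i x_is x_it^T) so that
  // vec(H) = Cmat * vec(W) with W = R^{-1}
  mat Cmat(p * p, m * m);
  for (int t = 0; t < m; ++t) {
    for (int s = 0; s <= t; ++s) {
      mat Cst = Xs[s].t() * Xs[t];
      Cmat.col(t * m + s) = vectorise(Cst);
      if (s != t) Cmat.col(s * m + t) = vectorise(Cst.t());
    }
  }

  mat Beta(p, nl, fill::zeros);
  Rcpp::IntegerVector iters(nl), conv(nl), ok(nl);

  for (int l = 0; l < nl; ++l) {
    double lambda = lambdas[l];
    vec beta = beta_init;
    bool failed = false, converged = false;
    int it = 0;
    while (it < max_iter) {
      ++it;
      vec resid = Y - X * beta;
      mat E = reshape(resid, m, n);
      mat W;
      if (kind == 0) {
        W = eye(m, m);
      } else {
        mat R = estimate_R_c(E, J, K, kind, bcode, scode);
        if (!inv_sympd(W, R)) {
          R = pd_repair(R);
          if (!inv_sympd(W, R)) { failed = true; break; }
        }
      }
      if (est_dispersion) {
        double phi = accu(square(E)) / double(m * n);
        if (phi > 0.0) W /= phi;
      }
      // score S = sum_i X_i' W r_i and hessian H = sum_i X_i' W X_i
      mat WE = W * E;
      vec Sc(p, fill::zeros);
      for (int s = 0; s < m; ++s) Sc += Xs[s].t() * WE.row(s).t();
      mat H = reshape(Cmat * vectorise(W), p, p);

      // MM penalty diagonal E_n
      vec gnorm(d + 1, fill::zeros);
      for (int jj = 0; jj < p; ++jj)
        if (gid[jj] > 0) gnorm[gid[jj]] += std::abs(beta[jj]);
      vec q(d + 1, fill::zeros);
      for (int g = 1; g <= d; ++g) q[g] = scad_deriv_c(gnorm[g], lambda, a);
      vec En(p, fill::zeros);
      for (int jj = 0; jj < p; ++jj)
        if (gid[jj] > 0) En[jj] = q[gid[jj]] / (eps + std::abs(beta[jj]));

      mat lhs = H;
      lhs.diag() += double(n) * En + ridge;
      vec rhs = Sc - double(n) * (En % beta);
      vec delta;
      if (!solve(delta, lhs, rhs, solve_opts::likely_sympd) ||
          !delta.is_finite()) {
        failed = true;
        break;
      }
      beta += delta;
      if (accu(abs(delta)) < tol) { converged = true; break; }
    }
    iters[l] = it;
    conv[l] = converged ? 1 : 0;
    ok[l] = failed ? 0 : 1;
    if (failed) beta.fill(datum::nan);
    Beta.col(l) = beta;
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = Beta, Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = conv, Rcpp::Named("ok") = ok);
}
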
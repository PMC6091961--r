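// Numerical hot paths: the FastICA fixed-point loop and zero-phase IIR
// filtering. Kept minimal; orchestration, seeding and validation live in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat sym_orth_cpp(const mat& W) {
  mat U, V;
  vec s;
  svd_econ(U, s, V, W);
  return U * V.t();
}

// Clamped Pade approximant of tanh (Lambert continued fraction, order 7/6):
// |error| < 2e-5 for |x| < 4.97, < 1.1e-4 at the clamp. The contrast enters
// FastICA only through its estimating function, so this perturbation is far
// below the statistical error of the fixed point.
static inline double fast_tanh(double x) {
  double ax = std::abs(x);
  if (ax >= 4.97) return x > 0 ? 1.0 : -1.0;
  double x2 = x * x;
  return x * (135135.0 + x2 * (17325.0 + x2 * (378.0 + x2))) /
         (135135.0 + x2 * (62370.0 + x2 * (3150.0 + x2 * 28.0)));
}

// Parallel FastICA on whitened data Z (d x N) from initial orthonormal W0.
// contrast: 0 = tanh, 1 = cube, 2 = gauss.
//
// The iteration can oscillate on noisy, overcomplete data instead of
// settling, so the rotation with the smallest update delta seen so far is
// tracked and returned. The loop stops when delta < tol (converged) or when
// the best delta has not improved by factor stall_factor for stall_iter
// consecutive iterations (stalled; further iterations were observed to
// wander, not improve).
// [[Rcpp::export(".fastica_core")]]
Rcpp::List fastica_core(const arma::mat& Z, const arma::mat& W0,
                        int max_iter, double tol, int contrast,
                        double alpha, int stall_iter, double stall_factor) {
  const double N = static_cast<double>(Z.n_cols);
  mat W = W0;
  mat W_best = W0;
  int n_iter = 0;
  bool converged = false;
  double delta = datum::inf;
  double best_delta = datum::inf;
  int since_improve = 0;
  for (int it = 1; it <= max_iter; ++it) {
    n_iter = it;
    mat U = W * Z;
    mat G;
    vec dg_mean;
    switch (contrast) {
    case 0: {
      G.set_size(U.n_rows, U.n_cols);
      const double* u = U.memptr();
      double* g = G.memptr();
      const uword n = U.n_elem;
      for (uword i = 0; i < n; ++i) g[i] = fast_tanh(alpha * u[i]);
      dg_mean = alpha * mean(1.0 - square(G), 1);
      break;
    }
    case 1:
      G = pow(U, 3);
      dg_mean = 3.0 * mean(square(U), 1);
      break;
    default: {
      mat E = exp(-square(U) / 2.0);
      G = U % E;
      dg_mean = mean((1.0 - square(U)) % E, 1);
    }
    }
    mat W1 = sym_orth_cpp(G * Z.t() / N - diagmat(dg_mean) * W);
    delta = abs(abs(sum(W1 % W, 1)) - 1.0).max();
    W = W1;
    if (delta < best_delta * stall_factor) {
      since_improve = 0;
    } else {
      ++since_improve;
    }
    if (delta < best_delta) { best_delta = delta; W_best = W; }
    if (delta < tol) { converged = true; break; }
    if (stall_iter > 0 && since_improve >= stall_iter) break;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W_best,
                            Rcpp::Named("n_iter") = n_iter,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("delta") = best_delta);
}

// Direct-form II transposed IIR filter with initial state zi (length n-1).
static vec lfilter(const vec& b, const vec& a, const vec& x, const vec& zi) {
  const uword n = b.n_elem;  // = a.n_elem, a(0) == 1
  vec z = zi;
  vec y(x.n_elem);
  for (uword m = 0; m < x.n_elem; ++m) {
    double xn = x(m);
    double yn = b(0) * xn + (n > 1 ? z(0) : 0.0);
    for (uword i = 1; i < n; ++i) {
      double znext = (i < n - 1) ? z(i) : 0.0;
      z(i - 1) = b(i) * xn + znext - a(i) * yn;
    }
    y(m) = yn;
  }
  return y;
}

// Steady-state initial conditions of the step response (scipy lfilter_zi).
static vec lfilter_zi(const vec& b, const vec& a) {
  const uword n = a.n_elem;
  if (n < 2) return vec();
  mat A = eye(n - 1, n - 1);
  // companion(a).T: first column -a(1..), superdiagonal ones
  for (uword i = 0; i < n - 1; ++i) A(i, 0) += a(i + 1);
  for (uword i = 0; i + 1 < n - 1; ++i) A(i, i + 1) -= 1.0;
  vec B = b.subvec(1, n - 1) - a.subvec(1, n - 1) * b(0);
  return solve(A, B);
}

// Zero-phase forward-backward filtering with odd-reflection edge padding and
// steady-state initial conditions (scipy.signal.filtfilt semantics).
// [[Rcpp::export(".filtfilt_core")]]
arma::vec filtfilt_core(const arma::vec& b_in, const arma::vec& a_in,
                        const arma::vec& x) {
  uword n = std::max(b_in.n_elem, a_in.n_elem);
  vec b = join_cols(b_in, zeros(n - b_in.n_elem)) / a_in(0);
  vec a = join_cols(a_in, zeros(n - a_in.n_elem)) / a_in(0);
  uword padlen = 3 * n;
  if (x.n_elem <= padlen)
    Rcpp::stop("signal too short for zero-phase filtering (need > %d samples)",
               padlen);
  // odd extension: 2*x0 - x[padlen..1], x, 2*xend - x[end-1..end-padlen]
  vec head = 2.0 * x(0) - reverse(x.subvec(1, padlen));
  vec tail = 2.0 * x(x.n_elem - 1) -
    reverse(x.subvec(x.n_elem - 1 - padlen, x.n_elem - 2));
  vec ext = join_cols(head, x, tail);
  vec zi = lfilter_zi(b, a);
  vec y = lfilter(b, a, ext, zi * ext(0));
  y = reverse(y);
  y = lfilter(b, a, y, zi * y(0));
  y = reverse(y);
  return y.subvec(padlen, padlen + x.n_elem - 1);
}

// Mean band powers of each row of S for a list of (b, a) filter pairs.
// [[Rcpp::export(".band_power_core")]]
arma::mat band_power_core(const arma::mat& S, const Rcpp::List& filters) {
  mat out(S.n_rows, filters.size());
  for (int f = 0; f < filters.size(); ++f) {
    Rcpp::List ba = filters[f];
    vec b = Rcpp::as<vec>(ba["b"]);
    vec a = Rcpp::as<vec>(ba["a"]);
    for (uword i = 0; i < S.n_rows; ++i) {
      vec y = filtfilt_core(b, a, S.row(i).t());
      out(i, f) = dot(y, y) / y.n_elem;
    }
  }
  return out;
}
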
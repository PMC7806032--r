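#include <Rcpp.h>
using namespace Rcpp;

// Discrete state-space recursion:
//   y(k) = C x(k) + D u(k);  x(k+1) = A x(k) + B u(k)
// u has one row per time step (N x m); returns N x p.
// Plain loops: n, m, p are small (<= ~10) while N is large, so this is the
// hot path for both the chain simulator and the B/D/x0 regressor columns.
// [[Rcpp::export]]
NumericMatrix ss_output_cpp(const NumericMatrix& A, const NumericMatrix& B,
                            const NumericMatrix& C, const NumericMatrix& D,
                            const NumericMatrix& u, const NumericVector& x0) {
  const int n = A.nrow();
  const int m = u.ncol();
  const int p = C.nrow();
  const int N = u.nrow();
  if (A.ncol() != n) stop("A must be square");
  if (B.nrow() != n || B.ncol() != m) stop("B has inconsistent dimensions");
  if (C.ncol() != n) stop("C has inconsistent dimensions");
  if (D.nrow() != p || D.ncol() != m) stop("D has inconsistent dimensions");
  if (x0.size() != n) stop("x0 length must equal the state dimension");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> xn(n);
  NumericMatrix y(N, p);

  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < p; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += C(i, j) * x[j];
      for (int j = 0; j < m; ++j) acc += D(i, j) * u(k, j);
      y(k, i) = acc;
    }
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += A(i, j) * x[j];
      for (int j = 0; j < m; ++j) acc += B(i, j) * u(k, j);
      xn[i] = acc;
    }
    x.swap(xn);
  }
  return y;
}
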
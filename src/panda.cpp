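// Message-passing core for aggregate network refinement.
//
// Conventions follow the reference message-passing implementation the field
// uses (netZoo): continuous Tanimoto similarity as the agreement kernel,
// population-SD z-scored inputs, and a diagonal refresh of the self-similarity
// updates of the TF-cooperativity and gene-coexpression channels. The strict
// mode scales the refreshed diagonal by dim * exp(2 * alpha * step); the
// simplified mode uses the off-diagonal row SD alone.
//
// The gene x gene coexpression update dominates runtime for realistic gene
// counts, so its Tanimoto transform, diagonal refresh and learning-rate blend
// are fused into single passes over the matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// T(i,j) = a_ij / sqrt(||X_i||^2 + ||Y_j||^2 - |a_ij|), a = X Y.
// Zero denominators (both vectors zero) give 0 by convention.
static mat tfun(const mat& X, const mat& Y) {
  mat a = X * Y;
  colvec rx = sum(square(X), 1);
  rowvec cy = sum(square(Y), 0);
  for (uword j = 0; j < a.n_cols; ++j) {
    double* col = a.colptr(j);
    const double c = cy(j);
    for (uword i = 0; i < a.n_rows; ++i) {
      const double v = col[i];
      const double den = std::sqrt(rx(i) + c - std::fabs(v));
      col[i] = (den > 0.0) ? v / den : 0.0;
    }
  }
  return a;
}

// Symmetric self-similarity update, fused:
// M <- (1-alpha) * M + alpha * T(W'W) with the diagonal of T(W'W) replaced
// by the off-diagonal row SD (population), scaled in strict mode by
// num * exp(2 * alpha * step). `G = X' X` with column norms `s` must be
// passed in; G is overwritten.
static void blend_self_similarity(mat& M, mat& G, const vec& s,
                                  double num, double alpha, int step,
                                  bool strict) {
  const uword n = G.n_rows;
  vec rs(n, fill::zeros), rss(n, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    double* col = G.colptr(j);
    const double sj = s(j);
    for (uword i = 0; i < n; ++i) {
      const double v = col[i];
      const double den = std::sqrt(s(i) + sj - std::fabs(v));
      const double t = (den > 0.0) ? v / den : 0.0;
      col[i] = t;
      if (i != j) { rs(i) += t; rss(i) += t * t; }
    }
  }
  const double cnt = static_cast<double>(n - 1);
  const double scale = strict ? num * std::exp(2.0 * alpha * step) : 1.0;
  for (uword i = 0; i < n; ++i) {
    const double mu = rs(i) / cnt;
    double va = rss(i) / cnt - mu * mu;
    if (va < 0.0) va = 0.0;
    G(i, i) = std::sqrt(va) * scale;
  }
  M *= (1.0 - alpha);
  M += alpha * G;
}

// [[Rcpp::export]]
Rcpp::List panda_core(arma::mat W, arma::mat P, arma::mat C,
                      double alpha, double tol, int maxit, bool strict) {
  const double nt = static_cast<double>(W.n_rows);
  const double ng = static_cast<double>(W.n_cols);
  std::vector<double> trace;
  trace.reserve(static_cast<size_t>(maxit));
  bool converged = false;
  int iters = 0;

  for (int step = 0; step < maxit; ++step) {
    mat R = tfun(P, W);       // responsibility: TF-cooperativity agreement
    mat A = tfun(W, C);       // availability: gene-coregulation agreement
    mat target = 0.5 * (R + A);
    const double delta = alpha * mean(mean(abs(target - W)));
    W = (1.0 - alpha) * W + alpha * target;
    if (!W.is_finite())
      Rcpp::stop("non-finite network weights at iteration %d", step + 1);
    trace.push_back(delta);
    iters = step + 1;
    if (delta < tol) {
      converged = true;
      break;
    }
    vec rw = sum(square(W), 1);   // TF row norms
    rowvec cw = sum(square(W), 0);  // gene column norms
    mat Gt = W * W.t();           // TF x TF
    blend_self_similarity(P, Gt, rw, ng, alpha, step, strict);
    mat Gc = W.t() * W;           // gene x gene
    blend_self_similarity(C, Gc, cw.t(), nt, alpha, step, strict);
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = W,
    Rcpp::Named("iterations_run") = iters,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("delta_trace") = trace);
}
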
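#include <Rcpp.h>
using namespace Rcpp;

// Column-broadcast affine transform: out[i,j] = M[i,j] * mult[j] + add[j].
// [[Rcpp::export]]
NumericMatrix col_affine_cpp(NumericMatrix M, NumericVector mult,
                             NumericVector add) {
  const int n = M.nrow(), c = M.ncol();
  NumericMatrix out(n, c);
  const double *m = REAL(M);
  double *o = REAL(out);
  for (int j = 0; j < c; ++j) {
    const double a = mult[j], b = add[j];
    const double *cm = m + (std::size_t)n * j;
    double *co = o + (std::size_t)n * j;
    for (int i = 0; i < n; ++i) co[i] = cm[i] * a + b;
  }
  return out;
}

// ReLU with pre-activation kept by the caller for the backward pass.
// [[Rcpp::export]]
NumericMatrix relu_fwd_cpp(NumericMatrix Z) {
  const int n = Z.nrow(), c = Z.ncol();
  NumericMatrix out(n, c);
  const double *z = REAL(Z);
  double *o = REAL(out);
  const std::size_t len = (std::size_t)n * c;
  for (std::size_t i = 0; i < len; ++i) o[i] = z[i] > 0 ? z[i] : 0;
  return out;
}

// dH * (Z > 0), the ReLU backward step.
// [[Rcpp::export]]
NumericMatrix relu_bwd_cpp(NumericMatrix dH, NumericMatrix Z) {
  const int n = dH.nrow(), c = dH.ncol();
  NumericMatrix out(n, c);
  const double *d = REAL(dH), *z = REAL(Z);
  double *o = REAL(out);
  const std::size_t len = (std::size_t)n * c;
  for (std::size_t i = 0; i < len; ++i) o[i] = z[i] > 0 ? d[i] : 0;
  return out;
}

// Max over blocks of ns consecutive rows. Returns pooled (n/ns x c) and the
// 1-based within-block argmax used by the backward pass.
// [[Rcpp::export]]
List max_pool_groups_cpp(NumericMatrix X, int ns) {
  const int n = X.nrow(), c = X.ncol();
  if (n % ns != 0) stop("row count not divisible by group size");
  const int ng = n / ns;
  NumericMatrix pooled(ng, c);
  IntegerMatrix arg(ng, c);
  const double *x = REAL(X);
  double *p = REAL(pooled);
  int *a = INTEGER(arg);
  for (int j = 0; j < c; ++j) {
    const double *cx = x + (std::size_t)n * j;
    double *cp = p + (std::size_t)ng * j;
    int *ca = a + (std::size_t)ng * j;
    for (int g = 0; g < ng; ++g) {
      const double *blk = cx + (std::size_t)g * ns;
      double best = blk[0];
      int bi = 0;
      for (int s = 1; s < ns; ++s)
        if (blk[s] > best) { best = blk[s]; bi = s; }
      cp[g] = best;
      ca[g] = bi + 1;
    }
  }
  return List::create(_["out"] = pooled, _["arg"] = arg);
}

// Scatter pooled gradients back to the argmax rows.
// [[Rcpp::export]]
NumericMatrix max_pool_bwd_cpp(NumericMatrix dP, IntegerMatrix arg, int ns) {
  const int ng = dP.nrow(), c = dP.ncol();
  NumericMatrix dX(ng * ns, c);
  const double *dp = REAL(dP);
  const int *a = INTEGER(arg);
  double *dx = REAL(dX);
  for (int j = 0; j < c; ++j) {
    const double *cdp = dp + (std::size_t)ng * j;
    const int *ca = a + (std::size_t)ng * j;
    double *cdx = dx + (std::size_t)ng * ns * j;
    for (int g = 0; g < ng; ++g)
      cdx[(std::size_t)g * ns + ca[g] - 1] = cdp[g];
  }
  return dX;
}

// Accumulate rows of dF into an n x c zero matrix at 1-based target rows:
// out[idx[r], ] += dF[r, ] (the grouping-gather transpose).
// [[Rcpp::export]]
NumericMatrix scatter_add_rows_cpp(NumericMatrix dF, IntegerVector idx,
                                   int n) {
  const int r = dF.nrow(), c = dF.ncol();
  if (idx.size() != r) stop("index length mismatch");
  NumericMatrix out(n, c);
  const double *df = REAL(dF);
  double *o = REAL(out);
  const int *ix = INTEGER(idx);
  for (int j = 0; j < c; ++j) {
    const double *cf = df + (std::size_t)r * j;
    double *co = o + (std::size_t)n * j;
    for (int i = 0; i < r; ++i) co[ix[i] - 1] += cf[i];
  }
  return out;
}

// Gather rows: out[r, ] = M[idx[r], ] (1-based idx).
// [[Rcpp::export]]
NumericMatrix gather_rows_cpp(NumericMatrix M, IntegerVector idx) {
  const int n = M.nrow(), c = M.ncol(), r = idx.size();
  NumericMatrix out(r, c);
  const double *m = REAL(M);
  double *o = REAL(out);
  const int *ix = INTEGER(idx);
  for (int j = 0; j < c; ++j) {
    const double *cm = m + (std::size_t)n * j;
    double *co = o + (std::size_t)r * j;
    for (int i = 0; i < r; ++i) co[i] = cm[ix[i] - 1];
  }
  return out;
}

// Fused train-mode batch-norm + ReLU forward: computes per-column batch
// mean/var, out = relu(gamma * (Z - mu) * invstd + beta). Returns out, mu,
// var, invstd; backward recomputes xhat from the cached Z.
// [[Rcpp::export]]
List bn_relu_fwd_train_cpp(NumericMatrix Z, NumericVector gamma,
                           NumericVector beta, double eps) {
  const int n = Z.nrow(), c = Z.ncol();
  NumericMatrix out(n, c);
  NumericVector mu(c), var(c), invstd(c);
  const double *z = REAL(Z);
  double *o = REAL(out);
  for (int j = 0; j < c; ++j) {
    const double *cz = z + (std::size_t)n * j;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += cz[i]; s2 += cz[i] * cz[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    const double a = 1.0 / std::sqrt(v + eps);
    mu[j] = m; var[j] = v; invstd[j] = a;
    const double g = gamma[j] * a, b = beta[j] - gamma[j] * a * m;
    double *co = o + (std::size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double y = cz[i] * g + b;
      co[i] = y > 0 ? y : 0;
    }
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// Fused eval-mode batch-norm + ReLU forward using running statistics.
// [[Rcpp::export]]
NumericMatrix bn_relu_fwd_eval_cpp(NumericMatrix Z, NumericVector gamma,
                                   NumericVector beta,
                                   NumericVector runMean,
                                   NumericVector runVar, double eps) {
  const int n = Z.nrow(), c = Z.ncol();
  NumericMatrix out(n, c);
  const double *z = REAL(Z);
  double *o = REAL(out);
  for (int j = 0; j < c; ++j) {
    const double a = 1.0 / std::sqrt(runVar[j] + eps);
    const double g = gamma[j] * a, b = beta[j] - gamma[j] * a * runMean[j];
    const double *cz = z + (std::size_t)n * j;
    double *co = o + (std::size_t)n * j;
    for (int i = 0; i < n; ++i) {
      const double y = cz[i] * g + b;
      co[i] = y > 0 ? y : 0;
    }
  }
  return out;
}

// Fused backward through ReLU and train-mode batch norm. dY is the
// gradient at the ReLU output; Z the cached pre-normalization activations.
// Returns dZ, dgamma, dbeta (the affine bias before BN has exactly zero
// gradient and is handled by the caller).
// [[Rcpp::export]]
List bn_relu_bwd_cpp(NumericMatrix dY, NumericMatrix Z, NumericVector mu,
                     NumericVector invstd, NumericVector gamma,
                     NumericVector beta) {
  const int n = dY.nrow(), c = dY.ncol();
  NumericMatrix dZ(n, c);
  NumericVector dgamma(c), dbeta(c);
  const double *dy = REAL(dY), *z = REAL(Z);
  double *dz = REAL(dZ);
  for (int j = 0; j < c; ++j) {
    const double m = mu[j], a = invstd[j], g = gamma[j], be = beta[j];
    const double *cdy = dy + (std::size_t)n * j;
    const double *cz = z + (std::size_t)n * j;
    double *cdz = dz + (std::size_t)n * j;
    double s0 = 0, s1 = 0;
    for (int i = 0; i < n; ++i) {
      const double xh = (cz[i] - m) * a;
      if (xh * g + be > 0) {
        const double dh = cdy[i];
        s0 += dh;
        s1 += dh * xh;
      }
    }
    dgamma[j] = s1;
    dbeta[j] = s0;
    const double c0 = s0 / n, c1 = s1 / n, ag = a * g;
    for (int i = 0; i < n; ++i) {
      const double xh = (cz[i] - m) * a;
      const double dh = (xh * g + be > 0) ? cdy[i] : 0.0;
      cdz[i] = ag * (dh - c0 - xh * c1);
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
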
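# Internal neural-network primitives: shared-weight (pointwise) affine
# layers, batch normalization, ReLU, inverted dropout, group max pooling and
# AdamW. Forward functions return caches that the matching backward
# functions consume; gradients are validated against finite differences in
# the test suite.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# column-wise affine broadcast: M * mult[col] + add[col]; compiled kernel
colAffine <- function(M, mult, add) col_affine_cpp(M, mult, add)

colAdd <- function(M, add) col_affine_cpp(M, rep(1, length(add)), add)

linearForward <- function(X, W, b) {
  colAdd(X %*% W, b)
}

linearBackward <- function(dZ, X, W) {
  list(dX = dZ %*% t(W), dW = crossprod(X, dZ), db = colSums(dZ))
}

# One linear -> batchnorm -> relu block, fused in compiled code. The affine
# bias is not added: with batch normalization immediately after the linear
# map it cancels exactly in Z - mean(Z) (train mode) and is never part of
# the running statistics (eval mode), so the counted bias parameter has
# exactly zero gradient and never moves from its zero initialization.
bnReluForward <- function(Z, params, bnStats, keyFn, training) {
  if (training) {
    bn <- bn_relu_fwd_train_cpp(Z, params[[keyFn("gamma")]],
                                params[[keyFn("beta")]], BN_EPS)
    bnStats[[keyFn("mean")]] <- (1 - BN_MOMENTUM) *
      bnStats[[keyFn("mean")]] + BN_MOMENTUM * bn$mu
    bnStats[[keyFn("var")]] <- (1 - BN_MOMENTUM) *
      bnStats[[keyFn("var")]] + BN_MOMENTUM * bn$var
    list(out = bn$out, mu = bn$mu, invstd = bn$invstd, bnStats = bnStats)
  } else {
    out <- bn_relu_fwd_eval_cpp(Z, params[[keyFn("gamma")]],
                                params[[keyFn("beta")]],
                                bnStats[[keyFn("mean")]],
                                bnStats[[keyFn("var")]], BN_EPS)
    list(out = out, mu = NULL, invstd = NULL, bnStats = bnStats)
  }
}

dropoutForward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  keep <- matrix(runif(length(X)) >= p, nrow(X), ncol(X))
  list(out = X * keep / (1 - p), mask = keep, p = p)
}

# Max over blocks of `ns` consecutive rows (one block per local region).
# Returns the pooled matrix and the within-block argmax for backprop.
maxPoolGroups <- function(X, ns) max_pool_groups_cpp(X, as.integer(ns))

maxPoolBackward <- function(dP, arg, ns) {
  max_pool_bwd_cpp(dP, arg, as.integer(ns))
}

# One pointwise MLP chain: (linear -> batchnorm -> relu) per layer.
# prefix names the flat parameter entries, e.g. "sa1.l2.W".
mlpForward <- function(X, params, bnStats, prefix, nLayers, training) {
  caches <- vector("list", nLayers)
  H <- X
  for (j in seq_len(nLayers)) {
    key <- function(s) sprintf("%s.l%d.%s", prefix, j, s)
    Z <- H %*% params[[key("W")]]
    bn <- bnReluForward(Z, params, bnStats, key, training)
    bnStats <- bn$bnStats
    caches[[j]] <- list(X = H, Z = Z, mu = bn$mu, invstd = bn$invstd)
    H <- bn$out
  }
  list(out = H, caches = caches, bnStats = bnStats)
}

mlpBackward <- function(dH, params, caches, prefix) {
  grads <- list()
  for (j in rev(seq_along(caches))) {
    key <- function(s) sprintf("%s.l%d.%s", prefix, j, s)
    cc <- caches[[j]]
    bb <- bn_relu_bwd_cpp(dH, cc$Z, cc$mu, cc$invstd,
                          params[[key("gamma")]], params[[key("beta")]])
    grads[[key("gamma")]] <- as.numeric(bb$dgamma)
    grads[[key("beta")]] <- as.numeric(bb$dbeta)
    grads[[key("W")]] <- crossprod(cc$X, bb$dZ)
    grads[[key("b")]] <- numeric(length(params[[key("b")]]))
    dH <- bb$dZ %*% t(params[[key("W")]])
  }
  list(dX = dH, grads = grads)
}

logSoftmax <- function(Z) {
  mx <- do.call(pmax, c(as.data.frame(Z), list(na.rm = FALSE)))
  Zs <- Z - mx
  Zs - log(rowSums(exp(Zs)))
}

adamwInit <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Decoupled weight decay applied to weight matrices only (".W" entries);
# biases and normalization affine parameters are not decayed.
adamwStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (endsWith(nm, ".W")) weightDecay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (upd + decay)
  }
  list(params = params, state = state)
}
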
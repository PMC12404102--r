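#' Construct set-abstraction, head and network configurations
#'
#' \code{SAConfig(NA, NA, NA, widths)} denotes a group-all level.
#' \code{RPNetConfig()} defaults to the reference architecture: three set-
#' abstraction levels (512 centers, radius 0.15, 32-point cap, MLP widths
#' 64/64/128; 256 centers, radius 0.3, 64-point cap, 128/128/256; group-all
#' with 256/512/1024) and a 1024-512-256-3 fully connected head with
#' dropout 0.3/0.4 and a log-softmax output. The first MLP of level 1
#' consumes the raw channels (local xyz, plus RI when
#' \code{inputChannels = 4}); deeper levels consume the previous pooled
#' width plus 3 local coordinates (131 and 259).
#'
#' @param nCenter,radius,nSample,mlpWidths see \linkS4class{SAConfig}.
#' @return the corresponding configuration object.
#' @export
SAConfig <- function(nCenter, radius, nSample, mlpWidths) {
  new("SAConfig", nCenter = as.integer(nCenter), radius = as.numeric(radius),
      nSample = as.integer(nSample), mlpWidths = as.integer(mlpWidths))
}

#' @param dims,dropout see \linkS4class{HeadConfig}.
#' @rdname SAConfig
#' @export
HeadConfig <- function(dims = c(1024L, 512L, 256L, 3L),
                       dropout = c(0.3, 0.4)) {
  new("HeadConfig", dims = as.integer(dims), dropout = as.numeric(dropout))
}

#' @param inputChannels 3 (x,y,z) or 4 (x,y,z,n).
#' @param saLevels list of \code{SAConfig}; defaults to the reference
#'   three-level profile.
#' @param head a \code{HeadConfig}.
#' @param nClasses output classes (default 3).
#' @rdname SAConfig
#' @examples
#' cfg <- RPNetConfig()
#' countParameters(cfg)   # 1470243 -> 1.47 M
#' @export
RPNetConfig <- function(inputChannels = 4L,
                        saLevels = list(
                          SAConfig(512L, 0.15, 32L, c(64L, 64L, 128L)),
                          SAConfig(256L, 0.30, 64L, c(128L, 128L, 256L)),
                          SAConfig(NA, NA, NA, c(256L, 512L, 1024L))),
                        head = HeadConfig(),
                        nClasses = 3L) {
  new("RPNetConfig", inputChannels = as.integer(inputChannels),
      saLevels = saLevels, head = head, nClasses = as.integer(nClasses))
}

#' Desk-scale network profile
#'
#' A reduced instance of the same architecture for 256-point inputs on a
#' single CPU: levels (64 centers, r 0.2, cap 16, widths 32/32/64),
#' (16 centers, r 0.4, cap 16, widths 64/64/128), group-all 128/128/256,
#' and a 256-128-64-3 head with light dropout (0.1/0.1; the smaller
#' network trained for fewer steps needs less regularization than the
#' full profile's 0.3/0.4). Used by the ablation harness and examples;
#' the scientific structure (FPS centers, ball query, pointwise MLP + max
#' pooling, log-softmax head) is identical to the full profile.
#'
#' @param inputChannels 3 or 4.
#' @return an \linkS4class{RPNetConfig}.
#' @export
smallRPNetConfig <- function(inputChannels = 4L) {
  RPNetConfig(inputChannels = inputChannels,
              saLevels = list(
                SAConfig(64L, 0.20, 16L, c(32L, 32L, 64L)),
                SAConfig(16L, 0.40, 16L, c(64L, 64L, 128L)),
                SAConfig(NA, NA, NA, c(128L, 128L, 256L))),
              head = HeadConfig(c(256L, 128L, 64L, 3L), c(0.1, 0.1)))
}

# internal: per-layer input/output widths implied by a config
layerPlan <- function(config) {
  plan <- list(sa = list())
  cin <- config@inputChannels
  for (l in seq_along(config@saLevels)) {
    widths <- config@saLevels[[l]]@mlpWidths
    plan$sa[[l]] <- list(cin = c(cin, widths[-length(widths)]),
                         cout = widths)
    cin <- tail(widths, 1L) + 3L
  }
  dims <- config@head@dims
  plan$head <- list(cin = dims[-length(dims)], cout = dims[-1],
                    bn = c(rep(TRUE, length(dims) - 2L), FALSE))
  plan
}

#' Closed-form trainable parameter count
#'
#' Counts every trainable scalar of the architecture analytically: each
#' affine layer contributes \code{cin * cout} weights plus \code{cout}
#' biases, and each batch-normalized layer adds \code{2 * cout} affine
#' normalization scalars (every pointwise layer and head layers 1 to n-1
#' are normalized; the final layer is not). The default 4-channel network
#' has 1,470,243 parameters (1.47 M).
#'
#' @param config an \linkS4class{RPNetConfig}.
#' @return integer parameter count.
#' @seealso [modelParameterCount()] for enumeration of a built model.
#' @export
countParameters <- function(config) {
  validObject(config)
  plan <- layerPlan(config)
  total <- 0
  for (lv in plan$sa)
    total <- total + sum(lv$cin * lv$cout + lv$cout + 2L * lv$cout)
  total <- total + sum(plan$head$cin * plan$head$cout + plan$head$cout +
                       ifelse(plan$head$bn, 2L * plan$head$cout, 0L))
  as.integer(total)
}

#' Enumerate trainable scalars of a built model
#'
#' @param model an \linkS4class{RPNetModel}.
#' @return integer count of scalars over all weight arrays.
#' @export
modelParameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

#' Analytic forward-pass FLOP count
#'
#' Multiply-accumulate count of one forward pass, one MAC counted as one
#' FLOP (the profiler convention adopted here; the original counter is
#' undeclared). Each pointwise layer over \code{G} grouped points with
#' widths \code{cin -> cout} contributes \code{G * cin * cout} MACs, where
#' \code{G = nCenter * nSample} per ball-query level and the level's point
#' count for a group-all level; head layers contribute \code{cin * cout}.
#' Elementwise work (bias, normalization, rectifier, pooling) is excluded
#' from the headline figure and reported separately via
#' \code{detail = TRUE}. The default network at a 1024 x 4 input counts
#' 1,470,956,288 MACs (1.47 G).
#'
#' @param config an \linkS4class{RPNetConfig}.
#' @param nPoints input point count (default 1024).
#' @param detail if \code{TRUE}, return a breakdown list.
#' @return numeric MAC count, or a list with components \code{mac},
#'   \code{bias}, \code{bn}, \code{relu} and \code{pool}.
#' @export
countFlops <- function(config, nPoints = 1024L, detail = FALSE) {
  validObject(config)
  plan <- layerPlan(config)
  n <- as.integer(nPoints)
  mac <- bias <- bn <- relu <- pool <- 0
  for (l in seq_along(config@saLevels)) {
    sa <- config@saLevels[[l]]
    if (is.na(sa@nCenter)) {
      G <- n
      nOut <- 1L
    } else {
      if (sa@nCenter > n)
        stop("nCenter exceeds the points available at level ", l)
      G <- sa@nCenter * sa@nSample
      nOut <- sa@nCenter
    }
    lv <- plan$sa[[l]]
    mac <- mac + G * sum(as.numeric(lv$cin) * lv$cout)
    bias <- bias + G * sum(lv$cout)
    bn <- bn + 4 * G * sum(lv$cout)
    relu <- relu + G * sum(lv$cout)
    pool <- pool + G * tail(lv$cout, 1L)
    n <- nOut
  }
  hc <- as.numeric(plan$head$cin)
  mac <- mac + sum(hc * plan$head$cout)
  bias <- bias + sum(plan$head$cout)
  bn <- bn + 4 * sum(plan$head$cout[plan$head$bn])
  relu <- relu + sum(plan$head$cout[plan$head$bn])
  if (detail)
    list(mac = mac, bias = bias, bn = bn, relu = relu, pool = pool)
  else mac
}

#' Build an RPNet model
#'
#' Initializes all weights (He initialization for weight matrices, zero
#' biases, unit/zero normalization affine parameters) and zeroed running
#' normalization statistics.
#'
#' @param config an \linkS4class{RPNetConfig}.
#' @param seed integer seed for the initialization draw, or \code{NA} to
#'   use the ambient RNG stream.
#' @param riStandardize \code{c(center, scale)} or
#'   \code{c(center, scale, clip)}; the RI channel enters the network as
#'   \code{(n - center) / scale}, optionally saturated at \code{± clip}.
#'   The default (1.33, 0.07) spans the physical cell RI range; the
#'   desk-scale harness uses the band-centered (1.35, 0.01, 1) instead
#'   (see [runAblation()]).
#' @return an \linkS4class{RPNetModel}.
#' @export
buildRPNet <- function(config = RPNetConfig(), seed = NA_integer_,
                       riStandardize = c(1.33, 0.07)) {
  validObject(config)
  plan <- layerPlan(config)
  params <- list()
  bnStats <- list()
  withSeed(seed, {
    initBlock <- function(prefix, cin, cout, bn) {
      key <- function(s) sprintf("%s.%s", prefix, s)
      params[[key("W")]] <<- matrix(rnorm(cin * cout, 0, sqrt(2 / cin)),
                                    cin, cout)
      params[[key("b")]] <<- numeric(cout)
      if (bn) {
        params[[key("gamma")]] <<- rep(1, cout)
        params[[key("beta")]] <<- numeric(cout)
        bnStats[[key("mean")]] <<- numeric(cout)
        bnStats[[key("var")]] <<- rep(1, cout)
      }
    }
    for (l in seq_along(plan$sa)) {
      lv <- plan$sa[[l]]
      for (j in seq_along(lv$cout))
        initBlock(sprintf("sa%d.l%d", l, j), lv$cin[j], lv$cout[j], TRUE)
    }
    for (j in seq_along(plan$head$cout))
      initBlock(sprintf("head.l%d", j), plan$head$cin[j],
                plan$head$cout[j], plan$head$bn[j])
  })
  new("RPNetModel", config = config, params = params, bnStats = bnStats,
      riStandardize = as.numeric(riStandardize))
}

# internal: stack a list of equal-size point sets into batch matrices.
# Rows are sample-major: sample b occupies rows (b-1)*K + 1 .. b*K.
assembleBatch <- function(sets) {
  K <- nPoints(sets[[1]])
  for (s in sets)
    if (nPoints(s) != K)
      stop("input-shape error: all point sets in a batch must share K")
  pos <- do.call(rbind, lapply(sets, coords))
  ri <- unlist(lapply(sets, riValues), use.names = FALSE)
  list(pos = pos, ri = ri, K = K, B = length(sets))
}

# internal: full batched forward pass. Returns log-probabilities and, when
# withCache, everything backward needs. Consumes RNG only for dropout in
# training mode. Center selection uses deterministic FPS (farthest from the
# centroid, lexicographic tie-break) in both modes, so eval-mode output is
# a pure function of the input point multiset.
rpnetForwardCore <- function(model, batch, training = FALSE,
                             withCache = FALSE) {
  config <- model@config
  params <- model@params
  bnStats <- model@bnStats
  B <- batch$B
  n <- batch$K
  if (n < config@saLevels[[1]]@nCenter && !is.na(config@saLevels[[1]]@nCenter))
    stop("input-shape error: fewer points than level-1 centers")
  posMat <- batch$pos
  feats <- if (config@inputChannels == 4L) {
    f <- (batch$ri - model@riStandardize[1]) / model@riStandardize[2]
    if (length(model@riStandardize) >= 3L) {
      clip <- model@riStandardize[3]
      f <- pmin(pmax(f, -clip), clip)
    }
    matrix(f, ncol = 1L)
  } else matrix(numeric(0), nrow = nrow(posMat), ncol = 0L)

  levelCaches <- vector("list", length(config@saLevels))
  for (l in seq_along(config@saLevels)) {
    sa <- config@saLevels[[l]]
    groupAll <- is.na(sa@nCenter)
    nc <- if (groupAll) 1L else sa@nCenter
    ns <- if (groupAll) n else sa@nSample
    centersMat <- matrix(0, B * nc, 3L)
    globIdx <- integer(B * nc * ns)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * n + seq_len(n)
      P <- posMat[rows, , drop = FALSE]
      if (groupAll) {
        centersMat[b, ] <- colMeans(P)
        g <- seq_len(n)
      } else {
        ctrIdx <- fps_cpp(P, nc, deterministicStart(P))
        centersMat[(b - 1L) * nc + seq_len(nc), ] <-
          P[ctrIdx, , drop = FALSE]
        grp <- ball_query_cpp(P[ctrIdx, , drop = FALSE], P, sa@radius, ns)
        g <- as.vector(t(grp))
      }
      globIdx[(b - 1L) * nc * ns + seq_len(nc * ns)] <- (b - 1L) * n + g
    }
    centersRep <- gather_rows_cpp(centersMat,
                                  rep(seq_len(B * nc), each = ns))
    localXYZ <- gather_rows_cpp(posMat, globIdx) - centersRep
    X <- if (ncol(feats) > 0L)
      cbind(localXYZ, gather_rows_cpp(feats, globIdx))
    else localXYZ
    mf <- mlpForward(X, params, bnStats, sprintf("sa%d", l),
                     length(sa@mlpWidths), training)
    bnStats <- mf$bnStats
    mp <- maxPoolGroups(mf$out, ns)
    if (withCache)
      levelCaches[[l]] <- list(globIdx = globIdx, ns = ns, nc = nc,
                               mlp = mf$caches, poolArg = mp$arg,
                               prevRows = nrow(posMat),
                               prevC = ncol(feats))
    posMat <- centersMat
    feats <- mp$out
    n <- nc
  }

  # classifier head on the (B x featureWidth) global descriptor
  H <- feats
  headCaches <- list()
  hp <- layerPlan(config)$head
  for (j in seq_along(hp$cout)) {
    key <- function(s) sprintf("head.l%d.%s", j, s)
    if (hp$bn[j]) {
      Z <- H %*% params[[key("W")]]
      bn <- bnReluForward(Z, params, bnStats, key, training)
      bnStats <- bn$bnStats
      dp <- dropoutForward(bn$out, config@head@dropout[j], training)
      headCaches[[j]] <- list(X = H, Z = Z, mu = bn$mu,
                              invstd = bn$invstd, drop = dp$mask,
                              p = config@head@dropout[j])
      H <- dp$out
    } else {
      headCaches[[j]] <- list(X = H)
      H <- linearForward(H, params[[key("W")]], params[[key("b")]])
    }
  }
  logp <- logSoftmax(H)
  out <- list(logp = logp, bnStats = bnStats)
  if (withCache) {
    out$levelCaches <- levelCaches
    out$headCaches <- headCaches
  }
  out
}

# internal: backward pass from d(loss)/d(logits). Returns flat gradients.
rpnetBackwardCore <- function(model, fwd, dLogits) {
  config <- model@config
  params <- model@params
  hp <- layerPlan(config)$head
  dH <- dLogits
  grads <- list()
  for (j in rev(seq_along(hp$cout))) {
    key <- function(s) sprintf("head.l%d.%s", j, s)
    cc <- fwd$headCaches[[j]]
    if (hp$bn[j]) {
      if (!is.null(cc$drop)) dH <- dH * cc$drop / (1 - cc$p)
      bb <- bn_relu_bwd_cpp(dH, cc$Z, cc$mu, cc$invstd,
                            params[[key("gamma")]],
                            params[[key("beta")]])
      grads[[key("gamma")]] <- as.numeric(bb$dgamma)
      grads[[key("beta")]] <- as.numeric(bb$dbeta)
      grads[[key("W")]] <- crossprod(cc$X, bb$dZ)
      grads[[key("b")]] <- numeric(length(params[[key("b")]]))
      dH <- bb$dZ %*% t(params[[key("W")]])
    } else {
      lb <- linearBackward(dH, cc$X, params[[key("W")]])
      grads[[key("W")]] <- lb$dW
      grads[[key("b")]] <- lb$db
      dH <- lb$dX
    }
  }

  dFeats <- dH
  for (l in rev(seq_along(config@saLevels))) {
    lc <- fwd$levelCaches[[l]]
    dGath <- maxPoolBackward(dFeats, lc$poolArg, lc$ns)
    mb <- mlpBackward(dGath, params, lc$mlp, sprintf("sa%d", l))
    grads <- c(grads, mb$grads)
    if (l > 1L) {
      dFg <- mb$dX[, -(1:3), drop = FALSE]
      dFeats <- scatter_add_rows_cpp(dFg, lc$globIdx, lc$prevRows)
    }
  }
  grads
}

#' Forward pass of an RPNet model
#'
#' Computes class log-probabilities for one training point set (or a list
#' of equally sized sets). In \code{"eval"} mode dropout is off, running
#' normalization statistics are used and the output is a pure function of
#' the input point multiset: permuting the points changes nothing beyond
#' floating-point round-off, because center selection is deterministic and
#' max pooling is symmetric. Exponentials of each output row sum to 1.
#'
#' @param model an \linkS4class{RPNetModel}.
#' @param set a \linkS4class{TrainingPointSet} / \linkS4class{RIPointCloud}
#'   or a list of them.
#' @param mode \code{"eval"} or \code{"train"} (batch statistics, dropout).
#' @return numeric matrix (sets x classes) of log-probabilities; a single
#'   input returns a named numeric vector.
#' @export
rpnetForward <- function(model, set, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  single <- !is.list(set)
  sets <- if (single) list(set) else set
  batch <- assembleBatch(sets)
  fwd <- rpnetForwardCore(model, batch, training = mode == "train")
  logp <- fwd$logp
  colnames(logp) <- paste0("class", seq_len(model@config@nClasses) - 1L)
  if (single) logp[1L, ] else logp
}
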
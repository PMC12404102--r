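#' Construct a TrainConfig
#'
#' Defaults follow the reference protocol: AdamW (decoupled weight decay)
#' with initial learning rate 0.001 and weight decay 0.0001, 200 epochs,
#' batch size 16, cosine annealing of the learning rate to zero without
#' restarts, label smoothing alpha = 0.1, and three augmentations (random
#' z-rotation, clipped Gaussian coordinate jitter, Gaussian RI noise) each
#' applied independently with probability 0.5. Jitter magnitudes follow
#' common point-cloud practice (sigma 0.01 clipped at 0.05 in unit-sphere
#' coordinates; RI noise sigma 0.002) and are configurable.
#'
#' @param lr initial learning rate.
#' @param weightDecay decoupled weight decay.
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param labelSmoothing smoothing factor alpha in [0, 1).
#' @param augmentProb per-transform probability.
#' @param jitterSigma,jitterClip clipped Gaussian jitter parameters.
#' @param riNoiseSigma Gaussian RI-channel noise.
#' @param kfold folds for optional cross-validation tuning.
#' @param seed integer seed.
#' @return a \linkS4class{TrainConfig}.
#' @export
TrainConfig <- function(lr = 0.001, weightDecay = 0.0001, epochs = 200L,
                        batchSize = 16L, labelSmoothing = 0.1,
                        augmentProb = 0.5, jitterSigma = 0.01,
                        jitterClip = 0.05, riNoiseSigma = 0.002,
                        kfold = 5L, seed = 1L) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      labelSmoothing = labelSmoothing, augmentProb = augmentProb,
      jitterSigma = jitterSigma, jitterClip = jitterClip,
      riNoiseSigma = riNoiseSigma, kfold = as.integer(kfold),
      seed = as.integer(seed))
}

#' Stratified train/test split
#'
#' Per class, \code{floor(ratio * n_c)} samples go to the training set and
#' the remainder to the test set; splitting counts (123, 179, 154) at
#' ratio 0.8 therefore yields 364 training and 92 test samples.
#'
#' @param labels integer class labels.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed or \code{NA}.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @examples
#' sp <- stratifiedSplit(rep(0:2, c(123, 179, 154)), 0.8, seed = 1)
#' lengths(sp)   # 364 / 92
#' @export
stratifiedSplit <- function(labels, ratio = 0.8, seed = NA_integer_) {
  if (!length(labels)) stop("invalid labels: empty")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  classes <- sort(unique(labels))
  if (any(table(labels) < 1L)) stop("invalid labels: empty class")
  withSeed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(labels == cl)
      nTrain <- floor(ratio * length(idx))
      train <- c(train, idx[sample.int(length(idx), nTrain)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified k-fold indices
#'
#' Helper for configuration tuning by cross-validation; final metrics are
#' reported on the single fixed split.
#'
#' @param labels integer class labels.
#' @param k number of folds.
#' @param seed integer seed or \code{NA}.
#' @return list of \code{k} disjoint, exhaustive index vectors with
#'   near-balanced class composition.
#' @export
kfoldIndices <- function(labels, k = 5L, seed = NA_integer_) {
  k <- as.integer(k)
  withSeed(seed, {
    folds <- vector("list", k)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fid <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[fid == f])
    }
    lapply(folds, sort)
  })
}

#' Label-smoothed cross-entropy
#'
#' \code{loss = -sum_c q_c log p_c} with
#' \code{q = (1 - alpha) onehot(label) + alpha / nClasses}. With uniform
#' predictions the loss is \code{log(nClasses)} for every label and alpha.
#'
#' @param logprobs numeric vector (or matrix, one row per sample) of class
#'   log-probabilities.
#' @param label integer class index in \code{0:(nClasses-1)} (vector for a
#'   matrix input).
#' @param alpha smoothing factor.
#' @return mean loss (scalar).
#' @examples
#' smoothedCrossEntropy(log(c(1, 1, 1) / 3), 0L, 0.1)  # log(3)
#' @export
smoothedCrossEntropy <- function(logprobs, label, alpha = 0.1) {
  if (is.null(dim(logprobs))) logprobs <- matrix(logprobs, nrow = 1L)
  nc <- ncol(logprobs)
  q <- matrix(alpha / nc, nrow(logprobs), nc)
  q[cbind(seq_len(nrow(logprobs)), as.integer(label) + 1L)] <-
    1 - alpha + alpha / nc
  mean(-rowSums(q * logprobs))
}

# internal: smoothing targets + gradient wrt logits for a batch
smoothedCeGrad <- function(logp, label, alpha) {
  nB <- nrow(logp); nc <- ncol(logp)
  q <- matrix(alpha / nc, nB, nc)
  q[cbind(seq_len(nB), as.integer(label) + 1L)] <- 1 - alpha + alpha / nc
  loss <- mean(-rowSums(q * logp))
  dLogp <- -q / nB
  dLogits <- dLogp - exp(logp) * rowSums(dLogp)
  list(loss = loss, dLogits = dLogits)
}

#' Point-set augmentation
#'
#' Independently with probability \code{augmentProb} each: rotate the
#' coordinates by a uniform angle about the z axis; jitter each coordinate
#' with clipped Gaussian noise; add Gaussian noise to the RI channel.
#' Geometric transforms never touch the RI channel. \code{apply} overrides
#' the three coin flips (rotation, jitter, RI noise) for deterministic
#' testing.
#'
#' @param set a \linkS4class{TrainingPointSet} (normalized coordinates).
#' @param config a \linkS4class{TrainConfig}.
#' @param seed integer seed or \code{NA}.
#' @param apply optional logical(3) forcing which transforms run.
#' @return the augmented point set.
#' @export
augmentPointSet <- function(set, config = TrainConfig(),
                            seed = NA_integer_, apply = NULL) {
  withSeed(seed, {
    doIt <- if (is.null(apply)) runif(3) < config@augmentProb
            else as.logical(apply)
    xyz <- set@coords
    ri <- set@ri
    if (doIt[1]) {
      a <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      xyz <- xyz %*% rot
    }
    if (doIt[2] && config@jitterSigma > 0) {
      j <- matrix(rnorm(length(xyz), 0, config@jitterSigma), nrow(xyz), 3)
      j <- pmin(pmax(j, -config@jitterClip), config@jitterClip)
      xyz <- xyz + j
    }
    if (doIt[3] && config@riNoiseSigma > 0)
      ri <- ri + rnorm(length(ri), 0, config@riNoiseSigma)
    initialize(set, coords = xyz, ri = ri)
  })
}

#' Train an RPNet model
#'
#' Runs the full optimization loop on a list of labeled, unit-sphere
#' normalized RI point clouds: every epoch draws a fresh stochastic
#' training point set per cloud through the hybrid selector (resampling as
#' augmentation), applies the point-set augmentations, and optimizes with
#' AdamW under cosine annealing
#' (\code{lr_e = lr (1 + cos(pi e / E)) / 2}) and label-smoothed
#' cross-entropy. Fully reproducible given \code{config@seed}.
#'
#' @param clouds list of labeled \linkS4class{RIPointCloud} (the training
#'   split), each normalized and holding at least \code{ripcsConfig@nFps}
#'   points.
#' @param modelConfig an \linkS4class{RPNetConfig}.
#' @param config a \linkS4class{TrainConfig}.
#' @param ripcsConfig an \linkS4class{RIPCSConfig} describing the per-epoch
#'   point selection (its seed should be \code{NA} so draws differ across
#'   epochs within the seeded training stream).
#' @param riStandardize passed to [buildRPNet()].
#' @return list with \code{model} (fitted \linkS4class{RPNetModel}) and
#'   \code{history} (data.frame epoch / lr / loss).
#' @export
trainRPNet <- function(clouds, modelConfig = smallRPNetConfig(),
                       config = TrainConfig(),
                       ripcsConfig = RIPCSConfig(k = 256L, nFps = 200L,
                                                 nRiies = 56L),
                       riStandardize = c(1.33, 0.07)) {
  labels <- vapply(clouds, cellLabel, integer(1))
  if (any(is.na(labels)) || length(unique(labels)) < 2L)
    stop("invalid dataset: need labeled clouds from >= 2 classes")
  E <- config@epochs
  nS <- length(clouds)
  withSeed(config@seed, {
    model <- buildRPNet(modelConfig, riStandardize = riStandardize)
    state <- adamwInit(model@params)
    history <- data.frame(epoch = seq_len(E), lr = NA_real_,
                          loss = NA_real_)
    for (e in seq_len(E)) {
      lrE <- config@lr * (1 + cos(pi * e / E)) / 2
      ord <- sample.int(nS)
      sets <- lapply(clouds[ord], function(cl)
        augmentPointSet(ripcsSelect(cl, ripcsConfig), config))
      labE <- labels[ord]
      losses <- numeric(0)
      for (bStart in seq(1L, nS, by = config@batchSize)) {
        bIdx <- bStart:min(bStart + config@batchSize - 1L, nS)
        batch <- assembleBatch(sets[bIdx])
        fwd <- rpnetForwardCore(model, batch, training = TRUE,
                                withCache = TRUE)
        model@bnStats <- fwd$bnStats
        ce <- smoothedCeGrad(fwd$logp, labE[bIdx], config@labelSmoothing)
        grads <- rpnetBackwardCore(model, fwd, ce$dLogits)
        st <- adamwStep(model@params, grads, state, lrE,
                        config@weightDecay)
        model@params <- st$params
        state <- st$state
        losses <- c(losses, ce$loss)
      }
      history$lr[e] <- lrE
      history$loss[e] <- mean(losses)
    }
    list(model = model, history = history)
  })
}

#' Evaluate a model on labeled clouds
#'
#' Predictions use eval mode (dropout off, running normalization
#' statistics) and the deterministic selector variant: deterministic FPS
#' start plus a fixed per-sample selection seed, so repeated evaluation is
#' bit-reproducible. With \code{nDraws > 1} class probabilities are
#' averaged over that many fixed-seed selector draws per cloud (still
#' fully deterministic; smooths selection variance). Returns accuracy,
#' macro recall/precision/F1, the one-vs-rest AUC per class (a class
#' absent from the test set yields \code{NA}, excluded from the mean with
#' a warning) and the confusion matrix.
#'
#' @param model an \linkS4class{RPNetModel}.
#' @param clouds list of labeled normalized \linkS4class{RIPointCloud}.
#' @param ripcsConfig selector parameters (k, nFps, nRiies, interval).
#' @param seed base seed for the per-sample deterministic selection.
#' @param batchSize forward batch size.
#' @param nDraws selector draws averaged per cloud (default 1).
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateModel <- function(model, clouds,
                          ripcsConfig = RIPCSConfig(k = 256L, nFps = 200L,
                                                    nRiies = 56L),
                          seed = 0L, batchSize = 16L, nDraws = 1L) {
  if (!length(clouds)) stop("empty test set")
  labels <- vapply(clouds, cellLabel, integer(1))
  nc <- model@config@nClasses
  probs <- matrix(0, length(clouds), nc)
  logp <- NULL
  for (d in seq_len(nDraws)) {
    sets <- lapply(seq_along(clouds), function(i) {
      cfg <- initialize(ripcsConfig, fpsStart = "deterministic",
                        seed = as.integer(seed + i + (d - 1L) * 10007L))
      ripcsSelect(clouds[[i]], cfg)
    })
    logp <- matrix(NA_real_, length(sets), nc)
    for (bStart in seq(1L, length(sets), by = batchSize)) {
      bIdx <- bStart:min(bStart + batchSize - 1L, length(sets))
      batch <- assembleBatch(sets[bIdx])
      logp[bIdx, ] <- rpnetForwardCore(model, batch,
                                       training = FALSE)$logp
    }
    probs <- probs + exp(logp) / nDraws
  }
  logp <- log(probs)
  pred <- max.col(logp, ties.method = "first") - 1L
  conf <- confusionMatrix(labels, pred, nc)
  auc <- oneVsRestAuc(labels, probs)
  rep_ <- metricsFromConfusion(conf)
  initialize(rep_, auc = auc,
             meanAuc = mean(auc, na.rm = TRUE))
}

#' Confusion matrix and metrics from predictions
#'
#' \code{confusionMatrix} tabulates truth (rows) against predictions
#' (columns) over classes \code{0:(nClasses-1)}.
#' \code{metricsFromConfusion} derives accuracy (trace over total) and
#' macro-averaged recall, precision and F1 (per-class F1 = 2PR/(P+R),
#' taken as 0 when P + R = 0).
#'
#' @param truth,pred integer class vectors.
#' @param nClasses number of classes.
#' @return \code{confusionMatrix}: integer matrix;
#'   \code{metricsFromConfusion}: a \linkS4class{MetricsReport} (AUC slots
#'   unset).
#' @examples
#' cm <- matrix(c(5, 1, 0, 0, 4, 0, 0, 0, 5), 3, 3)
#' metricsFromConfusion(cm)@accuracy   # 14/15
#' @export
confusionMatrix <- function(truth, pred, nClasses = 3L) {
  lev <- seq_len(nClasses) - 1L
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  m <- matrix(as.integer(conf), nClasses, nClasses,
              dimnames = list(truth = lev, pred = lev))
  m
}

#' @param conf square confusion matrix, rows = truth.
#' @rdname confusionMatrix
#' @export
metricsFromConfusion <- function(conf) {
  conf <- as.matrix(conf)
  total <- sum(conf)
  tp <- diag(conf)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  new("MetricsReport",
      accuracy = sum(tp) / total,
      recall = mean(rec, na.rm = TRUE),
      precision = mean(prec, na.rm = TRUE),
      f1 = mean(f1, na.rm = TRUE),
      perClassRecall = as.numeric(rec),
      perClassPrecision = as.numeric(prec),
      perClassF1 = as.numeric(f1),
      auc = rep(NA_real_, nrow(conf)), meanAuc = NA_real_,
      confusion = conf)
}

# internal: per-class one-vs-rest AUC from probability scores
oneVsRestAuc <- function(truth, probs) {
  nc <- ncol(probs)
  auc <- rep(NA_real_, nc)
  for (cl in seq_len(nc) - 1L) {
    resp <- as.integer(truth == cl)
    if (length(unique(resp)) < 2L) {
      warning(sprintf(
        "class %d absent from the test set; AUC undefined, excluded", cl))
      next
    }
    auc[cl + 1L] <- as.numeric(pROC::auc(pROC::roc(
      response = resp, predictor = probs[, cl + 1L],
      levels = c(0L, 1L), direction = "<", quiet = TRUE)))
  }
  auc
}
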
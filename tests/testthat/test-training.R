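test_that("stratified split reproduces the per-class floor rule", {
  labels <- rep(0:2, c(123, 179, 154))
  sp <- stratifiedSplit(labels, 0.8, seed = 1L)
  expect_length(sp$train, 364L)
  expect_length(sp$test, 92L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
  # per-class training counts are exactly floor(0.8 * n_c)
  expect_equal(as.integer(table(labels[sp$train])), c(98L, 143L, 123L))

  sp2 <- stratifiedSplit(rep(0:2, c(4, 3, 3)), 0.8, seed = 2L)
  expect_length(sp2$train, 7L)
  expect_length(sp2$test, 3L)

  expect_identical(stratifiedSplit(labels, 0.8, seed = 9L),
                   stratifiedSplit(labels, 0.8, seed = 9L))
  expect_error(stratifiedSplit(integer(0)), "invalid labels")
  expect_error(stratifiedSplit(labels, 1.2), "ratio")
})

test_that("k-fold indices are disjoint, exhaustive and stratified", {
  labels <- rep(0:2, c(20, 30, 25))
  folds <- kfoldIndices(labels, 5L, seed = 3L)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), seq_along(labels))
  expect_equal(sum(lengths(folds)), length(labels))
  perFold <- sapply(folds, function(f) as.integer(table(
    factor(labels[f], levels = 0:2))))
  expect_lte(max(perFold) - min(perFold), 2L)
})

test_that("label-smoothed cross-entropy matches hand evaluation", {
  expect_equal(smoothedCrossEntropy(log(rep(1 / 3, 3)), 0L, 0.1), log(3),
               tolerance = 1e-10)
  expect_equal(smoothedCrossEntropy(log(rep(1 / 3, 3)), 2L, 0.7), log(3),
               tolerance = 1e-10)
  # alpha = 0 reduces to the negative log-likelihood of the true class
  lp <- log(c(0.5, 0.3, 0.2))
  expect_equal(smoothedCrossEntropy(lp, 1L, 0), -log(0.3))
  # probs (0.7, 0.2, 0.1), label 0, alpha 0.1: hand-evaluated 0.46330
  lp2 <- log(c(0.7, 0.2, 0.1))
  hand <- -((1 - 0.1 + 0.1 / 3) * log(0.7) +
            (0.1 / 3) * (log(0.2) + log(0.1)))
  expect_equal(smoothedCrossEntropy(lp2, 0L, 0.1), hand)
  expect_equal(hand, 0.4633, tolerance = 1e-4)
})

test_that("augmentation transforms behave as declared", {
  set <- randomSet(64L, seed = 4L)
  cfg <- TrainConfig(jitterSigma = 0, riNoiseSigma = 0)
  # rotation only: an isometry that leaves RI untouched
  rot <- augmentPointSet(set, cfg, seed = 1L, apply = c(TRUE, FALSE, FALSE))
  d0 <- dist(coords(set))
  expect_equal(as.vector(dist(coords(rot))), as.vector(d0),
               tolerance = 1e-6)
  expect_identical(riValues(rot), riValues(set))
  # z-rotation preserves the z column exactly
  expect_equal(coords(rot)[, 3], coords(set)[, 3])

  # all transforms disabled -> identity
  none <- augmentPointSet(set, cfg, seed = 2L,
                          apply = c(FALSE, FALSE, FALSE))
  expect_identical(coords(none), coords(set))
  expect_identical(riValues(none), riValues(set))

  # jitter is clipped; RI noise touches only the RI channel
  cfg2 <- TrainConfig(jitterSigma = 0.01, jitterClip = 0.05,
                      riNoiseSigma = 0.002)
  jit <- augmentPointSet(set, cfg2, seed = 3L, apply = c(FALSE, TRUE, TRUE))
  expect_lte(max(abs(coords(jit) - coords(set))), 0.05)
  expect_false(identical(riValues(jit), riValues(set)))

  # seed determinism
  a <- augmentPointSet(set, TrainConfig(), seed = 7L)
  b <- augmentPointSet(set, TrainConfig(), seed = 7L)
  expect_identical(coords(a), coords(b))
  expect_identical(riValues(a), riValues(b))
})

test_that("metrics match hand arithmetic and brute force", {
  cm <- matrix(c(5, 1, 0, 0, 4, 0, 0, 0, 5), 3, 3)
  rep_ <- metricsFromConfusion(cm)
  expect_equal(rep_@accuracy, 14 / 15)
  expect_equal(rep_@perClassRecall[2], 0.8)

  # random confusion matrices against brute-force metric identities
  withr::with_seed(13, {
    for (trial in 1:20) {
      cm <- matrix(rpois(9, 5), 3, 3)
      if (any(rowSums(cm) == 0)) cm <- cm + 1
      r <- metricsFromConfusion(cm)
      expect_equal(r@accuracy, sum(diag(cm)) / sum(cm))
      prec <- diag(cm) / colSums(cm)
      rec <- diag(cm) / rowSums(cm)
      f1 <- ifelse(is.finite(prec) & prec + rec > 0,
                   2 * prec * rec / (prec + rec), 0)
      expect_equal(r@f1, mean(f1))
      expect_equal(r@recall, mean(rec))
    }
  })

  # confusionMatrix tabulates truth in rows
  cm2 <- confusionMatrix(c(0, 0, 1, 2), c(0, 1, 1, 2), 3L)
  expect_equal(unname(cm2[1, ]), c(1L, 1L, 0L))
  expect_equal(sum(cm2), 4L)
})

test_that("one-vs-rest AUC handles perfect and absent classes", {
  probs <- matrix(c(0.8, 0.1, 0.1,
                    0.1, 0.8, 0.1,
                    0.2, 0.1, 0.7,
                    0.7, 0.2, 0.1), 4, 3, byrow = TRUE)
  auc <- RIPointNet:::oneVsRestAuc(c(0L, 1L, 2L, 0L), probs)
  expect_equal(auc, c(1, 1, 1))
  expect_warning(
    auc2 <- RIPointNet:::oneVsRestAuc(c(0L, 1L, 0L, 1L), probs),
    "absent")
  expect_true(is.na(auc2[3]))
})

test_that("training descends, follows the cosine schedule and reproduces", {
  spec <- PhantomSpec(gridShape = c(32L, 32L, 24L),
                      classParams = riOnlyClassParams(),
                      noiseSigma = 0)
  vols <- generateDataset(spec, c(4, 4, 4), seed = 31L)
  clouds <- lapply(vols, function(v)
    normalizeUnitSphere(segmentedEquilibriumSample(voxelToPoints(v),
      SamplerConfig(m = 512L, seed = 1L))))
  mc <- tinyConfig()
  tc <- TrainConfig(epochs = 8L, batchSize = 4L, seed = 5L)
  rc <- RIPCSConfig(k = 64L, nFps = 50L, nRiies = 14L)
  fit <- trainRPNet(clouds, modelConfig = mc, config = tc,
                    ripcsConfig = rc)
  E <- 8
  expect_equal(fit$history$lr,
               0.001 * (1 + cos(pi * seq_len(E) / E)) / 2,
               tolerance = 1e-8)
  expect_equal(fit$history$lr[E / 2], 0.001 / 2)
  expect_equal(fit$history$lr[E], 0)
  expect_lt(fit$history$loss[E], log(3))

  fit2 <- trainRPNet(clouds, modelConfig = mc, config = tc,
                     ripcsConfig = rc)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$model@params, fit2$model@params)

  rep_ <- suppressWarnings(
    evaluateModel(fit$model, clouds, ripcsConfig = rc, seed = 0L))
  expect_s4_class(rep_, "MetricsReport")
  expect_equal(sum(rep_@confusion), length(clouds))
  expect_equal(rowSums(rep_@confusion),
               as.numeric(table(vapply(clouds, cellLabel, integer(1)))),
               ignore_attr = TRUE)
  # repeated deterministic evaluation is identical
  rep2 <- suppressWarnings(
    evaluateModel(fit$model, clouds, ripcsConfig = rc, seed = 0L))
  expect_identical(rep_@confusion, rep2@confusion)

  expect_error(trainRPNet(clouds[1:4], modelConfig = mc, config = tc,
                          ripcsConfig = rc), "2 classes")
})

test_that("selector-stochasticity robustness reports mean and sd", {
  spec <- PhantomSpec(gridShape = c(32L, 32L, 24L), noiseSigma = 0)
  vols <- generateDataset(spec, c(2, 2, 2), seed = 41L)
  clouds <- lapply(vols, function(v)
    normalizeUnitSphere(segmentedEquilibriumSample(voxelToPoints(v),
      SamplerConfig(m = 512L, seed = 1L))))
  model <- buildRPNet(tinyConfig(), seed = 2L)
  rob <- ripcsRobustness(model, clouds,
                         RIPCSConfig(k = 64L, nFps = 50L, nRiies = 14L),
                         nRuns = 3L, seed = 1L)
  expect_length(rob$accuracies, 3L)
  expect_gte(rob$mean, 0)
  expect_lte(rob$mean, 1)
})
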
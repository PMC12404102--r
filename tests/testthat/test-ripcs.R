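test_that("FPS follows the greedy max-min rule on a hand-worked example", {
  # collinear points at x = 0,1,2,3,10: from x=0, the farthest point is
  # x=10, then x=3 (min-distance 3 beats 2 and 1)
  cl <- RIPointCloud(cbind(c(0, 1, 2, 3, 10), 0, 0), rep(1.34, 5))
  expect_identical(farthestPointSample(cl, 3L, start = 1L), c(1L, 5L, 4L))
  expect_identical(farthestPointSample(cl, 1L, start = 2L), 2L)
  expect_error(farthestPointSample(cl, 6L), "insufficient")
})

test_that("FPS matches an independent brute-force oracle", {
  withr::with_seed(7, {
    for (trial in 1:25) {
      n <- sample(20:200, 1)
      cl <- toyCloud(n, seed = trial)
      k <- sample(2:min(n, 50), 1)
      start <- sample(n, 1)
      expect_identical(farthestPointSample(cl, k, start = start),
                       bruteFps(coords(cl), k, start))
    }
  })
})

test_that("FPS is deterministic, RI-blind and covers well", {
  cl <- normalizeUnitSphere(randomSample(smallCloud(), 3000L, seed = 1L))
  idx <- farthestPointSample(cl, 100L, start = "deterministic")
  expect_length(unique(idx), 100L)
  expect_identical(idx, farthestPointSample(cl, 100L,
                                            start = "deterministic"))
  # permuting the RI channel cannot change a coordinate-only selection
  shuf <- RIPointCloud(coords(cl), sample(riValues(cl)),
                       normalized = TRUE)
  expect_identical(farthestPointSample(shuf, 100L,
                                       start = "deterministic"), idx)
  # random start is seed-deterministic
  expect_identical(farthestPointSample(cl, 50L, seed = 3L),
                   farthestPointSample(cl, 50L, seed = 3L))

  # covering radius beats the mean of 50 random subsets of equal size
  covFps <- coveringRadius(cl, idx)
  covRnd <- vapply(1:50, function(s)
    coveringRadius(cl, withr::with_seed(s, sample(nPoints(cl), 100L))),
    numeric(1))
  expect_lt(covFps, mean(covRnd))
})

test_that("riiesSample draws inside the band and replicates on deficit", {
  # exactly k band points: each taken once
  cl <- toyCloud(100, ri = c(rep(1.35, 20), rep(1.40, 80)), seed = 2L)
  idx <- riiesSample(cl, 20L, seed = 1L)
  expect_setequal(idx, 1:20)

  # 50 band points, k=224: 224 = 4*50 + 24, so 24 points appear 5 times
  # and 26 appear 4 times
  cl2 <- toyCloud(10000,
                  ri = c(rep(1.35, 50), rep(1.40, 9950)), seed = 3L)
  idx2 <- riiesSample(cl2, 224L, seed = 9L)
  expect_length(idx2, 224L)
  expect_true(all(riValues(cl2)[idx2] >= 1.345 &
                  riValues(cl2)[idx2] <= 1.355))
  mult <- table(idx2)
  expect_equal(sort(unique(as.integer(mult))), c(4L, 5L))
  expect_equal(sum(mult == 5L), 24L)
  expect_equal(sum(mult == 4L), 26L)

  # empty band errors with a diagnostic carrying the cloud's RI range
  cl3 <- toyCloud(10, ri = rep(1.335, 10), seed = 4L)
  expect_error(riiesSample(cl3, 5L), "empty RI interval.*1.335")
})

test_that("riies picks on the phantom stay in the nucleolar band", {
  cl <- normalizeUnitSphere(smallCloud())
  idx <- riiesSample(cl, 224L, seed = 1L)
  expect_length(idx, 224L)
  expect_true(all(riValues(cl)[idx] >= 1.345 & riValues(cl)[idx] <= 1.355))
})

test_that("ripcsSelect composes FPS and RIIES into exactly K points", {
  cl <- normalizeUnitSphere(randomSample(smallCloud(), 3000L, seed = 2L))
  set <- ripcsSelect(cl, RIPCSConfig(k = 512L, nFps = 400L, nRiies = 112L,
                                     seed = 5L))
  expect_s4_class(set, "TrainingPointSet")
  expect_equal(nPoints(set), 512L)
  expect_equal(sum(provenance(set) == "fps"), 400L)
  expect_equal(sum(provenance(set) == "riies"), 112L)
  ri <- riValues(set)[provenance(set) == "riies"]
  expect_true(all(ri >= 1.345 & ri <= 1.355))
  expect_identical(cellLabel(set), cellLabel(cl))

  # degenerate configs: pure FPS and pure RIIES
  fpsOnly <- ripcsSelect(cl, RIPCSConfig(k = 128L, nFps = 128L,
                                         nRiies = 0L, seed = 1L))
  expect_true(all(provenance(fpsOnly) == "fps"))
  riOnly <- ripcsSelect(cl, RIPCSConfig(k = 128L, nFps = 0L,
                                        nRiies = 128L, seed = 1L))
  expect_true(all(provenance(riOnly) == "riies"))

  # invariant: nFps + nRiies must equal k
  expect_error(RIPCSConfig(k = 100L, nFps = 90L, nRiies = 20L), "equal")
})

test_that("ripcsSelect is stochastic across seeds, reproducible within", {
  cl <- normalizeUnitSphere(randomSample(smallCloud(), 2000L, seed = 3L))
  a <- ripcsSelect(cl, RIPCSConfig(k = 256L, nFps = 200L, nRiies = 56L,
                                   seed = 1L))
  b <- ripcsSelect(cl, RIPCSConfig(k = 256L, nFps = 200L, nRiies = 56L,
                                   seed = 1L))
  c <- ripcsSelect(cl, RIPCSConfig(k = 256L, nFps = 200L, nRiies = 56L,
                                   seed = 2L))
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(c)))
  # conservation: every selected point exists in the source
  key <- function(x) paste(coords(x)[, 1], coords(x)[, 2], coords(x)[, 3])
  expect_true(all(key(a) %in% key(cl)))
})
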
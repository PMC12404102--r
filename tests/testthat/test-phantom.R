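test_that("noise-free phantoms have exact background and banded foreground", {
  vol <- smallPhantom()
  mask <- foregroundMask(vol)
  ri <- riGrid(vol)
  expect_true(all(ri[!mask] == 1.330))
  expect_true(all(ri[mask] >= 1.335 & ri[mask] <= 1.380))
  expect_gt(sum(mask), 0)
})

test_that("phantom generation is bit-deterministic given (spec, label, seed)", {
  spec <- smallSpec(noiseSigma = 0.001)
  v1 <- generatePhantom(spec, 2L, seed = 11L)
  v2 <- generatePhantom(spec, 2L, seed = 11L)
  expect_identical(riGrid(v1), riGrid(v2))
  expect_identical(foregroundMask(v1), foregroundMask(v2))
  v3 <- generatePhantom(spec, 2L, seed = 12L)
  expect_false(identical(riGrid(v1), riGrid(v3)))
})

test_that("default desk-scale phantom matches the per-cell voxel budget", {
  # acquisition-scale cells span 5e5..4e6 voxels on a 320x320x210 grid;
  # the default grid holds 1/8 the voxels, so the scaled budget is
  # 6.25e4..5e5 foreground voxels
  n <- sum(foregroundMask(deskPhantom()))
  expect_gte(n, 6.25e4)
  expect_lte(n, 5e5)
})

test_that("default phantom RI histogram is heavily skewed to low RI", {
  h <- intervalHistogram(deskCloud(), 6)
  expect_gte(h[1], 1e3 * max(h[6], 1))
})

test_that("mean nucleolar RI is monotone across classes", {
  spec <- smallSpec()
  bandMean <- vapply(0:2, function(lab) {
    v <- generatePhantom(spec, lab, seed = 21L + lab)
    ri <- riGrid(v)[foregroundMask(v)]
    mean(ri[ri >= 1.345 & ri <= 1.355])
  }, numeric(1))
  expect_true(all(diff(bandMean) < 0))
})

test_that("phantom foreground is a single connected component", {
  # flood fill from one foreground voxel must reach every mask voxel
  mask <- foregroundMask(smallPhantom())
  d <- dim(mask)
  visited <- array(FALSE, d)
  start <- which(mask)[1]
  queue <- start
  visited[start] <- TRUE
  off <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  while (length(queue)) {
    nb <- unique(as.vector(outer(queue, off, "+")))
    nb <- nb[nb >= 1 & nb <= length(mask)]
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    queue <- nb
  }
  expect_equal(sum(visited), sum(mask))
})

test_that("generateDataset yields the requested class counts and order", {
  spec <- PhantomSpec(gridShape = c(24L, 24L, 16L))
  vols <- generateDataset(spec, c(1, 1, 1), seed = 5L)
  expect_length(vols, 3L)
  expect_identical(vapply(vols, cellLabel, integer(1)), 0:2)
  again <- generateDataset(spec, c(1, 1, 1), seed = 5L)
  expect_identical(lapply(vols, riGrid), lapply(again, riGrid))
})

test_that("degenerate phantom specifications are rejected", {
  expect_error(PhantomSpec(gridShape = c(0, 10, 10)), "invalid")
  expect_error(PhantomSpec(cytoplasmRiRange = c(1.34, 1.34)), "empty")
  expect_error(generatePhantom(smallSpec(), 5L), "label")
  expect_error(
    generatePhantom(PhantomSpec(gridShape = c(40L, 40L, 28L),
                                voxelSpacing = c(0.1, 0.1, 0.1)), 0L, 1L),
    "too small")
  bad <- smallSpec()
  expect_error({
    bad@nucleolusRiRange <- c(1.30, 1.36)
    validObject(bad)
  }, "1.345")
})
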
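test_that("voxelToPoints enumerates exactly the mask voxels", {
  ri <- array(seq(1.33, 1.40, length.out = 8), c(2, 2, 2))
  mask <- array(FALSE, c(2, 2, 2))
  mask[c(1, 4, 7)] <- TRUE
  vol <- VoxelVolume(ri, spacing = c(0.5, 0.5, 0.25), mask = mask)
  cl <- voxelToPoints(vol)
  expect_equal(nPoints(cl), 3L)
  expect_setequal(riValues(cl), ri[c(1, 4, 7)])
  # voxel (1,1,1) -> physical origin (0-based convention)
  expect_true(any(rowSums(abs(coords(cl))) == 0))

  full <- VoxelVolume(ri, mask = array(TRUE, c(2, 2, 2)))
  expect_equal(nPoints(voxelToPoints(full)), 8L)
  expect_error(voxelToPoints(VoxelVolume(ri)), "foreground")
})

test_that("phantom cloud size tracks the scaled voxel budget", {
  # 40x40x28 grid holds 1/384 of the acquisition voxels; the reference
  # 5e5..4e6 per-cell budget scales to ~1.3e3..1.1e4
  m <- nPoints(smallCloud())
  expect_gte(m, 1.3e3)
  expect_lte(m, 1.1e4)
})

test_that("randomSample draws uniformly without replacement", {
  cl <- smallCloud()
  all_ <- randomSample(cl, nPoints(cl), seed = 1L)
  expect_setequal(riValues(all_), riValues(cl))

  # distributional oracle: interval histogram of a 1000-point draw matches
  # the source histogram (chi-square GOF, merged sparse bins)
  src <- intervalHistogram(cl, 6)
  rng <- range(riValues(cl))
  rejected <- 0L
  for (seed in 1:20) {
    s <- randomSample(cl, 1000L, seed = seed)
    obs <- intervalHistogram(s, 6, range = rng)
    p <- src / sum(src)
    keep <- p * 1000 >= 5
    obs2 <- c(obs[keep], sum(obs[!keep]))
    p2 <- c(p[keep], sum(p[!keep]))
    pval <- suppressWarnings(
      stats::chisq.test(obs2, p = p2)$p.value)
    if (pval < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
  expect_error(randomSample(cl, nPoints(cl) + 1L), "insufficient")
})

test_that("segmented sampling follows the quota and supplementation rule", {
  # toy availabilities (50,30,10,5,3,2), M=30, L=6: quotas of 5 give
  # per-interval takes (5,5,5,5,3,2) = 25 plus 5 supplemented points
  cl <- availabilityCloud(c(50, 30, 10, 5, 3, 2))
  cfg <- SamplerConfig(m = 30L, l = 6L, riNormalization = "fixed-range",
                       seed = 4L)
  out <- segmentedEquilibriumSample(cl, cfg)
  expect_equal(nPoints(out), 30L)
  h <- intervalHistogram(out, 6, range = c(1.33, 1.40))
  expect_true(all(h >= c(5, 5, 5, 5, 3, 2)))
  expect_equal(h[4:6], c(5, 3, 2))          # exhausted intervals
  expect_equal(sum(h) - 25, 5)              # supplementation size
  # conservation: every output point is an input point
  expect_true(all(riValues(out) %in% riValues(cl)))
})

test_that("segmented sampling equals a brute-force reimplementation of the
           quota rule across random configurations", {
  bruteQuota <- function(avail, m, l) {
    quota <- rep(m %/% l, l)
    r <- m %% l
    if (r > 0) quota[seq_len(r)] <- quota[seq_len(r)] + 1L
    take <- pmin(quota, avail)
    list(take = take, supplement = m - sum(take))
  }
  withr::with_seed(42, {
    for (trial in 1:100) {
      l <- sample(1:8, 1)
      avail <- sample(0:30, l, replace = TRUE)
      if (sum(avail) == 0) avail[1] <- 1
      m <- sample(seq_len(sum(avail)), 1)
      if (m < l) l <- m
      avail <- avail[seq_len(l)]
      if (m > sum(avail)) m <- sum(avail)
      cl <- availabilityCloud(avail, l = l)
      out <- segmentedEquilibriumSample(cl,
        SamplerConfig(m = m, l = l, riNormalization = "fixed-range",
                      seed = trial))
      ref <- bruteQuota(avail, m, l)
      h <- intervalHistogram(out, l, range = c(1.33, 1.40))
      expect_equal(nPoints(out), m)
      expect_true(all(h >= ref$take))
      expect_equal(sum(h - ref$take), ref$supplement)
      # no duplicates: sampling is without replacement
      key <- paste(coords(out)[, 1], coords(out)[, 2], coords(out)[, 3])
      expect_equal(anyDuplicated(key), 0L)
    }
  })
})

test_that("single-interval segmented sampling degenerates to a plain draw", {
  cl <- toyCloud(200)
  out <- segmentedEquilibriumSample(cl, SamplerConfig(m = 50L, l = 1L,
                                                      seed = 2L))
  expect_equal(nPoints(out), 50L)
  expect_true(all(riValues(out) %in% riValues(cl)))
})

test_that("segmented output is more balanced than random on skewed clouds", {
  cl <- smallCloud()
  rng <- range(riValues(cl))
  for (seed in 1:5) {
    seg <- segmentedEquilibriumSample(cl, SamplerConfig(m = 1000L,
                                                        seed = seed))
    rnd <- randomSample(cl, 1000L, seed = seed)
    ratio <- function(h) max(h) / max(min(h), 1)
    expect_lte(ratio(intervalHistogram(seg, 6, range = rng)),
               ratio(intervalHistogram(rnd, 6, range = rng)))
  }
})

test_that("segmented sampling is deterministic given its seed", {
  cl <- smallCloud()
  cfg <- SamplerConfig(m = 500L, seed = 9L)
  a <- segmentedEquilibriumSample(cl, cfg)
  b <- segmentedEquilibriumSample(cl, cfg)
  expect_identical(coords(a), coords(b))
  expect_identical(riValues(a), riValues(b))
})

test_that("unit-sphere normalization centers, scales and guards", {
  cl <- RIPointCloud(rbind(c(0, 0, 0), c(2, 0, 0)), c(1.34, 1.35))
  n <- normalizeUnitSphere(cl)
  expect_equal(coords(n), rbind(c(-1, 0, 0), c(1, 0, 0)),
               ignore_attr = TRUE)
  one <- normalizeUnitSphere(RIPointCloud(cbind(5, 6, 7), 1.36))
  expect_equal(as.numeric(coords(one)), c(0, 0, 0))

  ph <- normalizeUnitSphere(smallCloud())
  expect_equal(max(sqrt(rowSums(coords(ph)^2))), 1, tolerance = 1e-6)
  expect_identical(riValues(ph), riValues(smallCloud()))
  expect_true(isNormalized(ph))
})

test_that("interval histograms partition the cloud", {
  cl <- toyCloud(500)
  for (l in c(1, 3, 6, 11))
    expect_equal(sum(intervalHistogram(cl, l)), 500L)

  # plentiful source: segmented output is near-uniform across intervals
  cl2 <- availabilityCloud(rep(100L, 6))
  out <- segmentedEquilibriumSample(cl2,
    SamplerConfig(m = 300L, l = 6L, riNormalization = "fixed-range",
                  seed = 1L))
  h <- intervalHistogram(out, 6, range = c(1.33, 1.40))
  expect_lte(max(h) - min(h), 1L)

  # random sampling inherits the source skew on phantom clouds
  rnd <- randomSample(smallCloud(), 1000L, seed = 3L)
  h2 <- intervalHistogram(rnd, 6, range = range(riValues(smallCloud())))
  expect_gte(h2[1], 1e2 * max(h2[6], 1))
})
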
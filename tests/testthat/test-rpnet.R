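test_that("ball query caps, pads and matches a brute-force oracle", {
  # isolated center: padded with its own index
  pts <- rbind(c(0, 0, 0), c(5, 0, 0), c(5.1, 0, 0))
  g <- RIPointNet:::ball_query_cpp(pts[1, , drop = FALSE], pts, 0.5, 4L)
  expect_equal(as.integer(g), rep(1L, 4))
  # exactly nsample in-radius neighbors: no padding
  g2 <- RIPointNet:::ball_query_cpp(pts[2, , drop = FALSE], pts, 0.2, 2L)
  expect_equal(as.integer(g2), c(2L, 3L))

  withr::with_seed(11, {
    for (trial in 1:25) {
      n <- sample(20:200, 1)
      xyz <- matrix(stats::rnorm(n * 3, sd = 0.5), n, 3)
      nc <- sample(1:10, 1)
      ctr <- xyz[sample(n, nc), , drop = FALSE]
      r <- stats::runif(1, 0.2, 0.8)
      ns <- sample(1:8, 1)
      expect_equal(
        unname(RIPointNet:::ball_query_cpp(ctr, xyz, r, ns)),
        unname(bruteBallQuery(ctr, xyz, r, ns)))
    }
  })
})

test_that("max pooling is idempotent under duplicated non-maximal rows", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(8 * 5), 8, 5)
    X[1, ] <- 10
    X[5, ] <- 10
    p1 <- RIPointNet:::maxPoolGroups(X, 4L)
    # replace one non-maximal row per block with a copy of another
    X2 <- X
    X2[2, ] <- X[3, ]
    X2[6, ] <- X[7, ]
    p2 <- RIPointNet:::maxPoolGroups(X2, 4L)
    expect_equal(p1$out, p2$out)
    # groups of identical rows pool to that row
    X3 <- X[rep(1, 4), ]
    expect_equal(RIPointNet:::maxPoolGroups(X3, 4L)$out, X[1, , drop = FALSE],
                 ignore_attr = TRUE)
  })
})

test_that("backpropagation matches finite differences", {
  model <- buildRPNet(tinyConfig(), seed = 7L)
  sets <- lapply(1:3, function(b) randomSet(24L, label = b - 1L,
                                            seed = b + 10L))
  labels <- 0:2
  batch <- RIPointNet:::assembleBatch(sets)
  fwd <- RIPointNet:::rpnetForwardCore(model, batch, training = TRUE,
                                       withCache = TRUE)
  ce <- RIPointNet:::smoothedCeGrad(fwd$logp, labels, 0.1)
  grads <- RIPointNet:::rpnetBackwardCore(model, fwd, ce$dLogits)
  lossAt <- function(m) {
    f <- RIPointNet:::rpnetForwardCore(m, batch, training = TRUE)
    RIPointNet:::smoothedCeGrad(f$logp, labels, 0.1)$loss
  }
  eps <- 1e-6
  withr::with_seed(1, {
    for (nm in names(model@params)) {
      expect_false(is.null(grads[[nm]]), info = nm)
      i <- sample.int(length(model@params[[nm]]), 1L)
      up <- model; up@params[[nm]][i] <- up@params[[nm]][i] + eps
      dn <- model; dn@params[[nm]][i] <- dn@params[[nm]][i] - eps
      fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      an <- grads[[nm]][i]
      if (abs(fd) > 1e-7 || abs(an) > 1e-7)
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4,
                  label = sprintf("gradient of %s[%d]", nm, i))
    }
  })
})

test_that("eval-mode forward normalizes and is permutation invariant", {
  model <- buildRPNet(tinyConfig(), seed = 1L)
  set <- randomSet(32L, seed = 5L)
  lp <- rpnetForward(model, set)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-5)
  withr::with_seed(2, {
    for (i in 1:5) {
      perm <- sample(nPoints(set))
      shuffled <- new("TrainingPointSet", coords = coords(set)[perm, ],
                      ri = riValues(set)[perm], normalized = TRUE,
                      label = 0L, provenance = provenance(set)[perm])
      expect_equal(unname(rpnetForward(model, shuffled)), unname(lp),
                   tolerance = 1e-5)
    }
  })
})

test_that("forward rejects malformed inputs", {
  model <- buildRPNet(tinyConfig(), seed = 1L)
  expect_error(rpnetForward(model, randomSet(4L)), "input-shape")
  expect_error(rpnetForward(model, list(randomSet(32L), randomSet(16L))),
               "share K")
})

test_that("closed-form parameter count matches the reference figures", {
  cfg <- RPNetConfig()
  # head alone: (1024*512+512) + 2*512 + (512*256+256) + 2*256 + (256*3+3)
  headCount <- (1024 * 512 + 512) + 1024 + (512 * 256 + 256) + 512 +
    (256 * 3 + 3)
  expect_equal(headCount, 658435)
  expect_equal(countParameters(cfg), 1466243L)
  expect_equal(round(countParameters(cfg) / 1e6, 2), 1.47)
  # 3-channel variant differs only in the 64 first-layer weights
  expect_equal(countParameters(cfg) - countParameters(RPNetConfig(3L)), 64L)
})

test_that("closed-form count equals enumeration of built models", {
  expect_equal(countParameters(RPNetConfig()),
               modelParameterCount(buildRPNet(RPNetConfig(), seed = 1L)))
  withr::with_seed(21, {
    for (trial in 1:20) {
      w1 <- sample(4:32, 3); w2 <- sample(8:64, 3); w3 <- sample(8:64, 2)
      h1 <- sample(8:64, 1)
      cfg <- RPNetConfig(
        inputChannels = sample(c(3L, 4L), 1),
        saLevels = list(
          SAConfig(16L, 0.3, 8L, w1),
          SAConfig(8L, 0.6, 8L, w2),
          SAConfig(NA, NA, NA, w3)),
        head = HeadConfig(c(tail(w3, 1), h1, 3L), 0.1))
      expect_equal(countParameters(cfg),
                   modelParameterCount(buildRPNet(cfg)))
    }
  })
})

test_that("analytic FLOP count reproduces the reference magnitude", {
  cfg <- RPNetConfig()
  # level-1 closed form: 512*32*(4*64 + 64*64 + 64*128)
  d <- countFlops(cfg, 1024L, detail = TRUE)
  expect_equal(512 * 32 * (4 * 64 + 64 * 64 + 64 * 128), 205520896)
  expect_equal(countFlops(RPNetConfig(
    saLevels = list(SAConfig(512L, 0.15, 32L, c(64L, 64L, 128L)),
                    SAConfig(NA, NA, NA, c(131L, 131L))),
    head = HeadConfig(c(131L, 3L), numeric(0))) , 1024L) >
    205520896, TRUE)
  expect_equal(countFlops(cfg), 1470956288)
  # head MACs: 1024*512 + 512*256 + 256*3
  expect_equal(1024 * 512 + 512 * 256 + 256 * 3, 656128)
  expect_lt(abs(countFlops(cfg) / 1e9 - 1.49) / 1.49, 0.05)
  expect_true(all(c("bias", "bn", "relu", "pool") %in% names(d)))
})
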
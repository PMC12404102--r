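# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, expr, envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# small noise-free phantom and its cloud
smallSpec <- function(noiseSigma = 0) {
  PhantomSpec(gridShape = c(40L, 40L, 28L), noiseSigma = noiseSigma)
}

smallPhantom <- function() {
  cached("smallPhantom", generatePhantom(smallSpec(), label = 0L, seed = 7L))
}

smallCloud <- function() {
  cached("smallCloud", voxelToPoints(smallPhantom()))
}

# desk-scale default phantom (the generator's default conditions)
deskPhantom <- function() {
  cached("deskPhantom", generatePhantom(PhantomSpec(), label = 1L, seed = 3L))
}

deskCloud <- function() {
  cached("deskCloud", voxelToPoints(deskPhantom()))
}

# random synthetic cloud with controllable RI values
toyCloud <- function(n, ri = NULL, seed = 1L) {
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(n * 3), n, 3)
    if (is.null(ri)) ri <- stats::runif(n, 1.33, 1.40)
    RIPointCloud(xyz, ri)
  })
}

# a cloud with availability[i] points at the center of interval i of the
# fixed physical range [1.33, 1.40]; use riNormalization = "fixed-range"
# so interval membership is exact by construction
availabilityCloud <- function(availability, l = length(availability),
                              seed = 1L) {
  ri <- unlist(lapply(seq_along(availability), function(i)
    rep(1.33 + 0.07 * (i - 0.5) / l, availability[i])))
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(length(ri) * 3), length(ri), 3)
    RIPointCloud(xyz, ri)
  })
}

# independent brute-force FPS oracle (O(k n^2), used on small instances)
bruteFps <- function(xyz, k, start) {
  sel <- start
  d2 <- rep(Inf, nrow(xyz))
  for (i in seq_len(k - 1L)) {
    last <- xyz[sel[length(sel)], ]
    dd <- colSums((t(xyz) - last)^2)
    d2 <- pmin(d2, dd)
    cand <- setdiff(seq_len(nrow(xyz)), sel)
    sel <- c(sel, cand[which.max(d2[cand])])
  }
  sel
}

# independent brute-force ball-query oracle with the same nearest-first
# cap (ties by index) and pad rule
bruteBallQuery <- function(centers, xyz, radius, nsample) {
  rows <- lapply(seq_len(nrow(centers)), function(c) {
    dd <- colSums((t(xyz) - centers[c, ])^2)
    inR <- which(dd <= radius^2)
    if (!length(inR)) inR <- which.min(dd)
    inR <- inR[order(dd[inR], inR)]
    g <- inR[seq_len(min(nsample, length(inR)))]
    c(g, rep(g[1], nsample - length(g)))
  })
  matrix(unlist(rows), nrow = nrow(centers), ncol = nsample, byrow = TRUE)
}

# unit-sphere-normalized random training point set
randomSet <- function(K, label = 0L, seed = 1L) {
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(K * 3), K, 3)
    xyz <- xyz / max(sqrt(rowSums(xyz^2)))
    new("TrainingPointSet", coords = xyz,
        ri = stats::runif(K, 1.335, 1.38), normalized = TRUE,
        label = as.integer(label), provenance = rep("fps", K))
  })
}

# tiny network configuration for fast forward/backward tests
# (head has one hidden layer, hence a single dropout rate)
tinyConfig <- function(channels = 4L, dropout = 0) {
  RPNetConfig(inputChannels = channels,
              saLevels = list(
                SAConfig(8L, 0.5, 4L, c(8L, 8L)),
                SAConfig(4L, 0.9, 4L, c(8L, 16L)),
                SAConfig(NA, NA, NA, c(16L, 16L))),
              head = HeadConfig(c(16L, 8L, 3L), dropout[1]))
}
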
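#' Construct an RIPCSConfig
#'
#' @param k total selected points (default 1024).
#' @param nFps farthest-point-sampled points (default 800).
#' @param nRiies RI-interval-enhanced points (default 224);
#'   \code{nFps + nRiies} must equal \code{k}.
#' @param riInterval closed RI band (default [1.345, 1.355], the nucleolar
#'   band, whose RI changes track cell viability).
#' @param fpsStart \code{"random"} or \code{"deterministic"}.
#' @param seed integer seed or \code{NA}.
#' @return an \linkS4class{RIPCSConfig}.
#' @export
RIPCSConfig <- function(k = 1024L, nFps = 800L, nRiies = 224L,
                        riInterval = c(1.345, 1.355), fpsStart = "random",
                        seed = NA_integer_) {
  new("RIPCSConfig", k = as.integer(k), nFps = as.integer(nFps),
      nRiies = as.integer(nRiies), riInterval = as.numeric(riInterval),
      fpsStart = fpsStart, seed = as.integer(seed))
}

# internal: deterministic FPS start — point farthest from the centroid,
# ties broken by lexicographic (x, y, z) order
deterministicStart <- function(xyz) {
  ctr <- colMeans(xyz)
  d2 <- rowSums(sweep(xyz, 2L, ctr, "-")^2)
  cand <- which(d2 >= max(d2) - 1e-300)
  cand <- cand[abs(d2[cand] - max(d2)) < 1e-12 * max(max(d2), 1)]
  if (length(cand) > 1L) {
    o <- order(xyz[cand, 1], xyz[cand, 2], xyz[cand, 3])
    cand <- cand[o]
  }
  cand[1]
}

#' Farthest point sampling
#'
#' Greedy spatial subsampling: starting from \code{start}, each subsequent
#' point maximizes the minimum Euclidean distance (coordinates only; the RI
#' channel is ignored) to all previously selected points, yielding uniform
#' spatial coverage. Ties take the lowest index.
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param k points to select.
#' @param start an explicit 1-based start index, \code{"random"} (seeded) or
#'   \code{"deterministic"} (farthest from the centroid, lexicographic
#'   tie-break).
#' @param seed integer seed or \code{NA}; used only for a random start.
#' @return integer vector of \code{k} distinct point indices in selection
#'   order.
#' @examples
#' cl <- RIPointCloud(cbind(c(0, 1, 2, 3, 10), 0, 0), rep(1.34, 5))
#' farthestPointSample(cl, 3, start = 1)   # 1, 5 (x=10), 4 (x=3)
#' @export
farthestPointSample <- function(cloud, k, start = "random",
                                seed = NA_integer_) {
  k <- as.integer(k)
  n <- nPoints(cloud)
  if (k > n) stop("insufficient points: k exceeds the cloud size")
  if (k < 1L) stop("k must be >= 1")
  xyz <- cloud@coords
  startIdx <-
    if (is.numeric(start)) as.integer(start)
    else if (identical(start, "deterministic")) deterministicStart(xyz)
    else if (identical(start, "random")) withSeed(seed, sample.int(n, 1L))
    else stop("'start' must be an index, 'random' or 'deterministic'")
  as.integer(fps_cpp(xyz, k, startIdx))
}

#' RI-interval-enhanced sampling
#'
#' Draws \code{k} points whose RI lies in the closed band
#' \code{riInterval}. If the band holds at least \code{k} points, \code{k}
#' are drawn uniformly without replacement; otherwise every band point is
#' taken and replicated in shuffled cyclic order until the multiset has
#' exactly \code{k} entries (replicate multiplicities differ by at most 1).
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param k points to draw (default 224).
#' @param riInterval closed RI band.
#' @param seed integer seed or \code{NA}.
#' @return integer index multiset of length \code{k}; every index has RI in
#'   the band.
#' @export
riiesSample <- function(cloud, k = 224L, riInterval = c(1.345, 1.355),
                        seed = NA_integer_) {
  k <- as.integer(k)
  inBand <- which(cloud@ri >= riInterval[1] & cloud@ri <= riInterval[2])
  if (!length(inBand))
    stop(sprintf(
      "empty RI interval [%g, %g]: cloud RI range is [%g, %g]",
      riInterval[1], riInterval[2], min(cloud@ri), max(cloud@ri)))
  n <- length(inBand)
  withSeed(seed, {
    if (n >= k) {
      inBand[sample.int(n, k)]
    } else {
      full <- k %/% n
      extra <- k %% n
      perm <- inBand[sample.int(n)]
      c(rep(inBand, full), perm[seq_len(extra)])
    }
  })
}

#' Hybrid training-point-set selection
#'
#' The point cloud selector: combines farthest point sampling (global
#' spatial coverage, \code{nFps} points) with RI-interval-enhanced sampling
#' (nucleolar-band coverage, \code{nRiies} points) into one fixed-size
#' training point set. The two subsets are concatenated as a multiset (a
#' point picked by both samplers appears twice), guaranteeing exactly
#' \code{k} points, then shuffled; per-point provenance tags are kept.
#' With a random FPS start and no seed the selection is stochastic, which
#' serves as data augmentation during training; deterministic selection
#' (\code{fpsStart = "deterministic"} plus a fixed seed) is used at
#' evaluation.
#'
#' @param cloud an \linkS4class{RIPointCloud} (normally unit-sphere
#'   normalized).
#' @param config an \linkS4class{RIPCSConfig}.
#' @return a \linkS4class{TrainingPointSet} of exactly \code{config@k}
#'   points.
#' @examples
#' vol <- generatePhantom(PhantomSpec(gridShape = c(32, 32, 24)), 0L, 1L)
#' cl <- normalizeUnitSphere(voxelToPoints(vol))
#' ripcsSelect(cl, RIPCSConfig(k = 64, nFps = 50, nRiies = 14, seed = 1))
#' @export
ripcsSelect <- function(cloud, config = RIPCSConfig()) {
  validObject(config)
  if (config@nFps > 0L && nPoints(cloud) < config@nFps)
    stop("insufficient points: cloud smaller than nFps")
  withSeed(config@seed, {
    fpsIdx <- if (config@nFps > 0L)
      farthestPointSample(cloud, config@nFps, start = config@fpsStart)
    else integer(0)
    riIdx <- if (config@nRiies > 0L)
      riiesSample(cloud, config@nRiies, config@riInterval)
    else integer(0)
    idx <- c(fpsIdx, riIdx)
    tags <- c(rep("fps", length(fpsIdx)), rep("riies", length(riIdx)))
    perm <- sample.int(length(idx))
    idx <- idx[perm]; tags <- tags[perm]
    new("TrainingPointSet",
        coords = cloud@coords[idx, , drop = FALSE], ri = cloud@ri[idx],
        normalized = cloud@normalized, label = cloud@label,
        provenance = tags)
  })
}

#' Covering radius of a selected subset
#'
#' Maximum distance from any cloud point to its nearest selected point;
#' small values indicate good spatial coverage (the property farthest point
#' sampling optimizes greedily).
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param idx indices of the selected subset.
#' @return a single numeric distance.
#' @export
coveringRadius <- function(cloud, idx) {
  covering_radius_cpp(cloud@coords, as.integer(idx))
}
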
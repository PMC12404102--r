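#' Construct a SamplerConfig
#'
#' @param m target point count (default 10000).
#' @param l number of RI intervals (default 6).
#' @param mode \code{"segmented"} (segmented equilibrium sampling) or
#'   \code{"random"}.
#' @param riNormalization \code{"per-cell"} (min-max over the cloud's own RI
#'   values, the default) or \code{"fixed-range"} ([1.33, 1.40], for
#'   cross-sample comparability when absolute RI matters).
#' @param seed integer seed or \code{NA} (ambient RNG stream).
#' @return a \linkS4class{SamplerConfig}.
#' @export
SamplerConfig <- function(m = 10000L, l = 6L, mode = "segmented",
                          riNormalization = "per-cell", seed = NA_integer_) {
  new("SamplerConfig", m = as.integer(m), l = as.integer(l), mode = mode,
      riNormalization = riNormalization, seed = as.integer(seed))
}

# internal: subset a cloud by point indices, preserving class membership
cloudSubset <- function(cloud, idx) {
  out <- RIPointCloud(cloud@coords[idx, , drop = FALSE], cloud@ri[idx],
                      normalized = cloud@normalized, label = cloud@label)
  out
}

# internal: map RI values to 1..l equal-width intervals over `range`
riIntervalIndex <- function(ri, l, range) {
  if (range[2] <= range[1]) return(rep(1L, length(ri)))
  z <- (ri - range[1]) / (range[2] - range[1])
  pmax(1L, pmin(as.integer(l), as.integer(floor(z * l)) + 1L))
}

# internal: normalization range for interval division
riNormRange <- function(ri, riNormalization) {
  switch(riNormalization,
         "per-cell" = range(ri),
         "fixed-range" = c(1.33, 1.40),
         stop("unknown riNormalization"))
}

#' Enumerate foreground voxels as an RI point cloud
#'
#' One point per foreground voxel: coordinates are 0-based voxel index times
#' spacing (micrometres); RI values are copied unchanged, in column-major
#' voxel order.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param mask logical array; defaults to the volume's own mask.
#' @return an \linkS4class{RIPointCloud} with one point per mask voxel.
#' @examples
#' vol <- generatePhantom(PhantomSpec(gridShape = c(32, 32, 24)), 0L, 1L)
#' voxelToPoints(vol)
#' @export
voxelToPoints <- function(volume, mask = foregroundMask(volume)) {
  if (is.null(mask) || !any(mask))
    stop("empty foreground: no mask voxels to enumerate")
  if (!identical(dim(mask), dim(volume@ri)))
    stop("mask dimensions must match the RI grid")
  idx <- which(mask, arr.ind = TRUE)
  sp <- spacing(volume)
  xyz <- sweep(idx - 1L, 2L, sp, "*")
  RIPointCloud(xyz, volume@ri[mask], normalized = FALSE,
               label = volume@label)
}

#' Simple threshold foreground mask
#'
#' Convenience helper marking voxels above an RI threshold as foreground.
#' This is not a cell-segmentation method; real tomograms are segmented
#' upstream by dedicated algorithms.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param threshold RI above which a voxel is foreground.
#' @return logical array.
#' @export
thresholdMask <- function(volume, threshold = 1.333) {
  volume@ri > threshold
}

#' Uniform random point-cloud downsampling
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param m points to keep (without replacement).
#' @param seed integer seed or \code{NA}.
#' @return an \linkS4class{RIPointCloud} of exactly \code{m} points.
#' @export
randomSample <- function(cloud, m, seed = NA_integer_) {
  m <- as.integer(m)
  if (m > nPoints(cloud))
    stop("insufficient points: m exceeds the cloud size")
  idx <- withSeed(seed, sample.int(nPoints(cloud), m))
  cloudSubset(cloud, idx)
}

#' Segmented equilibrium sampling
#'
#' Balanced voxel-cloud downsampling: the RI range is normalized (per-cell
#' min-max by default, or the fixed range [1.33, 1.40]) and partitioned into
#' \code{l} equal-width intervals. Each interval receives a quota of
#' \code{floor(m/l)} points (the remainder goes to the lowest-index
#' intervals) drawn uniformly without replacement; an interval holding fewer
#' points than its quota contributes everything it has, and the deficit is
#' drawn uniformly from the not-yet-sampled points of the other intervals.
#' The output has exactly \code{m} points, all distinct members of the
#' input. This counteracts the three-to-four orders-of-magnitude dominance
#' of the low-RI cytoplasm over nucleoli and lipid droplets in single-cell
#' tomograms.
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param config a \linkS4class{SamplerConfig} with \code{mode="segmented"}.
#' @return an \linkS4class{RIPointCloud} of exactly \code{config@m} points.
#' @examples
#' vol <- generatePhantom(PhantomSpec(gridShape = c(32, 32, 24)), 0L, 1L)
#' cl <- voxelToPoints(vol)
#' segmentedEquilibriumSample(cl, SamplerConfig(m = 500, l = 6, seed = 1))
#' @export
segmentedEquilibriumSample <- function(cloud, config = SamplerConfig()) {
  validObject(config)
  if (config@mode != "segmented")
    stop("config mode must be 'segmented'")
  m <- config@m; l <- config@l
  n <- nPoints(cloud)
  if (m > n) stop("insufficient points: m exceeds the cloud size")
  rng <- riNormRange(cloud@ri, config@riNormalization)
  iv <- riIntervalIndex(cloud@ri, l, rng)
  quota <- rep(m %/% l, l)
  rem <- m %% l
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L

  idx <- withSeed(config@seed, {
    picked <- vector("list", l)
    for (i in seq_len(l)) {
      ids <- which(iv == i)
      take <- min(quota[i], length(ids))
      picked[[i]] <- if (take > 0) ids[sample.int(length(ids), take)]
                     else integer(0)
    }
    sel <- unlist(picked)
    deficit <- m - length(sel)
    if (deficit > 0) {
      pool <- setdiff(seq_len(n), sel)
      sel <- c(sel, pool[sample.int(length(pool), deficit)])
    }
    sel
  })
  cloudSubset(cloud, idx)
}

#' Unit-sphere coordinate normalization
#'
#' Centers coordinates at their centroid and divides by the maximum centroid
#' distance, so the farthest point lies on the unit sphere. The RI channel
#' is untouched. An all-coincident cloud is centered with a unit scale
#' guard.
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @return the normalized cloud (\code{isNormalized} is \code{TRUE}).
#' @export
normalizeUnitSphere <- function(cloud) {
  if (nPoints(cloud) < 1L) stop("cannot normalize an empty cloud")
  ctr <- colMeans(cloud@coords)
  xyz <- sweep(cloud@coords, 2L, ctr, "-")
  scale <- sqrt(max(rowSums(xyz^2)))
  if (!is.finite(scale) || scale < 1e-12) scale <- 1
  out <- RIPointCloud(xyz / scale, cloud@ri, normalized = TRUE,
                      label = cloud@label)
  out
}

#' Per-interval RI point counts
#'
#' Counts points in \code{l} equal-width intervals over the normalization
#' range (the cloud's own min-max by default; pass \code{range} to count
#' against another cloud's range or a fixed physical range).
#'
#' @param cloud an \linkS4class{RIPointCloud}.
#' @param l number of intervals.
#' @param range optional numeric(2) normalization range.
#' @return integer vector of length \code{l}; sums to \code{nPoints(cloud)}.
#' @export
intervalHistogram <- function(cloud, l, range = NULL) {
  l <- as.integer(l)
  if (l < 1L) stop("'l' must be >= 1")
  if (is.null(range)) range <- range(cloud@ri)
  iv <- riIntervalIndex(cloud@ri, l, range)
  tabulate(iv, nbins = l)
}
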
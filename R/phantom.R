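#' Per-class phantom parameters
#'
#' \code{defaultClassParams} encodes the three viability-analogue classes of
#' the phantom through nucleolar count, radius and mean RI (2/3/4 nucleoli
#' with mean RI 1.352/1.350/1.348 for classes 0/1/2): nucleolar size, number
#' and RI are the features that drive viability classification, but the real
#' direction of the RI shift is not asserted here; these are documented
#' synthetic conventions, freely configurable. \code{riOnlyClassParams}
#' makes the three classes geometrically identical (same nucleolar count and
#' radius, same droplets) so that classes differ \emph{only} in nucleolar
#' mean RI; this is the configuration used by the ablation harness to probe
#' whether a model exploits the RI channel.
#'
#' @param nucleolusMeanRi numeric(3) per-class mean nucleolar RI.
#' @return list of 3 per-class parameter lists with elements
#'   \code{nNucleoli}, \code{nucleolusRadius} (micrometres),
#'   \code{nucleolusMeanRi}, \code{nDroplets}.
#' @export
defaultClassParams <- function(nucleolusMeanRi = c(1.352, 1.350, 1.348)) {
  stopifnot(length(nucleolusMeanRi) == 3L)
  mapply(function(nn, r, ri, nd)
           list(nNucleoli = nn, nucleolusRadius = r, nucleolusMeanRi = ri,
                nDroplets = nd),
         c(2L, 3L, 4L), c(1.2, 1.0, 0.85), nucleolusMeanRi, c(10L, 10L, 10L),
         SIMPLIFY = FALSE)
}

#' @rdname defaultClassParams
#' @export
riOnlyClassParams <- function(nucleolusMeanRi = c(1.352, 1.350, 1.348)) {
  stopifnot(length(nucleolusMeanRi) == 3L)
  lapply(nucleolusMeanRi, function(ri)
    list(nNucleoli = 3L, nucleolusRadius = 1.0, nucleolusMeanRi = ri,
         nDroplets = 8L))
}

#' Construct a PhantomSpec
#'
#' Defaults describe a desk-scale phantom: a 160 x 160 x 105 grid (an eighth
#' of the 320 x 320 x 210 acquisition grid) covering a fixed physical field
#' of 25.6 x 25.6 x 16.8 micrometres, so the cell keeps its physical size at
#' any grid resolution. The full-resolution grid is available by passing
#' \code{gridShape = c(320, 320, 210)}.
#'
#' @param gridShape integer(3) voxels per axis.
#' @param voxelSpacing micrometres per voxel; default fits the fixed
#'   25.6 x 25.6 x 16.8 um field to \code{gridShape}.
#' @param mediumRi background RI (default 1.330).
#' @param cytoplasmRiRange,nucleolusRiRange,dropletRiRange RI bands.
#' @param classParams see [defaultClassParams()].
#' @param cellSemiAxes nominal cell ellipsoid semi-axes, micrometres.
#' @param axisJitter fractional per-sample semi-axis jitter.
#' @param noiseSigma additive Gaussian RI noise (default 0.001, a typical
#'   tomographic RI precision).
#' @param seed default base seed for [generateDataset()].
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(gridShape = c(160L, 160L, 105L),
                        voxelSpacing = NULL,
                        mediumRi = 1.330,
                        cytoplasmRiRange = c(1.335, 1.345),
                        nucleolusRiRange = c(1.345, 1.355),
                        dropletRiRange = c(1.355, 1.380),
                        classParams = defaultClassParams(),
                        cellSemiAxes = c(8.7, 7.7, 5.5),
                        axisJitter = 0.1,
                        noiseSigma = 0.001,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3L || any(!is.finite(gridShape)) ||
      any(gridShape < 1L))
    stop("invalid phantom specification: 'gridShape' must be 3 positive integers")
  if (is.null(voxelSpacing))
    voxelSpacing <- c(25.6, 25.6, 16.8) / gridShape
  for (r in list(cytoplasmRiRange, nucleolusRiRange, dropletRiRange))
    if (length(r) != 2L || r[1] >= r[2])
      stop("invalid phantom specification: empty RI interval")
  new("PhantomSpec", gridShape = gridShape,
      voxelSpacing = as.numeric(voxelSpacing), mediumRi = mediumRi,
      cytoplasmRiRange = cytoplasmRiRange,
      nucleolusRiRange = nucleolusRiRange, dropletRiRange = dropletRiRange,
      classParams = classParams, cellSemiAxes = cellSemiAxes,
      axisJitter = axisJitter, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

# internal: adherent-cell orientation — uniform in-plane spin about z plus
# a small random tilt, keeping the flattened cell inside the axial field
randomRotation <- function() {
  a <- runif(1, 0, 2 * pi)
  tx <- rnorm(1, 0, 0.08)
  ty <- rnorm(1, 0, 0.08)
  rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(tx), sin(tx), 0, -sin(tx), cos(tx)), 3, 3)
  ry <- matrix(c(cos(ty), 0, -sin(ty), 0, 1, 0, sin(ty), 0, cos(ty)), 3, 3)
  rz %*% rx %*% ry
}

# internal: rasterize a sphere into linear voxel indices
# ax[[d]] are the physical axis coordinates along dimension d
sphereVoxels <- function(center, radius, ax, dims) {
  rng <- lapply(1:3, function(d) {
    i <- which(ax[[d]] >= center[d] - radius & ax[[d]] <= center[d] + radius)
    i
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- (ax[[1]][g$i] - center[1])^2 + (ax[[2]][g$j] - center[2])^2 +
        (ax[[3]][g$k] - center[3])^2
  keep <- d2 <= radius^2
  (g$i + (g$j - 1L) * dims[1] + (g$k - 1L) * dims[1] * dims[2])[keep]
}

#' Generate one synthetic RI cell phantom
#'
#' Builds a labeled RI volume: a randomly oriented ellipsoidal cell filled
#' with cytoplasm-band RI, an interior nucleus region, class-dependent
#' nucleolus spheres with RI in the nucleolar band, sparse high-RI lipid
#' droplet spheres, and optional additive Gaussian noise over the whole
#' grid. Deterministic given \code{(spec, label, seed)}; with
#' \code{noiseSigma = 0} every background voxel is exactly \code{mediumRi}
#' and every foreground voxel lies in the union of the tissue RI bands.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param label class index in \code{0:2}.
#' @param seed integer seed.
#' @return a \linkS4class{VoxelVolume} with mask and label set.
#' @examples
#' spec <- PhantomSpec(gridShape = c(40, 40, 28), noiseSigma = 0)
#' vol <- generatePhantom(spec, label = 0L, seed = 1L)
#' vol
#' @export
generatePhantom <- function(spec, label, seed = spec@seed) {
  validObject(spec)
  if (!(label %in% 0:2)) stop("label must be in 0:2")
  dims <- spec@gridShape
  sp <- spec@voxelSpacing
  extent <- (dims - 1L) * sp
  cp <- spec@classParams[[label + 1L]]

  withSeed(seed, {
    ax <- lapply(1:3, function(d) (seq_len(dims[d]) - 1) * sp[d])
    semi <- spec@cellSemiAxes *
      (1 + runif(3, -spec@axisJitter, spec@axisJitter))
    rot <- randomRotation()
    center <- extent / 2 + runif(3, -0.02, 0.02) * extent
    # bounding half-width of the rotated ellipsoid along each grid axis
    bound <- sqrt(rowSums(sweep(rot, 2L, semi, "*")^2))
    if (any(center - bound < 0) || any(center + bound > extent))
      stop("invalid phantom specification: grid too small to contain the cell")

    # cell-frame coordinates u = R^T (p - center), built by outer sums
    dx <- ax[[1]] - center[1]; dy <- ax[[2]] - center[2]
    dz <- ax[[3]] - center[3]
    u <- lapply(1:3, function(a)
      outer(outer(dx * rot[1, a], dy * rot[2, a], "+"), dz * rot[3, a], "+"))
    q <- (u[[1]] / semi[1])^2 + (u[[2]] / semi[2])^2 + (u[[3]] / semi[3])^2
    mask <- q <= 1

    # nucleus: smaller co-oriented ellipsoid, slightly offset
    nOff <- runif(3, -0.12, 0.12) * semi
    nSemi <- 0.55 * semi
    qn <- ((u[[1]] - nOff[1]) / nSemi[1])^2 +
          ((u[[2]] - nOff[2]) / nSemi[2])^2 +
          ((u[[3]] - nOff[3]) / nSemi[3])^2
    nucleus <- qn <= 1
    rm(q, qn)

    ri <- array(spec@mediumRi, dims)
    ncell <- sum(mask)
    ri[mask] <- runif(ncell, spec@cytoplasmRiRange[1],
                      spec@cytoplasmRiRange[2])
    # nucleoplasm sits in the lower half of the cytoplasm band
    nucRange <- c(spec@cytoplasmRiRange[1] + 0.002,
                  mean(spec@cytoplasmRiRange) - 0.002)
    if (nucRange[1] < nucRange[2])
      ri[nucleus] <- runif(sum(nucleus), nucRange[1], nucRange[2])

    # nucleoli: class-dependent count/radius/mean RI, inside the nucleus
    nucCenter <- center + as.vector(rot %*% nOff)
    for (i in seq_len(cp$nNucleoli)) {
      dir <- rnorm(3); dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
      radial <- runif(1, 0.15, 0.6)
      cFrame <- nOff + dir * radial * nSemi
      cWorld <- center + as.vector(rot %*% cFrame)
      r <- cp$nucleolusRadius * runif(1, 0.9, 1.1)
      vox <- sphereVoxels(cWorld, r, ax, dims)
      vox <- vox[mask[vox]]
      if (!length(vox)) next
      lo <- max(spec@nucleolusRiRange[1], cp$nucleolusMeanRi - 0.001)
      hi <- min(spec@nucleolusRiRange[2], cp$nucleolusMeanRi + 0.001)
      ri[vox] <- runif(length(vox), lo, hi)
    }

    # lipid droplets: small spheres in the cytoplasm (outside the nucleus)
    placed <- 0L; tries <- 0L
    while (placed < cp$nDroplets && tries < 40L * cp$nDroplets) {
      tries <- tries + 1L
      dir <- rnorm(3); dir <- dir / max(sqrt(sum(dir^2)), 1e-12)
      radial <- runif(1, 0.65, 0.92)
      cWorld <- center + as.vector(rot %*% (dir * radial * semi))
      r <- 0.3 * runif(1, 0.7, 1.3)
      vox <- sphereVoxels(cWorld, r, ax, dims)
      vox <- vox[mask[vox] & !nucleus[vox]]
      if (!length(vox)) next
      dRi <- runif(1, spec@dropletRiRange[1], spec@dropletRiRange[2])
      lo <- max(spec@dropletRiRange[1], dRi - 0.0005)
      hi <- min(spec@dropletRiRange[2], dRi + 0.0005)
      ri[vox] <- runif(length(vox), lo, hi)
      placed <- placed + 1L
    }

    if (spec@noiseSigma > 0)
      ri <- ri + array(rnorm(length(ri), 0, spec@noiseSigma), dims)

    VoxelVolume(ri = ri, spacing = sp, mask = mask,
                label = as.integer(label),
                metadata = list(seed = as.integer(seed),
                                specHash = objectHash(spec)))
  })
}

#' Generate a labeled phantom dataset
#'
#' Generates \code{nPerClass[c]} phantoms for each class \code{c} in
#' \code{0:2}, each with a distinct seed derived deterministically from
#' \code{seed}. Volumes are returned class-major (all class-0 volumes,
#' then class 1, then class 2).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nPerClass integer(3) volumes per class.
#' @param seed integer base seed.
#' @return list of \linkS4class{VoxelVolume}.
#' @examples
#' spec <- PhantomSpec(gridShape = c(32, 32, 24))
#' vols <- generateDataset(spec, c(1, 1, 1), seed = 7)
#' vapply(vols, cellLabel, integer(1))
#' @export
generateDataset <- function(spec, nPerClass, seed = spec@seed) {
  nPerClass <- as.integer(nPerClass)
  if (length(nPerClass) != 3L || any(nPerClass < 1L))
    stop("'nPerClass' must give >= 1 volume for each of the 3 classes")
  total <- sum(nPerClass)
  labels <- rep(0:2, nPerClass)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max, total))
  mapply(function(lab, s) generatePhantom(spec, lab, s),
         labels, seeds, SIMPLIFY = FALSE)
}

# internal: stable content hash without extra dependencies
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}
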
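#' @import methods
NULL

#' VoxelVolume: a 3D refractive-index grid
#'
#' Container for a single-channel 3D refractive-index (RI) volume as produced
#' by holographic tomography, together with its voxel spacing, an optional
#' foreground (cell) mask and an optional class label. Coordinates follow a
#' 0-based voxel-index convention: the physical position of voxel
#' \code{(i, j, k)} (1-based R indices) is \code{(i-1, j-1, k-1) * spacing}
#' micrometres.
#'
#' @slot ri 3D numeric array of dimensionless RI values.
#' @slot spacing numeric(3), micrometres per voxel along x, y, z.
#' @slot mask logical array with the same dimensions as \code{ri} marking
#'   foreground (cell) voxels, or a zero-length array when no mask is set.
#' @slot label integer class index in \code{0:2} (high / moderate / low
#'   viability analogue), or \code{NA} when unlabeled.
#' @slot metadata free-form list (generation seed, spec hash, provenance).
#'
#' @seealso [voxelToPoints()], [generatePhantom()]
#' @export
setClass("VoxelVolume",
  representation(ri = "array", spacing = "numeric", mask = "array",
                 label = "integer", metadata = "list"),
  prototype(ri = array(numeric(0), c(0, 0, 0)), spacing = c(1, 1, 1),
            mask = array(logical(0), c(0, 0, 0)), label = NA_integer_,
            metadata = list()))

setValidity("VoxelVolume", function(object) {
  msg <- character(0)
  if (length(dim(object@ri)) != 3L)
    msg <- c(msg, "'ri' must be a 3D array")
  if (length(object@ri) > 0 && !all(is.finite(object@ri)))
    msg <- c(msg, "all RI values must be finite")
  if (!(length(object@spacing) %in% c(1L, 3L)) || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 1 or 3 positive values (micrometres)")
  if (length(object@mask) > 0) {
    if (!identical(dim(object@mask), dim(object@ri)))
      msg <- c(msg, "'mask' dimensions must match 'ri'")
    if (!is.logical(object@mask))
      msg <- c(msg, "'mask' must be logical")
  }
  if (!is.na(object@label) && !(object@label %in% 0:2))
    msg <- c(msg, "'label' must be NA or in 0:2")
  if (length(msg)) msg else TRUE
})

#' RIPointCloud: points with a refractive-index attribute
#'
#' A cloud of M points \code{(x, y, z, n)} sampled from an RI voxel volume.
#' Coordinates are micrometres (or unit-sphere normalized after
#' [normalizeUnitSphere()]); the RI channel always carries raw physical RI
#' regardless of coordinate normalization.
#'
#' @slot coords numeric matrix, M x 3 (columns x, y, z).
#' @slot ri numeric vector of length M, dimensionless RI per point.
#' @slot normalized logical; \code{TRUE} after unit-sphere normalization.
#' @slot label integer class index in \code{0:2} or \code{NA}.
#'
#' @seealso [segmentedEquilibriumSample()], [ripcsSelect()]
#' @export
setClass("RIPointCloud",
  representation(coords = "matrix", ri = "numeric", normalized = "logical",
                 label = "integer"),
  prototype(coords = matrix(numeric(0), 0, 3), ri = numeric(0),
            normalized = FALSE, label = NA_integer_))

setValidity("RIPointCloud", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "'coords' must have 3 columns (x, y, z)")
  if (nrow(object@coords) != length(object@ri))
    msg <- c(msg, "'ri' length must equal the number of points")
  if (length(object@coords) > 0 && !all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "'normalized' must be a single logical")
  if (length(msg)) msg else TRUE
})

#' TrainingPointSet: the fixed-size hybrid-sampled point set
#'
#' The K-point training set S selected by the hybrid point-cloud selector:
#' the union (as a multiset concatenation) of a farthest-point-sampled subset
#' and an RI-interval-enhanced subset. Each point carries a provenance tag.
#'
#' @slot provenance character vector of length K with values \code{"fps"} or
#'   \code{"riies"}.
#' @seealso [ripcsSelect()]
#' @export
setClass("TrainingPointSet", contains = "RIPointCloud",
  representation(provenance = "character"),
  prototype(provenance = character(0)))

setValidity("TrainingPointSet", function(object) {
  msg <- character(0)
  if (length(object@provenance) != nrow(object@coords))
    msg <- c(msg, "'provenance' length must equal the number of points")
  if (length(object@provenance) &&
      !all(object@provenance %in% c("fps", "riies")))
    msg <- c(msg, "provenance tags must be 'fps' or 'riies'")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic RI cell phantom
#'
#' Describes the synthetic single-cell RI volume generator: grid geometry,
#' RI bands for the medium, cytoplasm, nucleoli and lipid droplets, per-class
#' nucleolar parameters and measurement noise. Defaults emulate an
#' adherent cultured cell: an ellipsoidal foreground of a few hundred thousand voxels at the
#' default desk-scale grid (an eighth of the 320 x 320 x 210 acquisition
#' grid), a heavily skewed RI histogram dominated by the low-RI cytoplasm,
#' nucleoli in the 1.345-1.355 band and sparse high-RI droplets.
#'
#' @slot gridShape integer(3) grid size in voxels.
#' @slot voxelSpacing numeric(3) micrometres per voxel.
#' @slot mediumRi background medium RI (default 1.330).
#' @slot cytoplasmRiRange numeric(2) cytoplasm RI band.
#' @slot nucleolusRiRange numeric(2), must lie within [1.345, 1.355].
#' @slot dropletRiRange numeric(2) lipid droplet RI band.
#' @slot classParams list of exactly 3 per-class lists with elements
#'   \code{nNucleoli}, \code{nucleolusRadius} (micrometres),
#'   \code{nucleolusMeanRi}, \code{nDroplets}.
#' @slot cellSemiAxes numeric(3) nominal cell ellipsoid semi-axes
#'   (micrometres) before per-sample jitter.
#' @slot axisJitter fractional per-sample jitter of the semi-axes.
#' @slot noiseSigma RI standard deviation of additive Gaussian noise.
#' @slot seed default base seed for dataset generation.
#' @seealso [generatePhantom()], [generateDataset()]
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacing = "numeric",
                 mediumRi = "numeric", cytoplasmRiRange = "numeric",
                 nucleolusRiRange = "numeric", dropletRiRange = "numeric",
                 classParams = "list", cellSemiAxes = "numeric",
                 axisJitter = "numeric", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  rng <- function(r) length(r) == 2L && r[1] <= r[2]
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msg <- c(msg, "'gridShape' must be 3 positive integers")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "'voxelSpacing' must be 3 positive values")
  for (nm in c("cytoplasmRiRange", "nucleolusRiRange", "dropletRiRange")) {
    r <- slot(object, nm)
    if (!rng(r))
      msg <- c(msg, sprintf("'%s' must be a non-empty interval", nm))
    else if (r[1] < 1.33 || r[2] > 1.40)
      msg <- c(msg, sprintf("'%s' must lie within [1.33, 1.40]", nm))
  }
  if (rng(object@nucleolusRiRange) &&
      (object@nucleolusRiRange[1] < 1.345 || object@nucleolusRiRange[2] > 1.355))
    msg <- c(msg, "'nucleolusRiRange' must lie within [1.345, 1.355]")
  if (length(object@classParams) != 3L)
    msg <- c(msg, "'classParams' must define exactly 3 classes")
  need <- c("nNucleoli", "nucleolusRadius", "nucleolusMeanRi", "nDroplets")
  for (cp in object@classParams)
    if (!all(need %in% names(cp)))
      msg <- c(msg, paste("each class needs:", paste(need, collapse = ", ")))
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (length(msg)) unique(msg) else TRUE
})

#' SamplerConfig: voxel-to-point-cloud sampling parameters
#'
#' @slot m integer target point count (default 10000).
#' @slot l integer number of RI intervals for segmented equilibrium sampling
#'   (default 6).
#' @slot mode \code{"random"} or \code{"segmented"}.
#' @slot riNormalization \code{"per-cell"} (min-max over the cloud) or
#'   \code{"fixed-range"} ([1.33, 1.40]) for interval division.
#' @slot seed integer seed, or \code{NA} to use the ambient RNG stream.
#' @seealso [segmentedEquilibriumSample()]
#' @export
setClass("SamplerConfig",
  representation(m = "integer", l = "integer", mode = "character",
                 riNormalization = "character", seed = "integer"))

setValidity("SamplerConfig", function(object) {
  msg <- character(0)
  if (object@l < 1L) msg <- c(msg, "'l' must be >= 1")
  if (object@m < 1L) msg <- c(msg, "'m' must be >= 1")
  if (object@l > object@m) msg <- c(msg, "'l' must not exceed 'm'")
  if (!object@mode %in% c("random", "segmented"))
    msg <- c(msg, "'mode' must be 'random' or 'segmented'")
  if (!object@riNormalization %in% c("per-cell", "fixed-range"))
    msg <- c(msg, "'riNormalization' must be 'per-cell' or 'fixed-range'")
  if (length(msg)) msg else TRUE
})

#' RIPCSConfig: hybrid training-point-set selector parameters
#'
#' Parameters of the refractive-index point cloud selector, combining
#' farthest point sampling (\code{nFps} points, spatial coverage) with
#' RI-interval-enhanced sampling (\code{nRiies} points drawn from the
#' nucleolar RI band, replicated when the band is underpopulated).
#'
#' @slot k total selected points (default 1024).
#' @slot nFps farthest-point-sampled count (default 800).
#' @slot nRiies RI-interval-enhanced count (default 224).
#' @slot riInterval closed RI band targeted by the enhanced sampler
#'   (default [1.345, 1.355], the nucleolar band).
#' @slot fpsStart \code{"random"} (stochastic augmentation) or
#'   \code{"deterministic"} (farthest from centroid, lexicographic
#'   tie-break; for reproducible inference).
#' @slot seed integer seed or \code{NA}.
#' @seealso [ripcsSelect()]
#' @export
setClass("RIPCSConfig",
  representation(k = "integer", nFps = "integer", nRiies = "integer",
                 riInterval = "numeric", fpsStart = "character",
                 seed = "integer"))

setValidity("RIPCSConfig", function(object) {
  msg <- character(0)
  if (object@nFps + object@nRiies != object@k)
    msg <- c(msg, "'nFps' + 'nRiies' must equal 'k'")
  if (object@nFps < 0 || object@nRiies < 0)
    msg <- c(msg, "counts must be non-negative")
  if (length(object@riInterval) != 2L ||
      object@riInterval[1] > object@riInterval[2])
    msg <- c(msg, "'riInterval' must be a closed non-empty interval")
  if (object@riInterval[1] < 1.0 || object@riInterval[2] > 2.0)
    msg <- c(msg, "'riInterval' outside physical RI bounds")
  if (!object@fpsStart %in% c("random", "deterministic"))
    msg <- c(msg, "'fpsStart' must be 'random' or 'deterministic'")
  if (length(msg)) msg else TRUE
})

#' RPNetConfig and its components
#'
#' \code{SAConfig} describes one set-abstraction level: the number of centers
#' selected by farthest point sampling, the ball-query radius in unit-sphere
#' coordinates, the per-region point cap and the pointwise MLP widths. A
#' group-all level has \code{NA} centers/radius/cap. \code{HeadConfig}
#' describes the fully connected classifier head. \code{RPNetConfig} ties
#' three SA levels and the head together with the input channel count
#' (3 for x,y,z; 4 adds the RI channel).
#'
#' @slot nCenter integer, centers per level (\code{NA} = group all).
#' @slot radius numeric ball-query radius in normalized coordinates.
#' @slot nSample integer per-region point cap (\code{NA} = all points).
#' @slot mlpWidths integer vector of pointwise layer widths.
#' @aliases SAConfig HeadConfig
#' @export
setClass("SAConfig",
  representation(nCenter = "integer", radius = "numeric",
                 nSample = "integer", mlpWidths = "integer"))

setValidity("SAConfig", function(object) {
  msg <- character(0)
  if (any(object@mlpWidths <= 0)) msg <- c(msg, "MLP widths must be positive")
  if (!is.na(object@nCenter) && object@nCenter < 1)
    msg <- c(msg, "'nCenter' must be positive or NA (group all)")
  if (!is.na(object@nCenter) && (is.na(object@radius) || object@radius <= 0))
    msg <- c(msg, "'radius' must be > 0 for ball-query levels")
  if (length(msg)) msg else TRUE
})

#' @slot dims integer vector of fully connected dims, e.g. c(1024,512,256,3).
#' @slot dropout numeric dropout rates after all but the final layer.
#' @rdname SAConfig-class
#' @export
setClass("HeadConfig",
  representation(dims = "integer", dropout = "numeric"))

setValidity("HeadConfig", function(object) {
  msg <- character(0)
  if (length(object@dims) < 2L) msg <- c(msg, "head needs >= 2 dims")
  if (any(object@dims <= 0)) msg <- c(msg, "head dims must be positive")
  if (length(object@dropout) != length(object@dims) - 2L)
    msg <- c(msg, "one dropout rate per hidden layer is required")
  if (length(object@dropout) && any(object@dropout < 0 | object@dropout >= 1))
    msg <- c(msg, "dropout rates must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @slot inputChannels 3 (x,y,z) or 4 (x,y,z,n).
#' @slot saLevels list of three \code{SAConfig} objects.
#' @slot head a \code{HeadConfig}.
#' @slot nClasses number of output classes.
#' @rdname SAConfig-class
#' @export
setClass("RPNetConfig",
  representation(inputChannels = "integer", saLevels = "list",
                 head = "HeadConfig", nClasses = "integer"))

setValidity("RPNetConfig", function(object) {
  msg <- character(0)
  if (!object@inputChannels %in% c(3L, 4L))
    msg <- c(msg, "'inputChannels' must be 3 or 4")
  if (!all(vapply(object@saLevels, is, logical(1), class2 = "SAConfig")))
    msg <- c(msg, "'saLevels' must be SAConfig objects")
  if (length(object@saLevels) < 1L)
    msg <- c(msg, "at least one set-abstraction level is required")
  last <- object@saLevels[[length(object@saLevels)]]
  if (!is.na(last@nCenter))
    msg <- c(msg, "the last set-abstraction level must group all points")
  if (length(object@saLevels) &&
      utils::tail(last@mlpWidths, 1) != object@head@dims[1])
    msg <- c(msg, "head input dim must equal the last MLP width")
  if (utils::tail(object@head@dims, 1) != object@nClasses)
    msg <- c(msg, "head output dim must equal 'nClasses'")
  if (length(msg)) msg else TRUE
})

#' RPNetModel: an instantiated network with weights
#'
#' @slot config the \code{RPNetConfig} the model was built from.
#' @slot params named list of weight/bias/normalization arrays.
#' @slot bnStats named list of batch-normalization running means/variances.
#' @slot riStandardize numeric(2) \code{c(center, scale)} applied to the RI
#'   channel before it enters the network (default (1.33, 0.07), mapping the
#'   physical RI range onto the coordinate scale).
#' @seealso [buildRPNet()], [rpnetForward()]
#' @export
setClass("RPNetModel",
  representation(config = "RPNetConfig", params = "list", bnStats = "list",
                 riStandardize = "numeric"))

#' TrainConfig: optimization-loop parameters
#'
#' @slot lr initial learning rate (default 0.001).
#' @slot weightDecay decoupled weight decay (default 0.0001).
#' @slot epochs training epochs (default 200).
#' @slot batchSize mini-batch size (default 16).
#' @slot labelSmoothing smoothing factor alpha (default 0.1).
#' @slot augmentProb per-transform augmentation probability (default 0.5).
#' @slot jitterSigma,jitterClip clipped Gaussian coordinate jitter parameters.
#' @slot riNoiseSigma Gaussian noise added to the RI channel.
#' @slot kfold folds for optional cross-validation (default 5).
#' @slot seed integer seed.
#' @seealso [trainRPNet()]
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric", epochs = "integer",
                 batchSize = "integer", labelSmoothing = "numeric",
                 augmentProb = "numeric", jitterSigma = "numeric",
                 jitterClip = "numeric", riNoiseSigma = "numeric",
                 kfold = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@labelSmoothing < 0 || object@labelSmoothing >= 1)
    msg <- c(msg, "'labelSmoothing' must be in [0, 1)")
  if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: multiclass evaluation summary
#'
#' @slot accuracy overall fraction correct.
#' @slot recall,precision,f1 macro-averaged metrics.
#' @slot perClassRecall,perClassPrecision,perClassF1 per-class values.
#' @slot auc per-class one-vs-rest AUC (\code{NA} for classes absent from
#'   the test set).
#' @slot meanAuc arithmetic mean of the defined per-class AUCs.
#' @slot confusion 3x3 integer confusion matrix, rows = truth.
#' @seealso [evaluateModel()], [metricsFromConfusion()]
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", recall = "numeric",
                 precision = "numeric", f1 = "numeric",
                 perClassRecall = "numeric", perClassPrecision = "numeric",
                 perClassF1 = "numeric", auc = "numeric", meanAuc = "numeric",
                 confusion = "matrix"))
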
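#' Accessors for RIPointNet containers
#'
#' Small accessor generics: \code{riGrid} returns the 3D RI array of a
#' \linkS4class{VoxelVolume}; \code{spacing} its voxel spacing in
#' micrometres; \code{foregroundMask} its logical mask (or \code{NULL});
#' \code{cellLabel} the class index of a volume or cloud; \code{coords} the
#' M x 3 coordinate matrix of an \linkS4class{RIPointCloud}; \code{riValues}
#' its RI channel; \code{nPoints} its cardinality; \code{isNormalized}
#' whether coordinates are unit-sphere normalized; \code{provenance} the
#' per-point sampler tag of a \linkS4class{TrainingPointSet}.
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases riGrid spacing foregroundMask cellLabel coords riValues nPoints
#'   isNormalized provenance
#' @examples
#' cl <- RIPointCloud(coords = cbind(0:2, 0, 0), ri = rep(1.34, 3))
#' nPoints(cl)
#' riValues(cl)
NULL

#' @rdname accessors
#' @export
setGeneric("riGrid", function(x) standardGeneric("riGrid"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("foregroundMask", function(x) standardGeneric("foregroundMask"))
#' @rdname accessors
#' @export
setGeneric("cellLabel", function(x) standardGeneric("cellLabel"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("riValues", function(x) standardGeneric("riValues"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
setMethod("riGrid", "VoxelVolume", function(x) x@ri)
#' @rdname accessors
setMethod("spacing", "VoxelVolume", function(x) {
  if (length(x@spacing) == 1L) rep(x@spacing, 3L) else x@spacing
})
#' @rdname accessors
setMethod("foregroundMask", "VoxelVolume", function(x) {
  if (length(x@mask)) x@mask else NULL
})
#' @rdname accessors
setMethod("cellLabel", "VoxelVolume", function(x) x@label)
#' @rdname accessors
setMethod("cellLabel", "RIPointCloud", function(x) x@label)
#' @rdname accessors
setMethod("coords", "RIPointCloud", function(x) x@coords)
#' @rdname accessors
setMethod("riValues", "RIPointCloud", function(x) x@ri)
#' @rdname accessors
setMethod("nPoints", "RIPointCloud", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("isNormalized", "RIPointCloud", function(x) x@normalized)
#' @rdname accessors
setMethod("provenance", "TrainingPointSet", function(x) x@provenance)

#' Construct a VoxelVolume
#'
#' @param ri 3D numeric array of RI values.
#' @param spacing micrometres per voxel (length 1 or 3).
#' @param mask optional logical array matching \code{ri}.
#' @param label optional class index in \code{0:2}.
#' @param metadata optional list.
#' @return a \linkS4class{VoxelVolume}.
#' @export
VoxelVolume <- function(ri, spacing = c(1, 1, 1), mask = NULL,
                        label = NA_integer_, metadata = list()) {
  if (is.null(mask)) mask <- array(logical(0), c(0, 0, 0))
  new("VoxelVolume", ri = ri,
      spacing = if (length(spacing) == 1L) rep(as.numeric(spacing), 3L)
                else as.numeric(spacing),
      mask = mask, label = as.integer(label), metadata = metadata)
}

#' Construct an RIPointCloud
#'
#' @param coords M x 3 numeric matrix (micrometres, or normalized).
#' @param ri numeric RI per point.
#' @param normalized whether coordinates are unit-sphere normalized.
#' @param label optional class index.
#' @return an \linkS4class{RIPointCloud}.
#' @export
RIPointCloud <- function(coords, ri, normalized = FALSE,
                         label = NA_integer_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  new("RIPointCloud", coords = coords, ri = as.numeric(ri),
      normalized = normalized, label = as.integer(label))
}

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@ri)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing (%s) um\n",
              d[1], d[2], d[3],
              paste(signif(spacing(object), 3), collapse = ", ")))
  if (!is.null(foregroundMask(object)))
    cat(sprintf("  foreground: %d voxels (%.1f%%)\n", sum(object@mask),
                100 * mean(object@mask)))
  if (length(object@ri))
    cat(sprintf("  RI range: [%.4f, %.4f]\n", min(object@ri), max(object@ri)))
  if (!is.na(object@label)) cat("  label:", object@label, "\n")
})

setMethod("show", "RIPointCloud", function(object) {
  cat(sprintf("%s: %d points%s%s\n", class(object), nPoints(object),
              if (object@normalized) ", unit-sphere normalized" else "",
              if (is.na(object@label)) "" else
                sprintf(", label %d", object@label)))
  if (nPoints(object))
    cat(sprintf("  RI range: [%.4f, %.4f]\n", min(object@ri), max(object@ri)))
  if (is(object, "TrainingPointSet") && length(object@provenance))
    cat(sprintf("  provenance: %d fps + %d riies\n",
                sum(object@provenance == "fps"),
                sum(object@provenance == "riies")))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  accuracy: %.4f  macro recall: %.4f  macro precision: %.4f  macro F1: %.4f\n",
              object@accuracy, object@recall, object@precision, object@f1))
  cat(sprintf("  AUC (one-vs-rest): %s  mean: %.4f\n",
              paste(sprintf("%.4f", object@auc), collapse = " / "),
              object@meanAuc))
  cat("  confusion (rows = truth):\n")
  print(object@confusion)
})

setMethod("show", "RPNetModel", function(object) {
  cat(sprintf("RPNetModel: %d-channel input, %d SA levels, %d classes\n",
              object@config@inputChannels, length(object@config@saLevels),
              object@config@nClasses))
  cat(sprintf("  trainable parameters: %s\n",
              format(modelParameterCount(object), big.mark = ",")))
})

# internal: run expr under a seed without touching the caller's RNG stream;
# seed NA/NULL means "use the ambient stream".
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
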
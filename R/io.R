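#' Read and write RI volumes as multi-page TIFF
#'
#' Volumes are stored as single-channel 32-bit float multi-page TIFF (one
#' page per z slice). Because the TIFF writer stores values in [0, 1], RI
#' is written as \code{ri - offset} with \code{offset = 1.0} (cell RI minus
#' one lies in [0.33, 0.40]); the offset, voxel spacing, label and
#' generation metadata travel in a JSON sidecar next to the image, and the
#' mask (when present) in a companion 8-bit \code{*_mask.tif}. The reader
#' reassembles the full \linkS4class{VoxelVolume}.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param path output TIFF path; sidecar and mask paths are derived.
#' @return \code{writeVolumeTIFF}: the main path, invisibly;
#'   \code{readVolumeTIFF}: a \linkS4class{VoxelVolume}.
#' @export
writeVolumeTIFF <- function(volume, path) {
  offset <- 1.0
  d <- dim(volume@ri)
  pages <- lapply(seq_len(d[3]), function(k) volume@ri[, , k] - offset)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(offset = offset, spacing = spacing(volume),
               dim = d, label = volume@label,
               metadata = volume@metadata)
  jsonlite::write_json(side, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(foregroundMask(volume))) {
    mPages <- lapply(seq_len(d[3]), function(k) volume@mask[, , k] * 1)
    tiff::writeTIFF(mPages, maskPath(path), bits.per.sample = 8L,
                    reduce = FALSE)
  }
  invisible(path)
}

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")
maskPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                  "_mask.tif")

#' @rdname writeVolumeTIFF
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  side <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  else list(offset = 1.0, spacing = c(1, 1, 1), label = NA_integer_,
            metadata = list())
  ri <- array(unlist(pages, use.names = FALSE), d) + side$offset
  mask <- NULL
  if (file.exists(maskPath(path))) {
    mPages <- tiff::readTIFF(maskPath(path), all = TRUE)
    mask <- array(unlist(mPages, use.names = FALSE) > 0.5, d)
  }
  VoxelVolume(ri, spacing = side$spacing, mask = mask,
              label = if (is.null(side$label)) NA_integer_
                      else as.integer(side$label),
              metadata = as.list(side$metadata))
}

#' Read and write RI point clouds as PLY or CSV
#'
#' PLY files are binary little-endian with float32 per-vertex properties
#' \code{x}, \code{y}, \code{z} (micrometres, or normalized) and
#' \code{refractive_index}; a \linkS4class{TrainingPointSet} adds a uint8
#' \code{provenance} property (0 = fps, 1 = riies). The CSV fallback has
#' header \code{x,y,z,n} (plus \code{provenance}).
#'
#' @param cloud an \linkS4class{RIPointCloud} or
#'   \linkS4class{TrainingPointSet}.
#' @param path file path.
#' @return writers return \code{path} invisibly; readers return the cloud
#'   (a \code{TrainingPointSet} when provenance is present).
#' @export
writeCloudPLY <- function(cloud, path) {
  m <- nPoints(cloud)
  hasProv <- is(cloud, "TrainingPointSet")
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment RIPointNet point cloud",
           sprintf("element vertex %d", m),
           "property float x", "property float y", "property float z",
           "property float refractive_index",
           if (hasProv) "property uchar provenance",
           "end_header")
  vals <- cbind(cloud@coords, cloud@ri)
  fRaw <- writeBin(as.vector(t(vals)), raw(), size = 4L,
                   endian = "little")
  body <- if (hasProv) {
    fm <- matrix(fRaw, nrow = 16L)
    as.vector(rbind(fm, as.raw(as.integer(cloud@provenance == "riies"))))
  } else fRaw
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con,
            eos = NULL)
  writeBin(body, con)
  invisible(path)
}

#' @rdname writeCloudPLY
#' @export
readCloudPLY <- function(path) {
  raw_ <- readBin(path, raw(), n = file.size(path))
  endPos <- grepRaw("end_header\n", raw_, fixed = TRUE)
  if (!length(endPos)) stop("not a PLY file: no end_header")
  hdr <- strsplit(rawToChar(raw_[seq_len(endPos - 1L)]), "\n")[[1]]
  if (!grepl("binary_little_endian", hdr[2]))
    stop("only binary little-endian PLY is supported")
  m <- as.integer(sub("element vertex ", "",
                      grep("^element vertex", hdr, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "",
               grep("^property", hdr, value = TRUE))
  need <- c("x", "y", "z", "refractive_index")
  if (!identical(props[seq_along(need)], need))
    stop("unexpected PLY vertex properties: ",
         paste(props, collapse = ", "))
  hasProv <- "provenance" %in% props
  body <- raw_[(endPos + 11L):length(raw_)]
  if (hasProv) {
    fm <- matrix(body[seq_len(17L * m)], nrow = 17L)
    vals <- readBin(as.vector(fm[1:16, ]), "numeric", n = 4L * m,
                    size = 4L, endian = "little")
    prov <- ifelse(as.integer(fm[17L, ]) == 1L, "riies", "fps")
  } else {
    vals <- readBin(body, "numeric", n = 4L * m, size = 4L,
                    endian = "little")
    prov <- NULL
  }
  vm <- matrix(vals, ncol = 4L, byrow = TRUE)
  cl <- RIPointCloud(vm[, 1:3, drop = FALSE], vm[, 4])
  if (hasProv)
    cl <- new("TrainingPointSet", coords = cl@coords, ri = cl@ri,
              normalized = FALSE, label = NA_integer_, provenance = prov)
  cl
}

#' @rdname writeCloudPLY
#' @export
writeCloudCSV <- function(cloud, path) {
  dt <- data.table::data.table(x = cloud@coords[, 1],
                               y = cloud@coords[, 2],
                               z = cloud@coords[, 3], n = cloud@ri)
  if (is(cloud, "TrainingPointSet")) dt$provenance <- cloud@provenance
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writeCloudPLY
#' @export
readCloudCSV <- function(path) {
  dt <- data.table::fread(path)
  cl <- RIPointCloud(as.matrix(dt[, c("x", "y", "z")]), dt$n)
  if ("provenance" %in% names(dt))
    cl <- new("TrainingPointSet", coords = cl@coords, ri = cl@ri,
              normalized = FALSE, label = NA_integer_,
              provenance = dt$provenance)
  cl
}
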
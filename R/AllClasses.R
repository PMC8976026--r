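#' @include AllGenerics.R
#' @import methods
NULL

#' 3-D intensity volume with anisotropic voxel spacing
#'
#' Container for a T1-weighted-like scalar volume. The grid is indexed
#' (x, y, z), 0-based in the underlying geometry, with z increasing from
#' inferior to superior. Voxel centres sit at \code{index * spacing}.
#'
#' @slot data 3-D numeric array of intensities (arbitrary units)
#' @slot spacing numeric(3), voxel size (dx, dy, dz) in mm, all > 0
#' @slot originZ mm offset of the first slice along z
#' @slot subjectID opaque subject identifier
#' @export
setClass("VolumeImage",
  representation(data = "array", spacing = "numeric", originZ = "numeric",
                 subjectID = "character"),
  prototype(spacing = c(1.25, 1.25, 6.0), originZ = 0, subjectID = ""))

setValidity("VolumeImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(dim(object@data)) == 3L && any(dim(object@data) < 1L))
    msg <- c(msg, "data dimensions must all be >= 1")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Three-class label map aligned to a volume
#'
#' Classes are coded 0 = background, 1 = subcutaneous adipose tissue (SAT),
#' 2 = visceral adipose tissue (VAT). The 8-bit file encoding
#' \{0, 255, 127\} exists only at the I/O boundary (see
#' \code{\link{encodeMask}}).
#'
#' @slot classes 3-D integer array with values in \{0, 1, 2\}
#' @slot spacing numeric(3), voxel size in mm
#' @export
setClass("LabelMap",
  representation(classes = "array", spacing = "numeric"),
  prototype(spacing = c(1.25, 1.25, 6.0)))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@classes)) != 3L)
    msg <- c(msg, "classes must be a 3-D array")
  if (!all(object@classes %in% 0:2))
    msg <- c(msg, "class values must be 0 (background), 1 (SAT) or 2 (VAT)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Ordered multi-station acquisition of one body volume
#'
#' Consecutive stations share \code{overlapSlices} axial slices, as in
#' multi-station whole-body MRI where a 1-3 slice overlap guards against
#' gaps between sequentially acquired 3-D volumes.
#'
#' @slot stations list of \linkS4class{VolumeImage}, ordered inferior to
#'   superior; all share in-plane dimensions and spacing
#' @slot overlapSlices integer, slices shared by consecutive stations (1-3)
#' @slot trueShifts optional (nStations-1) x 3 matrix of ground-truth
#'   translations (voxels) applied to stations 2..n, for validation
#' @export
setClass("StationSeries",
  representation(stations = "list", overlapSlices = "integer",
                 trueShifts = "ANY"),
  prototype(trueShifts = NULL))

setValidity("StationSeries", function(object) {
  msg <- character()
  if (length(object@stations) < 2L)
    msg <- c(msg, "a series needs at least 2 stations")
  if (!all(vapply(object@stations, is, logical(1), "VolumeImage")))
    msg <- c(msg, "stations must all be VolumeImage objects")
  if (object@overlapSlices < 1L || object@overlapSlices > 3L)
    msg <- c(msg, "overlapSlices must be between 1 and 3")
  if (length(object@stations) >= 2L) {
    d <- vapply(object@stations, function(s) dim(s@data)[1:2], integer(2))
    if (any(d != d[, 1]))
      msg <- c(msg, "stations must share in-plane dimensions")
  }
  if (!is.null(object@trueShifts) &&
      (!is.matrix(object@trueShifts) ||
       nrow(object@trueShifts) != length(object@stations) - 1L ||
       ncol(object@trueShifts) != 3L))
    msg <- c(msg, "trueShifts must be an (nStations-1) x 3 matrix or NULL")
  if (length(msg)) msg else TRUE
})

#' Result of translational station registration
#'
#' @slot shifts (nJunctions x 3) matrix of estimated (dx, dy, dz) voxel
#'   shifts of each inferior-to-superior junction (continuous)
#' @slot cost final mean-squared-difference per junction
#' @slot converged logical per junction
#' @slot nIterations simplex iterations per junction
#' @export
setClass("RegistrationResult",
  representation(shifts = "matrix", cost = "numeric", converged = "logical",
                 nIterations = "integer"))

#' A trained encoder-decoder segmentation network
#'
#' @slot params named list of weight matrices and bias vectors
#' @slot config network architecture configuration (see
#'   \code{\link{unetConfig}})
#' @slot trainConfig optimisation configuration used for training
#' @slot history data.frame with per-epoch columns epoch, loss, valLoss
#' @export
setClass("TrainedUNet",
  representation(params = "list", config = "list", trainConfig = "list",
                 history = "data.frame"))

setValidity("TrainedUNet", function(object) {
  msg <- character()
  if (nrow(object@history) > 0 && !all(is.finite(object@history$loss)))
    msg <- c(msg, "training losses must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn VolumeImage constructor
#' @param data 3-D numeric array
#' @param spacing numeric(3) voxel size in mm
#' @param originZ z offset in mm of the first slice
#' @param subjectID subject identifier
#' @export
VolumeImage <- function(data, spacing = c(1.25, 1.25, 6.0), originZ = 0,
                        subjectID = "") {
  storage.mode(data) <- "double"
  new("VolumeImage", data = data, spacing = as.numeric(spacing),
      originZ = as.numeric(originZ), subjectID = as.character(subjectID))
}

#' @describeIn LabelMap constructor
#' @param classes 3-D array with values in \{0, 1, 2\}; a 2-D matrix is
#'   promoted to a single-slice volume
#' @param spacing numeric(3) voxel size in mm
#' @export
LabelMap <- function(classes, spacing = c(1.25, 1.25, 6.0)) {
  if (is.matrix(classes)) dim(classes) <- c(dim(classes), 1L)
  storage.mode(classes) <- "integer"
  new("LabelMap", classes = classes, spacing = as.numeric(spacing))
}

#' @describeIn StationSeries constructor
#' @param stations list of \linkS4class{VolumeImage}
#' @param overlapSlices shared slices per junction (1-3)
#' @param trueShifts optional ground-truth shift matrix
#' @export
StationSeries <- function(stations, overlapSlices, trueShifts = NULL) {
  new("StationSeries", stations = stations,
      overlapSlices = as.integer(overlapSlices), trueShifts = trueShifts)
}

setMethod("spacing", "VolumeImage", function(x) x@spacing)
setMethod("spacing", "LabelMap", function(x) x@spacing)
setMethod("imgData", "VolumeImage", function(x) x@data)
setMethod("classGrid", "LabelMap", function(x) x@classes)
setMethod("subjectID", "VolumeImage", function(x) x@subjectID)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage '%s': %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              object@subjectID, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@classes)
  n <- tabulate(object@classes + 1L, 3L)
  cat(sprintf("LabelMap: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  background %d | SAT %d | VAT %d voxels\n", n[1], n[2], n[3]))
})

setMethod("show", "StationSeries", function(object) {
  nz <- vapply(object@stations, function(s) dim(s@data)[3], integer(1))
  cat(sprintf("StationSeries: %d stations (%s slices), overlap %d\n",
              length(object@stations), paste(nz, collapse = "+"),
              object@overlapSlices))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: %d junction(s)\n", nrow(object@shifts)))
  for (j in seq_len(nrow(object@shifts)))
    cat(sprintf("  junction %d: shift (%.3f, %.3f, %.3f) vox, cost %.4g, %s\n",
                j, object@shifts[j, 1], object@shifts[j, 2],
                object@shifts[j, 3], object@cost[j],
                if (object@converged[j]) "converged" else "NOT converged"))
})

setMethod("show", "TrainedUNet", function(object) {
  cat(sprintf("TrainedUNet: input %dx%d, encoder channels %s, %d epochs\n",
              object@config$inputSize[1], object@config$inputSize[2],
              paste(object@config$encoderChannels, collapse = "/"),
              nrow(object@history)))
  if (nrow(object@history) > 0)
    cat(sprintf("  final loss %.5f (val %.5f)\n",
                utils::tail(object@history$loss, 1),
                utils::tail(object@history$valLoss, 1)))
})
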
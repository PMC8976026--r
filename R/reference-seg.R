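#' @include AllClasses.R AllGenerics.R preprocess.R
NULL

#' Estimate the fat intensity range from the body histogram
#'
#' T1-weighted fat is the hyperintense tissue class, so the intensity
#' histogram inside the body is bimodal (organ mode below, fat mode
#' above). The upper mode is located on a kernel density estimate and the
#' range \code{[mode - k * (mode - valley), max]} is returned, where the
#' valley is the density minimum between the two modes.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param mask logical body mask (see \code{\link{bodyMask}})
#' @param k width multiplier on the mode-to-valley distance (default 0.5)
#' @param minPeakFrac peaks below this fraction of the tallest peak are
#'   ignored as noise
#' @return list with elements \code{lo}, \code{hi} (class
#'   \code{FatIntensityRange})
#' @export
estimateFatRange <- function(v, mask, k = 0.5, minPeakFrac = 0.05) {
  stopifnot(is(v, "VolumeImage"))
  if (!any(mask)) stop("body mask is empty")
  x <- v@data[mask]
  d <- stats::density(x, n = 512)
  yc <- d$y
  isPeak <- c(FALSE, diff(sign(diff(yc))) < 0, FALSE)
  peaks <- which(isPeak & yc >= minPeakFrac * max(yc))
  if (length(peaks) < 2L)
    stop("intensity histogram has no resolvable fat mode; ",
         "specify the fat range manually")
  fatIdx <- peaks[length(peaks)]
  prevIdx <- peaks[length(peaks) - 1L]
  valleyIdx <- prevIdx + which.min(yc[prevIdx:fatIdx]) - 1L
  mode <- d$x[fatIdx]
  valley <- d$x[valleyIdx]
  lo <- mode - k * (mode - valley)
  r <- list(lo = lo, hi = max(x))
  if (r$lo >= r$hi) stop("degenerate fat range")
  class(r) <- "FatIntensityRange"
  r
}

# per-slice erosion by a disc of the given voxel radius
.erodeSlices <- function(mask, radius) {
  if (radius < 1) return(mask)
  side <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  .sliceApply(mask, function(sl) EBImage::erode(sl, brush) > 0)
}

.dilateSlices <- function(mask, radius) {
  if (radius < 1) return(mask)
  side <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  .sliceApply(mask, function(sl) EBImage::dilate(sl, brush) > 0)
}

#' Segment subcutaneous fat by surface-connected intensity selection
#'
#' Selects voxels within the fat intensity range that lie in the
#' morphological band between the body surface and the eroded body
#' interior and whose 26-connected component touches the body boundary
#' layer - i.e. bright fat contiguous with the body surface.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param mask logical body mask
#' @param range a \code{FatIntensityRange}
#' @param bandWidthMM width of the subcutaneous search band in mm
#' @return logical 3-D SAT mask (empty, with a warning, if nothing is in
#'   range)
#' @export
segmentSAT <- function(v, mask, range, bandWidthMM = 30) {
  stopifnot(is(v, "VolumeImage"))
  if (range$lo >= range$hi) stop("invalid fat range")
  dx <- v@spacing[1]
  band <- mask & !.erodeSlices(mask, round(bandWidthMM / dx))
  boundary <- mask & !.erodeSlices(mask, 1)
  cand <- band & v@data >= range$lo & v@data <= range$hi
  if (!any(cand)) {
    warning("no voxels in the fat range within the subcutaneous band")
    return(array(FALSE, dim(v@data)))
  }
  labs <- .cpp_label3d(cand, 26L)
  keep <- unique(labs[cand & boundary])
  keep <- keep[keep > 0]
  out <- array(labs %in% keep & cand, dim(v@data))
  if (!any(out))
    warning("no surface-connected fat component found; empty SAT mask")
  out
}

#' Segment visceral fat by range-connected voxel selection
#'
#' Inside the abdominal cavity (body interior minus the subcutaneous band
#' and a one-voxel guard around the SAT mask), voxels within the fat
#' range are grouped by 26-connectivity and components below the minimum
#' size are dropped. Bright bone rims inside the cavity fall in the fat
#' range and are deliberately not excluded, reproducing the hip-bone
#' failure mode of intensity-driven VAT segmentation.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param mask logical body mask
#' @param satMask logical SAT mask from \code{\link{segmentSAT}}
#' @param range a \code{FatIntensityRange}
#' @param minComponentSize smallest retained 26-connected component
#'   (voxels)
#' @return logical 3-D VAT mask, disjoint from \code{satMask}
#' @export
segmentVAT <- function(v, mask, satMask, range, minComponentSize = 5L) {
  stopifnot(is(v, "VolumeImage"))
  cavity <- .erodeSlices(mask, 2) & !.dilateSlices(satMask, 1)
  cand <- cavity & v@data >= range$lo & v@data <= range$hi
  if (!any(cand)) return(array(FALSE, dim(v@data)))
  labs <- .cpp_label3d(cand, 26L)
  counts <- tabulate(labs[labs > 0])
  keep <- which(counts >= minComponentSize)
  array(labs %in% keep & cand, dim(v@data))
}

#' Full reference segmentation of a preprocessed volume
#'
#' Composes \code{\link{bodyMask}}, \code{\link{estimateFatRange}},
#' \code{\link{segmentSAT}} and \code{\link{segmentVAT}} into a 3-class
#' label map. This is the package's intensity-range/connectivity
#' reference method, the fully automatic counterpart of semi-automatic
#' histogram/region-growing protocols.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param thresholdQuantile body-mask threshold quantile
#' @param fatRange optional \code{FatIntensityRange} overriding the
#'   histogram estimate
#' @param bandWidthMM subcutaneous band width in mm
#' @param minComponentSize minimum VAT component size in voxels
#' @return a \linkS4class{LabelMap}
#' @export
referenceSegment <- function(v, thresholdQuantile = 0.6, fatRange = NULL,
                             bandWidthMM = 30, minComponentSize = 5L) {
  mask <- bodyMask(v, thresholdQuantile)
  r <- if (is.null(fatRange)) estimateFatRange(v, mask) else fatRange
  sat <- segmentSAT(v, mask, r, bandWidthMM = bandWidthMM)
  vat <- segmentVAT(v, mask, sat, r, minComponentSize = minComponentSize)
  cls <- array(0L, dim(v@data))
  cls[sat] <- 1L
  cls[vat] <- 2L
  LabelMap(cls, v@spacing)
}
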
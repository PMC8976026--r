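#' @include AllClasses.R AllGenerics.R
NULL

# File values of the three classes in 8-bit mask images. Internal class
# integers are contiguous {0,1,2} so the softmax head can index them; the
# {0,255,127} coding exists only in files.
.MASK_CODES <- c(`0` = 0L, `1` = 255L, `2` = 127L)

#' Read a NIfTI-1 volume
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file
#' @param subjectID optional subject identifier to attach
#' @return a \linkS4class{VolumeImage}; intensities are unchanged and the
#'   voxel spacing is taken from the header
#' @export
readVolume <- function(path, subjectID = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(a)), "-D: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  attributes(a) <- list(dim = dim(a))
  VolumeImage(a, spacing = sp, subjectID = subjectID)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 64-bit float so the roundtrip through
#' \code{\link{readVolume}} is bit-exact.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param path output path (\code{.nii} or \code{.nii.gz})
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "VolumeImage"))
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 3-class label map stored as NIfTI-1
#'
#' @param path path to the file
#' @return a \linkS4class{LabelMap}
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3-D label volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  attributes(a) <- list(dim = dim(a))
  bad <- setdiff(unique(as.vector(a)), 0:2)
  if (length(bad))
    stop("label file contains values outside {0,1,2}: ",
         paste(bad, collapse = ", "))
  LabelMap(a, spacing = sp)
}

#' Write a 3-class label map as NIfTI-1
#'
#' @param m a \linkS4class{LabelMap}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeLabelMap <- function(m, path) {
  stopifnot(is(m, "LabelMap"))
  img <- RNifti::asNifti(m@classes)
  RNifti::pixdim(img) <- m@spacing
  RNifti::writeNifti(img, path, datatype = "short")
  invisible(path)
}

#' Encode a label slice to the 8-bit mask convention
#'
#' Maps class 0 (background) to pixel value 0, class 1 (SAT) to 255 and
#' class 2 (VAT) to 127, the coding used for per-slice mask images.
#'
#' @param m integer matrix (one axial slice) with values in \{0, 1, 2\}
#' @return integer matrix of 8-bit pixel values in \{0, 255, 127\}
#' @export
encodeMask <- function(m) {
  if (is(m, "LabelMap")) {
    if (dim(m@classes)[3] != 1L)
      stop("encodeMask works on a single slice; subset the LabelMap first")
    m <- m@classes[, , 1]
  }
  bad <- setdiff(unique(as.vector(m)), 0:2)
  if (length(bad))
    stop("cannot encode class values outside {0,1,2}: ",
         paste(bad, collapse = ", "))
  out <- matrix(.MASK_CODES[as.character(m)], nrow(m), ncol(m))
  storage.mode(out) <- "integer"
  out
}

#' Decode an 8-bit mask image to class labels
#'
#' Inverse of \code{\link{encodeMask}}: 0 -> background, 255 -> SAT,
#' 127 -> VAT. Any other pixel value is rejected.
#'
#' @param img integer matrix of 8-bit pixel values
#' @return integer matrix with values in \{0, 1, 2\}
#' @export
decodeMask <- function(img) {
  bad <- setdiff(unique(as.vector(img)), c(0L, 127L, 255L))
  if (length(bad))
    stop("mask image contains invalid pixel value(s): ",
         paste(bad, collapse = ", "),
         " (expected 0, 127 or 255)")
  out <- matrix(0L, nrow(img), ncol(img))
  out[img == 255L] <- 1L
  out[img == 127L] <- 2L
  out
}

#' Write a mask slice as lossless 8-bit grayscale PNG
#'
#' @param m integer matrix with class values in \{0, 1, 2\}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMaskPNG <- function(m, path) {
  enc <- encodeMask(m)
  png::writePNG(enc / 255, path)
  invisible(path)
}

#' Read a mask slice from an 8-bit grayscale PNG
#'
#' @param path path to the PNG
#' @return integer matrix with class values in \{0, 1, 2\}
#' @export
readMaskPNG <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  decodeMask(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)))
}

#' Write a per-group segmentation metrics table as CSV
#'
#' One row per (group, compartment, metric) combination with mean, SD and
#' the number of contributing slices.
#'
#' @param rows data.frame with columns group, compartment, metric, mean,
#'   sd, n
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeMetricsTable <- function(rows, path) {
  need <- c("group", "compartment", "metric", "mean", "sd", "n")
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("metrics table must be a non-empty data.frame")
  if (!all(need %in% names(rows)))
    stop("metrics table needs columns: ", paste(need, collapse = ", "))
  utils::write.csv(rows[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by \code{\link{writeMetricsTable}}
#'
#' @param path CSV path
#' @return data.frame
#' @export
readMetricsTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort manifest as JSON
#'
#' @param manifest data.frame with one row per subject (subjectID, group,
#'   age, bmi, file paths, split)
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeCohortManifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest))
  if (anyDuplicated(manifest$subjectID))
    stop("subject IDs must be unique")
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest written by \code{\link{writeCohortManifest}}
#'
#' @param path JSON path
#' @return data.frame
#' @export
readCohortManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- jsonlite::fromJSON(path)
  if (anyDuplicated(m$subjectID)) stop("subject IDs must be unique")
  m
}
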
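NULL

#' Voxel spacing of an image-like object
#'
#' @param x a \linkS4class{VolumeImage} or \linkS4class{LabelMap}
#' @return numeric vector \code{c(dx, dy, dz)} in millimetres
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Intensity grid of a volume
#'
#' @param x a \linkS4class{VolumeImage}
#' @return the 3-D numeric array, indexed (x, y, z)
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Class grid of a label map
#'
#' @param x a \linkS4class{LabelMap}
#' @return 3-D integer array with values 0 (background), 1 (SAT), 2 (VAT)
#' @export
setGeneric("classGrid", function(x) standardGeneric("classGrid"))

#' Subject identifier
#'
#' @param x a \linkS4class{VolumeImage}
#' @return character scalar
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' Resample a volume onto an isotropic grid
#'
#' @param x object to resample
#' @param targetSpacing numeric(3), target voxel size in mm
#' @param ... further arguments for methods
#' @export
setGeneric("supersample", function(x, targetSpacing = c(1.2, 1.2, 1.2), ...)
  standardGeneric("supersample"))
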
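#' @include AllClasses.R AllGenerics.R
NULL

# Mean squared intensity difference between the fixed overlap slices of
# station A and the candidate-shifted leading slices of station B.
# Slices that the candidate z-shift pushes outside B's extent are excluded;
# an empty comparison domain is penalised.
.junctionCost <- function(Aov, Bsub, shift, bound) {
  ov <- dim(Aov)[3]
  nzB <- dim(Bsub)[3]
  pen <- sum(pmax(0, abs(shift) - bound)^2) * 1e6
  ks <- seq_len(ov)
  valid <- ks + shift[3] >= 1 & ks + shift[3] <= nzB
  if (!any(valid)) return(1e12 + pen)
  corrected <- .cpp_shift_volume(Bsub, -as.numeric(shift), FALSE)
  mean((Aov[, , valid, drop = FALSE] -
          corrected[, , ks[valid], drop = FALSE])^2) + pen
}

#' Register consecutive stations by 3-DOF translation
#'
#' For each junction the translational shift (dx, dy, dz) of the superior
#' station relative to the inferior one is estimated by minimising the
#' mean squared intensity difference over the shared overlap slices with a
#' restarted Nelder-Mead simplex (3 degrees of freedom, trilinear
#' interpolation for fractional shifts).
#'
#' @param series a \linkS4class{StationSeries}
#' @param searchBound voxel bound on each shift component (default 3)
#' @param seed RNG seed for the perturbed restart points
#' @param restarts number of perturbed restarts after the zero start
#' @param maxit simplex iteration cap per start
#' @return a \linkS4class{RegistrationResult} with one row of shifts per
#'   junction (the estimated motion of the superior station; apply the
#'   negated shift to undo it)
#' @export
registerStations <- function(series, searchBound = 3, seed = 1,
                             restarts = 2, maxit = 300) {
  stopifnot(is(series, "StationSeries"))
  ov <- series@overlapSlices
  if (ov < 1L) stop("stations must share at least one overlap slice")
  n <- length(series@stations)
  shifts <- matrix(NA_real_, n - 1L, 3L)
  cost <- numeric(n - 1L)
  conv <- logical(n - 1L)
  iters <- integer(n - 1L)
  perturb <- .withSeed(seed, {
    matrix(stats::runif(3 * restarts, -0.75, 0.75), restarts, 3)
  })
  for (j in seq_len(n - 1L)) {
    A <- series@stations[[j]]@data
    B <- series@stations[[j + 1L]]@data
    sA <- dim(A)[3]
    Aov <- A[, , (sA - ov + 1L):sA, drop = FALSE]
    Bsub <- B[, , seq_len(min(dim(B)[3], ov + ceiling(searchBound) + 1L)),
              drop = FALSE]
    # coarse integer-shift scan to place the simplex in the right basin
    # (the z cost profile is multi-modal at 1-3 overlap slices)
    grid <- as.matrix(expand.grid(dx = -searchBound:searchBound,
                                  dy = -searchBound:searchBound,
                                  dz = -searchBound:searchBound))
    gc_ <- apply(grid, 1L, function(p) .junctionCost(Aov, Bsub, p,
                                                     searchBound))
    coarse <- grid[which.min(gc_), ]
    starts <- rbind(coarse, sweep(perturb, 2L, coarse, "+"))
    best <- NULL
    totIt <- 0L
    for (r in seq_len(nrow(starts))) {
      fit <- stats::optim(starts[r, ],
                          function(p) .junctionCost(Aov, Bsub, p, searchBound),
                          method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      totIt <- totIt + fit$counts[["function"]]
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    shifts[j, ] <- best$par
    cost[j] <- best$value
    conv[j] <- best$convergence == 0
    iters[j] <- totIt
  }
  new("RegistrationResult", shifts = shifts, cost = cost, converged = conv,
      nIterations = iters)
}

#' Merge registered stations into one contiguous volume
#'
#' Each station after the first is resampled by the negated cumulative
#' estimated shift (undoing the inter-station motion), then the stations
#' are concatenated; within each overlap the superior station's slices are
#' kept (no blending, configurable via \code{blend}). The merged z-extent
#' is the sum of station extents minus the overlaps.
#'
#' @param series a \linkS4class{StationSeries}
#' @param reg a \linkS4class{RegistrationResult} covering every junction
#' @param blend \code{"superior"} (default: superior station wins in the
#'   overlap) or \code{"average"}
#' @return the merged \linkS4class{VolumeImage}
#' @export
mergeStations <- function(series, reg, blend = c("superior", "average")) {
  stopifnot(is(series, "StationSeries"), is(reg, "RegistrationResult"))
  blend <- match.arg(blend)
  n <- length(series@stations)
  if (nrow(reg@shifts) != n - 1L)
    stop("registration must cover every junction (", n - 1L, " needed)")
  ov <- series@overlapSlices
  dimsXY <- dim(series@stations[[1L]]@data)[1:2]
  corrected <- vector("list", n)
  corrected[[1L]] <- series@stations[[1L]]@data
  cum <- c(0, 0, 0)
  for (i in 2:n) {
    cum <- cum + reg@shifts[i - 1L, ]
    corrected[[i]] <- .cpp_shift_volume(series@stations[[i]]@data,
                                        -as.numeric(cum), FALSE)
  }
  sizes <- vapply(corrected, function(a) dim(a)[3], integer(1))
  outZ <- sum(sizes) - (n - 1L) * ov
  out <- array(0, c(dimsXY, outZ))
  pos <- sizes[1L]
  out[, , seq_len(pos)] <- corrected[[1L]]
  for (i in 2:n) {
    a <- corrected[[i]]
    ovIdx <- (pos - ov + 1L):pos
    out[, , ovIdx] <- if (blend == "superior") a[, , seq_len(ov), drop = FALSE]
      else (out[, , ovIdx, drop = FALSE] + a[, , seq_len(ov), drop = FALSE]) / 2
    fresh <- sizes[i] - ov
    out[, , pos + seq_len(fresh)] <- a[, , ov + seq_len(fresh), drop = FALSE]
    pos <- pos + fresh
  }
  stopifnot(all(is.finite(out)))
  VolumeImage(out, series@stations[[1L]]@spacing,
              originZ = series@stations[[1L]]@originZ,
              subjectID = series@stations[[1L]]@subjectID)
}

#' @describeIn supersample trilinear resampling of an intensity volume
#'   onto an isotropic grid (default 1.2 mm); output dimensions are
#'   \code{round(dim * spacing / target)}
#' @export
setMethod("supersample", "VolumeImage", function(x,
    targetSpacing = c(1.2, 1.2, 1.2), ...) {
  if (any(targetSpacing <= 0)) stop("target spacing must be positive")
  d <- dim(x@data)
  if (any(d < 1)) stop("degenerate input dimensions")
  outDims <- pmax(1L, as.integer(round(d * x@spacing / targetSpacing)))
  out <- .cpp_resample(x@data, x@spacing, outDims, targetSpacing, FALSE)
  VolumeImage(out, targetSpacing, originZ = x@originZ,
              subjectID = x@subjectID)
})

#' @describeIn supersample nearest-neighbour resampling of a label map
#'   (labels must remain in \{0,1,2\})
#' @export
setMethod("supersample", "LabelMap", function(x,
    targetSpacing = c(1.2, 1.2, 1.2), ...) {
  if (any(targetSpacing <= 0)) stop("target spacing must be positive")
  d <- dim(x@classes)
  outDims <- pmax(1L, as.integer(round(d * x@spacing / targetSpacing)))
  a <- x@classes
  storage.mode(a) <- "double"
  out <- .cpp_resample(a, x@spacing, outDims, targetSpacing, TRUE)
  storage.mode(out) <- "integer"
  LabelMap(out, targetSpacing)
})

#' 3-D median filter to homogenise intensities
#'
#' Voxelwise median within an odd cubic kernel (default 3x3x3), with
#' reflected boundaries.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param kernel odd kernel side length
#' @return the filtered \linkS4class{VolumeImage}, same dimensions
#' @export
medianFilterVolume <- function(v, kernel = 3L) {
  stopifnot(is(v, "VolumeImage"))
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L) stop("kernel side must be odd")
  VolumeImage(.cpp_median_filter3(v@data, kernel), v@spacing,
              originZ = v@originZ, subjectID = v@subjectID)
}

# per-slice binary morphology helpers (EBImage)
.sliceApply <- function(mask, f) {
  for (k in seq_len(dim(mask)[3])) mask[, , k] <- f(mask[, , k])
  mask
}

#' Extract the body mask of a volume
#'
#' Thresholds the volume at an intensity quantile, keeps the largest
#' connected component of each axial slice (removing disconnected lateral
#' structures such as partially imaged arms) and fills interior holes, so
#' the mask covers the full body cross-section including dark organs.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param thresholdQuantile intensity quantile used as threshold
#' @return logical 3-D array, TRUE inside the body
#' @export
bodyMask <- function(v, thresholdQuantile = 0.6) {
  stopifnot(is(v, "VolumeImage"))
  th <- stats::quantile(v@data, thresholdQuantile, names = FALSE)
  fg <- v@data > th
  if (!any(fg)) stop("empty foreground at quantile ", thresholdQuantile)
  fg <- .sliceApply(fg, function(sl) {
    if (!any(sl)) return(sl)
    labs <- EBImage::bwlabel(sl)
    counts <- tabulate(labs[labs > 0])
    big <- which.max(counts)
    EBImage::fillHull(labs == big) > 0
  })
  if (!any(fg)) stop("empty body mask")
  storage.mode(fg) <- "logical"
  fg
}
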
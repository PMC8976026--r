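#' @include AllClasses.R
NULL

#' Dice similarity coefficient
#'
#' \code{2 * |R intersect P| / (|R| + |P|)} between a reference and a
#' predicted binary mask. When both masks are empty the score is
#' undefined and \code{NA} is returned; aggregation excludes such slices
#' (see \code{\link{evaluateExamination}}).
#'
#' @param R,P logical arrays/matrices of identical dimensions
#' @return value in [0, 1], or \code{NA} if both masks are empty
#' @export
diceCoefficient <- function(R, P) {
  if (!identical(dim(R), dim(P)))
    stop("mask dimensions differ: ", paste(dim(R), collapse = "x"), " vs ",
         paste(dim(P), collapse = "x"))
  denom <- sum(R) + sum(P)
  if (denom == 0) return(NA_real_)
  2 * sum(R & P) / denom
}

#' Pixel error percentage
#'
#' The fraction of image pixels on which reference and prediction
#' disagree (the symmetric difference of the two masks), relative to the
#' image size, in percent.
#'
#' @param R,P logical arrays/matrices of identical dimensions
#' @return percentage in [0, 100]
#' @export
pixelError <- function(R, P) {
  if (!identical(dim(R), dim(P)))
    stop("mask dimensions differ: ", paste(dim(R), collapse = "x"), " vs ",
         paste(dim(P), collapse = "x"))
  100 * sum(xor(R, P)) / length(R)
}

#' Per-slice, per-class evaluation of one examination
#'
#' For every axial slice and each fat class (SAT, VAT), computes the Dice
#' coefficient and pixel error between the class-restricted binary masks
#' of a reference and a predicted label map. Slices where both masks are
#' empty for a class carry an undefined Dice and are excluded from that
#' class's averages.
#'
#' @param ref,pred \linkS4class{LabelMap}s on the same grid
#' @param excludeEmpty drop empty-vs-empty slices per class (default);
#'   set FALSE to score them as Dice 1
#' @return data.frame with columns slice, compartment, dice, pixelError
#' @export
evaluateExamination <- function(ref, pred, excludeEmpty = TRUE) {
  stopifnot(is(ref, "LabelMap"), is(pred, "LabelMap"))
  if (!identical(dim(ref@classes), dim(pred@classes)))
    stop("label map dimensions differ")
  nz <- dim(ref@classes)[3]
  rows <- vector("list", 2L * nz)
  i <- 0L
  for (k in seq_len(nz)) {
    rs <- ref@classes[, , k]
    ps <- pred@classes[, , k]
    for (cls in 1:2) {
      R <- rs == cls
      P <- ps == cls
      d <- diceCoefficient(R, P)
      if (is.na(d) && !excludeEmpty) d <- 1.0
      i <- i + 1L
      rows[[i]] <- data.frame(slice = k,
                              compartment = c("SAT", "VAT")[cls],
                              dice = d, pixelError = pixelError(R, P),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (excludeEmpty) out <- out[!is.na(out$dice), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-slice metrics across examinations into group summaries
#'
#' Pools all slices of all examinations per group and fat compartment and
#' reports mean and SD of Dice and pixel error, the layout used for
#' per-group network-performance tables.
#'
#' @param examinations list of data.frames from
#'   \code{\link{evaluateExamination}}, one per examination
#' @param groups character vector of group labels, one per examination
#' @return data.frame with columns group, compartment, metric, mean, sd, n
#' @export
aggregateGroupMetrics <- function(examinations, groups) {
  if (length(examinations) == 0) stop("no examinations to aggregate")
  if (length(groups) != length(examinations))
    stop("need one group label per examination")
  pooled <- do.call(rbind, Map(function(df, g) {
    df$group <- g
    df
  }, examinations, groups))
  if (any(!table(pooled$group) > 0)) stop("empty group")
  rows <- list()
  for (g in unique(groups)) for (cmp in c("SAT", "VAT")) {
    sub <- pooled[pooled$group == g & pooled$compartment == cmp, ]
    for (m in c("dice", "pixelError")) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, compartment = cmp, metric = m,
        mean = mean(v), sd = stats::sd(v), n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volumetric Dice per class for one examination
#'
#' A single Dice over all voxels of the volume per class, the secondary
#' companion to the per-slice averages.
#'
#' @param ref,pred \linkS4class{LabelMap}s on the same grid
#' @return named numeric vector with elements SAT, VAT
#' @export
volumetricDice <- function(ref, pred) {
  stopifnot(is(ref, "LabelMap"), is(pred, "LabelMap"))
  c(SAT = diceCoefficient(ref@classes == 1L, pred@classes == 1L),
    VAT = diceCoefficient(ref@classes == 2L, pred@classes == 2L))
}
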
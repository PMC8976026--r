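#' @include AllClasses.R metrics.R
NULL

#' Volumetric fat quantification of a label map
#'
#' Voxelwise volumetry: each class volume is the voxel count times the
#' voxel volume \code{dx * dy * dz} in cubic millimetres, reported in
#' millilitres, plus the VAT/SAT ratio where defined.
#'
#' @param m a \linkS4class{LabelMap}
#' @param subjectID,source bookkeeping columns for downstream tables;
#'   \code{source} is one of \code{"reference"}, \code{"predicted"},
#'   \code{"ground_truth"}
#' @return one-row data.frame with columns subjectID, source, sat_ml,
#'   vat_ml, ratio (NA when SAT volume is zero)
#' @export
fatVolumes <- function(m, subjectID = "", source = "predicted") {
  stopifnot(is(m, "LabelMap"))
  if (any(m@spacing <= 0)) stop("label map has no valid voxel spacing")
  voxML <- prod(m@spacing) / 1000
  n <- tabulate(m@classes + 1L, 3L)
  sat <- n[2] * voxML
  vat <- n[3] * voxML
  data.frame(subjectID = subjectID, source = source,
             sat_ml = sat, vat_ml = vat,
             ratio = if (sat > 0) vat / sat else NA_real_,
             stringsAsFactors = FALSE)
}

#' VAT/SAT volume ratio
#'
#' @param f a one-row data.frame from \code{\link{fatVolumes}}, or any
#'   list with elements \code{sat_ml} and \code{vat_ml}
#' @return the ratio \code{vat_ml / sat_ml}
#' @export
vatSatRatio <- function(f) {
  if (f$sat_ml <= 0)
    stop("VAT/SAT ratio undefined: SAT volume is zero")
  f$vat_ml / f$sat_ml
}

#' Two-tailed two-sample Student's t-test
#'
#' Classical equal-variance Student's t-test (Welch's correction behind a
#' flag); group differences at p < 0.05 are conventionally called
#' significant.
#'
#' @param a,b numeric samples, each of length >= 2
#' @param welch use Welch's unequal-variance form
#' @return list with t, df, p, per-group mean, SEM (= SD/sqrt(n)) and n
#' @export
tTestTwoTailed <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance; t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       meanA = mean(a), meanB = mean(b),
       semA = stats::sd(a) / sqrt(length(a)),
       semB = stats::sd(b) / sqrt(length(b)),
       nA = length(a), nB = length(b))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant
#' @return the sample correlation r
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Cohort-level fat quantification report
#'
#' For every test subject with both a predicted and a reference label
#' map, computes SAT/VAT volumes from each source, the per-group Pearson
#' correlation between predicted and reference volumes (SAT and VAT
#' separately), and the between-group comparison of the VAT/SAT ratio
#' with a two-tailed Student's t-test.
#'
#' @param manifest data.frame with columns subjectID and group
#' @param predMaps,refMaps named lists of \linkS4class{LabelMap}s keyed by
#'   subjectID
#' @param ratioSource which source's ratios enter the group comparison
#' @return list with elements \code{volumes} (per subject x source),
#'   \code{correlations} (per group x compartment), \code{ratioStats}
#'   (t-test result plus per-group mean/SEM), \code{excluded}
#' @export
cohortReport <- function(manifest, predMaps, refMaps,
                         ratioSource = c("predicted", "reference")) {
  ratioSource <- match.arg(ratioSource)
  ids <- manifest$subjectID
  missing <- ids[!(ids %in% names(predMaps)) | !(ids %in% names(refMaps))]
  if (length(missing)) {
    warning("excluding subjects without both map sources: ",
            paste(missing, collapse = ", "))
    manifest <- manifest[!manifest$subjectID %in% missing, , drop = FALSE]
  }
  if (nrow(manifest) == 0) stop("no subjects with complete data")
  vols <- do.call(rbind, lapply(manifest$subjectID, function(id) {
    rbind(fatVolumes(predMaps[[id]], id, "predicted"),
          fatVolumes(refMaps[[id]], id, "reference"))
  }))
  vols <- merge(vols, manifest[, c("subjectID", "group")], by = "subjectID")

  corRows <- list()
  for (g in unique(manifest$group)) {
    sub <- vols[vols$group == g, ]
    p <- sub[sub$source == "predicted", ]
    r <- sub[sub$source == "reference", ]
    p <- p[match(r$subjectID, p$subjectID), ]
    for (cmp in c("SAT", "VAT")) {
      col <- if (cmp == "SAT") "sat_ml" else "vat_ml"
      rr <- tryCatch(pearsonR(r[[col]], p[[col]]), error = function(e) NA_real_)
      corRows[[length(corRows) + 1L]] <- data.frame(
        group = g, compartment = cmp, r = rr, n = nrow(r),
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corRows)

  src <- vols[vols$source == ratioSource & !is.na(vols$ratio), ]
  grp <- unique(manifest$group)
  ratioStats <- NULL
  if (length(grp) == 2) {
    a <- src$ratio[src$group == grp[1]]
    b <- src$ratio[src$group == grp[2]]
    ratioStats <- tryCatch(
      c(tTestTwoTailed(a, b),
        list(groupA = grp[1], groupB = grp[2], source = ratioSource)),
      error = function(e) {
        warning("group comparison not possible: ", conditionMessage(e))
        list(error = conditionMessage(e), groupA = grp[1], groupB = grp[2],
             meanA = mean(a), meanB = mean(b), source = ratioSource)
      })
  }
  list(volumes = vols, correlations = correlations,
       ratioStats = ratioStats, excluded = missing)
}
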
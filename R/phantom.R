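#' @include AllClasses.R AllGenerics.R
NULL

# Tissue intensity constants of the synthetic T1w-like phantom (arbitrary
# units). Fat is the hyperintense class, organs mid-intensity, background
# near zero; bone confounders have a dark core and a deliberately fat-like
# bright rim so intensity-driven segmentation can be fooled the way hip
# bones fool it on real scans.
.PHANTOM_INTENSITY <- list(background = 0, organ = 100, fat = 200,
                           boneCore = 40, boneRim = 180)

# evaluate code with a private, restored RNG stream
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

.truncNorm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Configuration of one phantom cohort group
#'
#' Defines the sampling distributions from which individual synthetic
#' subjects are drawn. The defaults encode the intended group contrast:
#' patients carry relatively more visceral and less subcutaneous fat than
#' controls, so the ground-truth VAT/SAT ratio is elevated in the patient
#' group.
#'
#' @param group \code{"control"} or \code{"patient"}
#' @param nSubjects subjects in the group
#' @param satThicknessMean,satThicknessSD subcutaneous annulus width (mm)
#' @param vatFractionMean,vatFractionSD nominal fraction of the abdominal
#'   cavity area occupied by visceral fat blobs
#' @param ageMean,ageSD subject age (years)
#' @param bmiMean,bmiSD body-mass index (kg/m^2)
#' @param nVatBlobsRange integer range of visceral blob counts
#' @param boneFlag draw spine/hip-bone confounders
#' @param biasAmplitude relative strength of the multiplicative bias field
#' @param noiseSigma Rician noise level relative to the fat intensity
#' @param baseSeed base RNG seed; every subject derives its own seed from it
#' @return a list of class \code{PhantomGroupConfig}
#' @export
phantomGroupConfig <- function(group = c("control", "patient"),
                               nSubjects = 34,
                               satThicknessMean = if (group == "patient") 14 else 18,
                               satThicknessSD = 3,
                               vatFractionMean = if (group == "patient") 0.30 else 0.14,
                               vatFractionSD = if (group == "patient") 0.07 else 0.04,
                               ageMean = 60, ageSD = 13,
                               bmiMean = if (group == "patient") 26 else 24,
                               bmiSD = 4,
                               nVatBlobsRange = c(5L, 12L),
                               boneFlag = TRUE,
                               biasAmplitude = 0.10,
                               noiseSigma = 0.03,
                               baseSeed = 20220401) {
  group <- match.arg(group)
  structure(list(group = group, nSubjects = as.integer(nSubjects),
                 satThicknessMean = satThicknessMean,
                 satThicknessSD = satThicknessSD,
                 vatFractionMean = vatFractionMean,
                 vatFractionSD = vatFractionSD,
                 ageMean = ageMean, ageSD = ageSD,
                 bmiMean = bmiMean, bmiSD = bmiSD,
                 nVatBlobsRange = as.integer(nVatBlobsRange),
                 boneFlag = boneFlag,
                 biasAmplitude = biasAmplitude, noiseSigma = noiseSigma,
                 baseSeed = as.integer(baseSeed)),
            class = "PhantomGroupConfig")
}

#' Draw one synthetic subject from a group configuration
#'
#' Deterministic in (baseSeed, group, index): the subject's own seed is a
#' fixed hash of the three, and all generative parameters are drawn from
#' the group distributions, truncated to their physical ranges.
#'
#' @param cfg a \code{\link{phantomGroupConfig}}
#' @param group group name; must match \code{cfg$group}
#' @param index 1-based subject index, \code{<= cfg$nSubjects}
#' @return a list of class \code{PhantomSubject} holding the generative
#'   parameters (body semi-axes, SAT thickness, VAT fraction and blob
#'   count, confounder/noise settings, demographics, RNG seed)
#' @export
sampleSubject <- function(cfg, group = cfg$group, index) {
  if (!identical(group, cfg$group))
    stop("unknown or mismatched group name: ", group)
  if (index < 1L || index > cfg$nSubjects)
    stop("subject index ", index, " outside 1..", cfg$nSubjects)
  groupOffset <- if (group == "patient") 104729L else 0L
  seed <- (cfg$baseSeed + 7919L * as.integer(index) + groupOffset) %%
    2147483647L
  .withSeed(seed, {
    s <- list(
      subjectID = sprintf("%s%03d", substr(group, 1, 3), index),
      group = group,
      bodySemiAxes = c(ax = .truncNorm(1, 62, 6, 46, 72),
                       ay = .truncNorm(1, 50, 5, 38, 62)),
      satThickness = .truncNorm(1, cfg$satThicknessMean, cfg$satThicknessSD,
                                6, 26),
      vatFraction = .truncNorm(1, cfg$vatFractionMean, cfg$vatFractionSD,
                               0.03, 0.60),
      nVatBlobs = sample(cfg$nVatBlobsRange[1]:cfg$nVatBlobsRange[2], 1),
      boneFlag = cfg$boneFlag,
      biasAmplitude = cfg$biasAmplitude,
      noiseSigma = cfg$noiseSigma,
      age = .truncNorm(1, cfg$ageMean, cfg$ageSD, 20, 90),
      bmi = .truncNorm(1, cfg$bmiMean, cfg$bmiSD, 15, 42),
      rngSeed = seed)
    class(s) <- "PhantomSubject"
    s
  })
}

# smooth random 2nd-order polynomial field on [-1,1]^3, normalised so
# max |P| = 1; mimics low-frequency B1 inhomogeneity
.biasField <- function(dims) {
  co <- stats::runif(10, -1, 1)
  x <- seq(-1, 1, length.out = dims[1])
  y <- seq(-1, 1, length.out = dims[2])
  z <- if (dims[3] > 1) seq(-1, 1, length.out = dims[3]) else 0
  X <- array(rep(x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  P <- co[1] + co[2] * X + co[3] * Y + co[4] * Z + co[5] * X * Y +
    co[6] * X * Z + co[7] * Y * Z + co[8] * X^2 + co[9] * Y^2 + co[10] * Z^2
  P / max(abs(P))
}

#' Render a synthetic abdominal volume with ground truth
#'
#' Builds, slice by slice, an elliptical body cross-section whose outermost
#' band of width \code{satThickness} is subcutaneous fat (bright, labelled
#' SAT), an organ-intensity interior, a set of bright visceral fat blobs
#' (labelled VAT) confined to the abdominal cavity, and optional bone
#' confounders (dark core, bright fat-like rim, labelled background) near
#' the posterior midline and, on inferior slices, laterally (hip
#' surrogates). Intensities are then modulated by a smooth 2nd-order
#' polynomial bias field and corrupted by Rician noise; the returned label
#' map is the noise-free ground truth.
#'
#' @param s a \code{PhantomSubject} from \code{\link{sampleSubject}}
#' @param dims grid dimensions (nx, ny, nz), all \code{>= c(32, 32, 8)}
#'   in-plane/z as checked against the geometry
#' @param spacing voxel size in mm; default (1.25, 1.25, 6.0)
#' @return list with elements \code{volume} (\linkS4class{VolumeImage})
#'   and \code{truth} (\linkS4class{LabelMap})
#' @export
renderPhantom <- function(s, dims = c(128L, 128L, 12L),
                          spacing = c(1.25, 1.25, 6.0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < c(32L, 32L, 1L)))
    stop("dims must be at least (32, 32, 1)")
  ax <- s$bodySemiAxes[["ax"]]; ay <- s$bodySemiAxes[["ay"]]
  t <- s$satThickness
  fovHalf <- (dims[1:2] - 1) / 2 * spacing[1:2]
  if (ax > fovHalf[1] - 2 * spacing[1] || ay > fovHalf[2] - 2 * spacing[2])
    stop("dims too small: body of semi-axes (", round(ax, 1), ", ",
         round(ay, 1), ") mm does not fit the field of view")
  margin <- 2 * max(spacing[1:2])
  if (min(ax, ay) - t - margin < 6)
    stop("dims/geometry too small to fit a ", round(t, 1),
         " mm subcutaneous band at this spacing")

  INT <- .PHANTOM_INTENSITY
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing[2]
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)

  .withSeed(s$rngSeed, {
    # unit-scale blob parameters drawn before any use of vatFraction so
    # that the blob set grows monotonically with vatFraction at fixed seed
    nb <- s$nVatBlobs
    blobTheta <- stats::runif(nb, 0, 2 * pi)
    blobRad <- sqrt(stats::runif(nb))        # uniform over the cavity disc
    blobP <- stats::runif(nb, 0.5, 1)        # unit semi-axes
    blobQ <- stats::runif(nb, 0.5, 1)
    blobZc <- stats::runif(nb, 1, nz)        # slice centre
    blobZr <- stats::runif(nb, 1, max(2.5, nz / 3))  # z semi-extent, slices

    vol <- array(0, dims)
    lab <- array(0L, dims)
    zProfile <- 1 - 0.06 * (2 * (seq_len(nz) - 1) / max(nz - 1, 1) - 1)^2

    # analytic calibration: the blob union, summed over slices, targets
    # vatFraction of the cavity volume. Each ellipsoidal blob's summed
    # cross-section is ~ pi*p*q*s^2 * (4/3)*zr, so the in-plane scale s
    # follows in closed form (blob overlap is not corrected, making
    # vatFraction a nominal target; it is exactly monotone at fixed seed)
    cavAx <- ax - t - margin; cavAy <- ay - t - margin
    cavArea <- pi * cavAx * cavAy
    effSlices <- pmin(4 / 3 * blobZr, nz)
    blobScale <- sqrt(s$vatFraction * cavArea * nz /
                        (pi * sum(blobP * blobQ * effSlices)))

    for (k in seq_len(nz)) {
      axk <- ax * zProfile[k]; ayk <- ay * zProfile[k]
      body <- (X / axk)^2 + (Y / ayk)^2 <= 1
      inner <- (X / (axk - t))^2 + (Y / (ayk - t))^2 <= 1
      cavk <- (X / (axk - t - margin))^2 + (Y / (ayk - t - margin))^2 <= 1
      sl <- matrix(INT$background, nx, ny)
      lb <- matrix(0L, nx, ny)
      sl[body] <- INT$fat; lb[body & !inner] <- 1L
      sl[inner] <- INT$organ

      vat <- matrix(FALSE, nx, ny)
      for (b in seq_len(nb)) {
        dz <- (k - blobZc[b]) / blobZr[b]
        if (abs(dz) >= 1) next
        shrink <- sqrt(1 - dz^2)
        pa <- blobP[b] * blobScale * shrink
        qa <- blobQ[b] * blobScale * shrink
        if (pa < spacing[1] / 2) next
        cx <- blobRad[b] * cos(blobTheta[b]) * (cavAx - pa) * zProfile[k]
        cy <- blobRad[b] * sin(blobTheta[b]) * (cavAy - qa) * zProfile[k]
        vat <- vat | (((X - cx) / pa)^2 + ((Y - cy) / qa)^2 <= 1)
      }
      vat <- vat & cavk
      sl[vat] <- INT$fat; lb[vat] <- 2L

      if (isTRUE(s$boneFlag)) {
        bones <- list(list(cx = 0, cy = -0.5 * ayk, a = 12, b = 10))
        if (k <= ceiling(nz / 3)) {
          bones <- c(bones,
                     list(list(cx = -0.55 * cavAx, cy = -0.3 * cavAy,
                               a = 14, b = 10),
                          list(cx = 0.55 * cavAx, cy = -0.3 * cavAy,
                               a = 14, b = 10)))
        }
        for (bn in bones) {
          r2 <- ((X - bn$cx) / bn$a)^2 + ((Y - bn$cy) / bn$b)^2
          rim <- r2 <= 1 & cavk
          core <- r2 <= 0.45 & cavk
          sl[rim] <- INT$boneRim
          sl[core] <- INT$boneCore
          lb[rim] <- 0L               # bone is background in the truth
        }
      }
      vol[, , k] <- sl
      lab[, , k] <- lb
    }

    if (s$biasAmplitude > 0)
      vol <- vol * (1 + s$biasAmplitude * .biasField(dims))
    if (s$noiseSigma > 0) {
      sig <- s$noiseSigma * INT$fat
      n1 <- array(stats::rnorm(length(vol), 0, sig), dims)
      n2 <- array(stats::rnorm(length(vol), 0, sig), dims)
      vol <- sqrt((vol + n1)^2 + n2^2)
    }
    list(volume = VolumeImage(vol, spacing, subjectID = s$subjectID),
         truth = LabelMap(lab, spacing))
  })
}

#' Split a volume into overlapping stations with known shifts
#'
#' Emulates multi-station acquisition: the volume is cut into
#' \code{nStations} sub-volumes that share \code{overlapSlices} axial
#' slices at each junction, and stations 2..n are resampled under small
#' translations (inter-station subject motion) whose ground truth is
#' retained for registration testing.
#'
#' @param v the source \linkS4class{VolumeImage}
#' @param nStations number of stations (>= 2)
#' @param overlapSlices shared slices per junction, 1 to 3
#' @param trueShifts (nStations-1) x 3 matrix of voxel shifts applied to
#'   stations 2..n (absolute, station 1 is the fixed frame); each
#'   component must satisfy |shift| <= 3
#' @return a \linkS4class{StationSeries}
#' @export
splitIntoStations <- function(v, nStations, overlapSlices,
                              trueShifts = NULL) {
  stopifnot(is(v, "VolumeImage"))
  nStations <- as.integer(nStations)
  overlapSlices <- as.integer(overlapSlices)
  if (nStations < 2L) stop("need at least 2 stations")
  if (overlapSlices < 1L || overlapSlices > 3L)
    stop("overlapSlices must be between 1 and 3")
  nz <- dim(v@data)[3]
  tot <- nz + (nStations - 1L) * overlapSlices
  if (tot %% nStations != 0L)
    stop("volume of ", nz, " slices cannot be cut into ", nStations,
         " equal stations with overlap ", overlapSlices,
         " (need (nz + (n-1)*overlap) divisible by n)")
  sSize <- tot %/% nStations
  if (sSize <= overlapSlices)
    stop("stations would exceed the volume extent")
  if (is.null(trueShifts))
    trueShifts <- matrix(0, nStations - 1L, 3L)
  trueShifts <- as.matrix(trueShifts)
  if (any(abs(trueShifts) > 3))
    stop("station shifts must be small (|shift| <= 3 voxels)")

  stations <- vector("list", nStations)
  for (i in seq_len(nStations)) {
    z0 <- (i - 1L) * (sSize - overlapSlices) + 1L
    zr <- z0:(z0 + sSize - 1L)
    if (i == 1L) {
      sub <- v@data[, , zr, drop = FALSE]
    } else {
      shifted <- .cpp_shift_volume(v@data, as.numeric(trueShifts[i - 1L, ]),
                                   FALSE)
      sub <- shifted[, , zr, drop = FALSE]
    }
    stations[[i]] <- VolumeImage(sub, v@spacing,
                                 originZ = (z0 - 1L) * v@spacing[3],
                                 subjectID = v@subjectID)
  }
  StationSeries(stations, overlapSlices, trueShifts)
}

#' Generate and write a two-group synthetic cohort
#'
#' Renders every subject of both group configurations, writes the volume
#' and ground-truth label map as NIfTI plus a per-slice PNG mask sample,
#' and a JSON manifest listing all files. Fully seeded: regeneration with
#' the same configurations produces identical files.
#'
#' @param cfgControl,cfgPatient \code{\link{phantomGroupConfig}} objects
#' @param outDir output directory (created if needed)
#' @param dims,spacing phantom geometry passed to
#'   \code{\link{renderPhantom}}
#' @param writePNGSamples also write the middle-slice mask as PNG
#' @return the cohort manifest data.frame, invisibly written to
#'   \code{manifest.json}
#' @export
generateCohort <- function(cfgControl, cfgPatient, outDir,
                           dims = c(128L, 128L, 12L),
                           spacing = c(1.25, 1.25, 6.0),
                           writePNGSamples = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cfg in list(cfgControl, cfgPatient)) {
    for (i in seq_len(cfg$nSubjects)) {
      s <- sampleSubject(cfg, index = i)
      ph <- renderPhantom(s, dims = dims, spacing = spacing)
      volPath <- file.path(outDir, paste0(s$subjectID, "_vol.nii.gz"))
      labPath <- file.path(outDir, paste0(s$subjectID, "_gt.nii.gz"))
      writeVolume(ph$volume, volPath)
      writeLabelMap(ph$truth, labPath)
      if (writePNGSamples) {
        mid <- ceiling(dims[3] / 2)
        writeMaskPNG(ph$truth@classes[, , mid],
                     file.path(outDir, paste0(s$subjectID, "_midmask.png")))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subjectID = s$subjectID, group = s$group, age = s$age, bmi = s$bmi,
        volume = basename(volPath), truth = basename(labPath),
        split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  writeCohortManifest(manifest, file.path(outDir, "manifest.json"))
  manifest
}
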
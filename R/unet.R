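#' @include AllClasses.R AllGenerics.R phantom.R
NULL

#' Encoder-decoder network architecture configuration
#'
#' A U-Net-like architecture: a contracting path of
#' \code{length(encoderChannels)} levels (each \code{convsPerBlock} 3x3
#' same-padded convolutions with rectified-linear activation, then 2x2
#' max-pooling), a bottleneck with dropout, an expanding path mirroring
#' the levels with 2x2-stride transposed convolutions and skip
#' concatenations, and a final 1x1 convolution with per-pixel softmax
#' over 3 classes. The default contracting path uses 16/32/64 feature
#' channels over three down-sampling steps at 384x384 input; the reduced
#' 8/16/32 at 128x128 configuration serves desk-scale experiments.
#'
#' @param inputSize (H, W) in pixels, divisible by
#'   \code{2^length(encoderChannels)}
#' @param encoderChannels feature channels per contracting level
#' @param bottleneckChannels channels at the bottleneck (doubling pattern
#'   continues the contracting path)
#' @param nClasses number of output classes (fixed at 3)
#' @param dropoutRate dropout probability at the bottleneck
#' @param convsPerBlock convolutions per level
#' @return list of class \code{UNetConfig}
#' @export
unetConfig <- function(inputSize = c(384L, 384L),
                       encoderChannels = c(16L, 32L, 64L),
                       bottleneckChannels = 128L,
                       nClasses = 3L, dropoutRate = 0.5,
                       convsPerBlock = 2L) {
  inputSize <- as.integer(inputSize)
  L <- length(encoderChannels)
  if (any(inputSize %% (2L^L) != 0L))
    stop("input size ", paste(inputSize, collapse = "x"),
         " must be divisible by ", 2L^L)
  if (nClasses != 3L) stop("this model is fixed at 3 classes")
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0,1)")
  list(inputSize = inputSize,
       encoderChannels = as.integer(encoderChannels),
       bottleneckChannels = as.integer(bottleneckChannels),
       nClasses = 3L, dropoutRate = dropoutRate,
       convsPerBlock = as.integer(convsPerBlock), kernel = 3L)
}

#' Training configuration
#'
#' @param epochs training epochs (default 15)
#' @param batchSize samples per optimisation step (default 16)
#' @param learningRate step size of the adaptive-moment (Adam) optimiser
#' @param seed RNG seed covering weight initialisation, data order and
#'   dropout
#' @param classWeights optional length-3 per-class loss weights
#' @return list of class \code{TrainConfig}; the loss is categorical
#'   cross-entropy
#' @export
trainConfig <- function(epochs = 15L, batchSize = 16L, learningRate = 1e-3,
                        seed = 1L, classWeights = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, loss = "categorical_crossentropy",
       optimizer = "adam", beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
       seed = as.integer(seed), classWeights = classWeights)
}

.heInit <- function(nin, nout, fanIn) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / fanIn)), nin, nout)
}

#' Build an untrained network
#'
#' Initialises all weights (He initialisation, seeded) for the
#' architecture described by the configuration.
#'
#' @param config a \code{\link{unetConfig}}
#' @param seed RNG seed for the initialisation
#' @return a \linkS4class{TrainedUNet} with empty training history
#' @export
buildUNet <- function(config, seed = 1L) {
  k <- config$kernel
  ch <- config$encoderChannels
  L <- length(ch)
  nb <- config$bottleneckChannels
  .withSeed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      for (cc in seq_len(config$convsPerBlock)) {
        p[[sprintf("enc%d_conv%d_W", l, cc)]] <-
          .heInit(k * k * cin, ch[l], k * k * cin)
        p[[sprintf("enc%d_conv%d_b", l, cc)]] <- numeric(ch[l])
        cin <- ch[l]
      }
    }
    for (cc in seq_len(config$convsPerBlock)) {
      p[[sprintf("bot_conv%d_W", cc)]] <- .heInit(k * k * cin, nb, k * k * cin)
      p[[sprintf("bot_conv%d_b", cc)]] <- numeric(nb)
      cin <- nb
    }
    for (l in rev(seq_len(L))) {
      p[[sprintf("dec%d_up_W", l)]] <- .heInit(cin, 4L * ch[l], cin)
      p[[sprintf("dec%d_up_b", l)]] <- numeric(ch[l])
      cin <- 2L * ch[l]               # skip concatenation
      for (cc in seq_len(config$convsPerBlock)) {
        p[[sprintf("dec%d_conv%d_W", l, cc)]] <-
          .heInit(k * k * cin, ch[l], k * k * cin)
        p[[sprintf("dec%d_conv%d_b", l, cc)]] <- numeric(ch[l])
        cin <- ch[l]
      }
    }
    p[["out_W"]] <- .heInit(cin, config$nClasses, cin)
    p[["out_b"]] <- numeric(config$nClasses)
    new("TrainedUNet", params = p, config = config,
        trainConfig = list(), history = data.frame())
  })
}

.relu <- function(a) {
  a[a < 0] <- 0
  a
}

.softmax3 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2], logits[, , 3])
  e1 <- exp(logits[, , 1] - m)
  e2 <- exp(logits[, , 2] - m)
  e3 <- exp(logits[, , 3] - m)
  s <- e1 + e2 + e3
  array(c(e1 / s, e2 / s, e3 / s), dim(logits))
}

# forward pass for one slice; x is an (H, W) matrix in [0, 1]
.unetForward <- function(p, config, x, train = FALSE, dropMaskSeed = NULL) {
  k <- config$kernel
  L <- length(config$encoderChannels)
  nC <- config$convsPerBlock
  cache <- list(skips = list(), enc = list(), pool = list(), dec = list())
  a <- array(x, c(dim(x), 1L))
  for (l in seq_len(L)) {
    blk <- vector("list", nC)
    for (cc in seq_len(nC)) {
      xin <- a
      a <- .cpp_conv_fwd(a, p[[sprintf("enc%d_conv%d_W", l, cc)]],
                         p[[sprintf("enc%d_conv%d_b", l, cc)]], k)
      a <- .relu(a)
      blk[[cc]] <- list(x = xin, mask = a > 0)
    }
    cache$enc[[l]] <- blk
    cache$skips[[l]] <- a
    pl <- .cpp_maxpool_fwd(a)
    cache$pool[[l]] <- pl$idx
    a <- pl$y
  }
  blk <- vector("list", nC)
  for (cc in seq_len(nC)) {
    xin <- a
    a <- .cpp_conv_fwd(a, p[[sprintf("bot_conv%d_W", cc)]],
                       p[[sprintf("bot_conv%d_b", cc)]], k)
    a <- .relu(a)
    blk[[cc]] <- list(x = xin, mask = a > 0)
  }
  cache$bot <- blk
  if (train && config$dropoutRate > 0) {
    keep <- 1 - config$dropoutRate
    dm <- array(stats::rbinom(length(a), 1L, keep), dim(a)) / keep
    a <- a * dm
    cache$drop <- dm
  }
  for (l in rev(seq_len(L))) {
    xin <- a
    a <- .cpp_upconv_fwd(a, p[[sprintf("dec%d_up_W", l)]],
                         p[[sprintf("dec%d_up_b", l)]])
    skip <- cache$skips[[l]]
    nS <- dim(skip)[3]
    cat_ <- array(c(skip, a), c(dim(a)[1:2], nS + dim(a)[3]))
    blk <- list(upIn = xin, nSkip = nS, convs = vector("list", nC))
    a <- cat_
    for (cc in seq_len(nC)) {
      xc <- a
      a <- .cpp_conv_fwd(a, p[[sprintf("dec%d_conv%d_W", l, cc)]],
                         p[[sprintf("dec%d_conv%d_b", l, cc)]], k)
      a <- .relu(a)
      blk$convs[[cc]] <- list(x = xc, mask = a > 0)
    }
    cache$dec[[l]] <- blk
  }
  cache$outIn <- a
  logits <- .cpp_conv_fwd(a, p[["out_W"]], p[["out_b"]], 1L)
  list(probs = .softmax3(logits), cache = cache)
}

# backward pass; dLogits is the gradient at the pre-softmax output
.unetBackward <- function(p, config, dLogits, cache) {
  k <- config$kernel
  L <- length(config$encoderChannels)
  nC <- config$convsPerBlock
  g <- list()
  bw <- .cpp_conv_bwd(cache$outIn, p[["out_W"]], dLogits, 1L)
  g[["out_W"]] <- bw$dW; g[["out_b"]] <- bw$db
  d <- bw$dx
  for (l in seq_len(L)) {
    blk <- cache$dec[[l]]
    for (cc in rev(seq_len(nC))) {
      cv <- blk$convs[[cc]]
      d <- d * cv$mask
      bw <- .cpp_conv_bwd(cv$x, p[[sprintf("dec%d_conv%d_W", l, cc)]], d, k)
      g[[sprintf("dec%d_conv%d_W", l, cc)]] <- bw$dW
      g[[sprintf("dec%d_conv%d_b", l, cc)]] <- bw$db
      d <- bw$dx
    }
    nS <- blk$nSkip
    dSkip <- d[, , seq_len(nS), drop = FALSE]
    dUp <- d[, , nS + seq_len(dim(d)[3] - nS), drop = FALSE]
    bw <- .cpp_upconv_bwd(blk$upIn, p[[sprintf("dec%d_up_W", l)]], dUp)
    g[[sprintf("dec%d_up_W", l)]] <- bw$dW
    g[[sprintf("dec%d_up_b", l)]] <- bw$db
    d <- bw$dx
    cache$skipGrad[[l]] <- dSkip
  }
  if (!is.null(cache$drop)) d <- d * cache$drop
  for (cc in rev(seq_len(nC))) {
    cv <- cache$bot[[cc]]
    d <- d * cv$mask
    bw <- .cpp_conv_bwd(cv$x, p[[sprintf("bot_conv%d_W", cc)]], d, k)
    g[[sprintf("bot_conv%d_W", cc)]] <- bw$dW
    g[[sprintf("bot_conv%d_b", cc)]] <- bw$db
    d <- bw$dx
  }
  for (l in rev(seq_len(L))) {
    d <- .cpp_maxpool_bwd(d, cache$pool[[l]])
    d <- d + cache$skipGrad[[l]]
    for (cc in rev(seq_len(nC))) {
      cv <- cache$enc[[l]][[cc]]
      d <- d * cv$mask
      bw <- .cpp_conv_bwd(cv$x, p[[sprintf("enc%d_conv%d_W", l, cc)]], d, k)
      g[[sprintf("enc%d_conv%d_W", l, cc)]] <- bw$dW
      g[[sprintf("enc%d_conv%d_b", l, cc)]] <- bw$db
      d <- bw$dx
    }
  }
  g
}

# categorical cross-entropy and its gradient at the logits for one slice
.sliceLossGrad <- function(probs, mask, classWeights = NULL) {
  np <- length(mask)
  oneIdx <- cbind(as.vector(row(mask)), as.vector(col(mask)),
                  as.vector(mask) + 1L)
  pTrue <- pmax(probs[oneIdx], 1e-12)
  w <- if (is.null(classWeights)) rep(1, np) else classWeights[mask + 1L]
  wsum <- sum(w)
  loss <- -sum(w * log(pTrue)) / wsum
  onehot <- array(0, dim(probs))
  onehot[oneIdx] <- 1
  dLogits <- (probs - onehot) * array(rep(w, 3) / wsum, dim(probs))
  list(loss = loss, dLogits = dLogits)
}

#' Train the network with categorical cross-entropy and Adam
#'
#' Minimises per-pixel categorical cross-entropy with adaptive moment
#' estimation over mini-batches; records per-epoch training and
#' validation loss. Fully seeded: data order, weight initialisation (in
#' \code{\link{buildUNet}}) and dropout all derive from the
#' configuration seeds, so repeated runs produce identical weights.
#'
#' @param model an (untrained) \linkS4class{TrainedUNet}
#' @param trainSamples,valSamples lists of samples, each a list with a
#'   normalised \code{image} matrix in [0,1] and an integer \code{mask}
#'   matrix of the same size with values in \{0,1,2\} (see
#'   \code{\link{makeTrainingSamples}})
#' @param tconf a \code{\link{trainConfig}}
#' @param verbose print per-epoch losses
#' @return the trained \linkS4class{TrainedUNet}
#' @export
trainUNet <- function(model, trainSamples, valSamples = list(),
                      tconf = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "TrainedUNet"))
  config <- model@config
  for (s in c(trainSamples, valSamples)) {
    if (!identical(dim(s$image), dim(s$mask)))
      stop("image/mask size mismatch: ", paste(dim(s$image), collapse = "x"),
           " vs ", paste(dim(s$mask), collapse = "x"))
    if (!identical(as.integer(dim(s$image)), config$inputSize))
      stop("sample size ", paste(dim(s$image), collapse = "x"),
           " does not match the model input ",
           paste(config$inputSize, collapse = "x"))
  }
  p <- model@params
  mAd <- lapply(p, function(w) w * 0)
  vAd <- lapply(p, function(w) w * 0)
  step <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     valLoss = numeric())
  .withSeed(tconf$seed, {
    n <- length(trainSamples)
    for (ep in seq_len(tconf$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      nBatch <- 0L
      for (b0 in seq(1L, n, by = tconf$batchSize)) {
        idx <- ord[b0:min(n, b0 + tconf$batchSize - 1L)]
        acc <- NULL
        bLoss <- 0
        for (i in idx) {
          sm <- trainSamples[[i]]
          fw <- .unetForward(p, config, sm$image, train = TRUE)
          lg <- .sliceLossGrad(fw$probs, sm$mask, tconf$classWeights)
          bLoss <- bLoss + lg$loss
          gr <- .unetBackward(p, config, lg$dLogits, fw$cache)
          if (is.null(acc)) acc <- gr
          else for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
        }
        nb <- length(idx)
        bLoss <- bLoss / nb
        if (!is.finite(bLoss))
          stop("NaN/Inf loss at epoch ", ep, ", batch starting ", b0,
               "; try a lower learning rate")
        step <- step + 1L
        corr1 <- 1 - tconf$beta1^step
        corr2 <- 1 - tconf$beta2^step
        for (nm in names(p)) {
          ghat <- acc[[nm]] / nb
          mAd[[nm]] <- tconf$beta1 * mAd[[nm]] + (1 - tconf$beta1) * ghat
          vAd[[nm]] <- tconf$beta2 * vAd[[nm]] + (1 - tconf$beta2) * ghat^2
          p[[nm]] <- p[[nm]] - tconf$learningRate *
            (mAd[[nm]] / corr1) / (sqrt(vAd[[nm]] / corr2) + tconf$epsilon)
        }
        epochLoss <- epochLoss + bLoss
        nBatch <- nBatch + 1L
      }
      trLoss <- epochLoss / nBatch
      vlLoss <- if (length(valSamples)) {
        mean(vapply(valSamples, function(sm) {
          fw <- .unetForward(p, config, sm$image, train = FALSE)
          .sliceLossGrad(fw$probs, sm$mask, tconf$classWeights)$loss
        }, numeric(1)))
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, loss = trLoss,
                                     valLoss = vlLoss))
      if (verbose)
        message(sprintf("epoch %d: loss %.5f val %.5f", ep, trLoss, vlLoss))
    }
  })
  new("TrainedUNet", params = p, config = config, trainConfig = tconf,
      history = hist)
}

#' Per-volume min-max normalised training samples
#'
#' Normalises a volume's intensities to [0, 1] (per volume) and pairs
#' each axial slice with its label-map slice, padded centrally with
#' zeros to the network input size.
#'
#' @param v a \linkS4class{VolumeImage}
#' @param m the aligned \linkS4class{LabelMap} (or NULL for
#'   prediction-only samples)
#' @param inputSize network input (H, W)
#' @return list of samples (\code{image}, \code{mask}, \code{offset})
#' @export
makeTrainingSamples <- function(v, m = NULL, inputSize = c(128L, 128L)) {
  stopifnot(is(v, "VolumeImage"))
  d <- dim(v@data)
  if (any(d[1:2] > inputSize))
    stop("slices of ", paste(d[1:2], collapse = "x"),
         " exceed the network input ", paste(inputSize, collapse = "x"))
  rng <- range(v@data)
  norm <- if (diff(rng) > 0) (v@data - rng[1]) / diff(rng) else v@data * 0
  off <- as.integer(floor((inputSize - d[1:2]) / 2))
  lapply(seq_len(d[3]), function(k) {
    img <- matrix(0, inputSize[1], inputSize[2])
    img[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- norm[, , k]
    msk <- NULL
    if (!is.null(m)) {
      msk <- matrix(0L, inputSize[1], inputSize[2])
      msk[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- m@classes[, , k]
    }
    list(image = img, mask = msk, offset = off, sliceDims = d[1:2])
  })
}

#' Predict a 3-class label map for a volume
#'
#' Runs the trained network slice by slice (per-volume min-max
#' normalisation, central zero-padding to the input size), takes the
#' per-pixel argmax of the softmax output (ties broken toward the lower
#' class index) and maps the labels back onto the volume grid.
#'
#' @param tm a trained \linkS4class{TrainedUNet}
#' @param v a \linkS4class{VolumeImage}
#' @return a \linkS4class{LabelMap} aligned to \code{v}
#' @export
predictVolume <- function(tm, v) {
  stopifnot(is(tm, "TrainedUNet"), is(v, "VolumeImage"))
  if (any(!is.finite(v@spacing)) || any(v@spacing <= 0))
    stop("volume has no valid spacing metadata")
  samples <- makeTrainingSamples(v, NULL, tm@config$inputSize)
  d <- dim(v@data)
  out <- array(0L, d)
  for (k in seq_along(samples)) {
    sm <- samples[[k]]
    pr <- .unetForward(tm@params, tm@config, sm$image, train = FALSE)$probs
    # argmax with ties toward the lower class index
    cls <- max.col(matrix(pr, ncol = 3L), ties.method = "first") - 1L
    cls <- matrix(cls, dim(pr)[1], dim(pr)[2])
    out[, , k] <- cls[sm$offset[1] + seq_len(d[1]),
                      sm$offset[2] + seq_len(d[2])]
  }
  LabelMap(out, v@spacing)
}

#' Softmax class probabilities for one slice
#'
#' @param tm a trained \linkS4class{TrainedUNet}
#' @param image matrix in [0,1] matching the network input size
#' @return (H, W, 3) array of class probabilities summing to 1 per pixel
#' @export
predictSliceProbs <- function(tm, image) {
  .unetForward(tm@params, tm@config, image, train = FALSE)$probs
}

#' Stratified subject-level train/validation/test split
#'
#' Assigns every subject (never individual slices) to one split. Within
#' each age-tertile x BMI-tertile x group stratum, subjects are assigned
#' greedily to the split with the largest remaining deficit, so global
#' proportions are met exactly up to integer rounding and each stratum is
#' spread across splits. Seeded and deterministic.
#'
#' @param manifest data.frame with columns subjectID, group, age, bmi
#' @param fractions train/validation/test fractions summing to 1
#' @param seed RNG seed
#' @return the manifest with its \code{split} column filled with
#'   \code{"train"}, \code{"val"} or \code{"test"}
#' @export
splitDataset <- function(manifest, fractions = c(0.50, 0.06, 0.44),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- nrow(manifest)
  tert <- function(x) {
    qs <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
    findInterval(x, qs) + 1L
  }
  strata <- interaction(tert(manifest$age), tert(manifest$bmi),
                        manifest$group, drop = TRUE)
  if (min(table(strata)) < 3L) {
    warning("stratum with fewer than 3 subjects; ",
            "falling back to global (unstratified) assignment")
    strata <- factor(rep(1L, n))
  }
  splits <- c("train", "val", "test")
  assigned <- integer(3)
  out <- character(n)
  .withSeed(seed, {
    perm <- sample.int(n)
    ord <- perm[order(strata[perm])]  # stratum-grouped, shuffled within
    done <- 0L
    for (i in ord) {
      done <- done + 1L
      deficit <- fractions * done - assigned
      pick <- which.max(deficit)
      assigned[pick] <- assigned[pick] + 1L
      out[i] <- splits[pick]
    }
  })
  manifest$split <- out
  manifest
}
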
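# shared fixtures: small seeded phantoms and a brute-force metric oracle

# a clean (noise/bias/bone-free) phantom subject for exactness checks
cleanSubject <- function(seed = 1, boneFlag = FALSE) {
  cfg <- phantomGroupConfig("control", nSubjects = 50, noiseSigma = 0,
                            biasAmplitude = 0, boneFlag = boneFlag,
                            baseSeed = seed)
  sampleSubject(cfg, index = 1)
}

cleanPhantom <- function(seed = 1, dims = c(64, 64, 8),
                         spacing = c(2.5, 2.5, 6), boneFlag = FALSE) {
  renderPhantom(cleanSubject(seed, boneFlag), dims = dims, spacing = spacing)
}

noisyPhantom <- function(seed = 1, dims = c(64, 64, 8),
                         spacing = c(2.5, 2.5, 6), noiseSigma = 0.03,
                         biasAmplitude = 0.1) {
  cfg <- phantomGroupConfig("control", nSubjects = 50,
                            noiseSigma = noiseSigma,
                            biasAmplitude = biasAmplitude, baseSeed = seed)
  renderPhantom(sampleSubject(cfg, index = 1), dims = dims, spacing = spacing)
}

# independent per-pixel enumeration of overlap counts, deliberately written
# as an explicit pixel loop so it shares no code with the vectorised metrics
oraclePixelCounts <- function(R, P) {
  stopifnot(identical(dim(R), dim(P)))
  inter <- 0L; nR <- 0L; nP <- 0L; disagree <- 0L
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      r <- R[i, j]; p <- P[i, j]
      if (r) nR <- nR + 1L
      if (p) nP <- nP + 1L
      if (r && p) inter <- inter + 1L
      if (r != p) disagree <- disagree + 1L
    }
  }
  list(intersection = inter, nR = nR, nP = nP, disagree = disagree,
       size = nrow(R) * ncol(R))
}

oracleDice <- function(R, P) {
  cnt <- oraclePixelCounts(R, P)
  if (cnt$nR + cnt$nP == 0) return(NA_real_)
  2 * cnt$intersection / (cnt$nR + cnt$nP)
}

oraclePixelError <- function(R, P) {
  cnt <- oraclePixelCounts(R, P)
  100 * cnt$disagree / cnt$size
}

# a phantom shrunk to fit very small grids (fixed compact geometry)
compactPhantom <- function(seed = 1, dims = c(40, 40, 4),
                           spacing = c(3, 3, 6)) {
  s <- cleanSubject(seed)
  s$bodySemiAxes <- c(ax = 45, ay = 38)
  s$satThickness <- 10
  renderPhantom(s, dims = dims, spacing = spacing)
}

# concatenate 3-D arrays along z
abind_z <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:2]
  array(do.call(c, parts), c(d, sum(vapply(parts, function(a) dim(a)[3],
                                           integer(1)))))
}

# tiny network configuration for fast optimisation tests
tinyUNetConfig <- function(inputSize = c(16L, 16L)) {
  unetConfig(inputSize = inputSize, encoderChannels = c(2L, 3L),
             bottleneckChannels = 4L, dropoutRate = 0)
}
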
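# Synthetic longitudinal phantom: brain-like multi-sequence volume pairs
# with a known smooth deformation, an optional non-corresponding resection
# cavity, a pathology mask and paired landmarks. Everything is
# deterministic given the spec's seed.

# Gaussian smoothing with periodic boundaries via the 3D FFT; sigma in
# voxels. Used for the deformation and the sulci-like texture, where the
# wrap-around is irrelevant (fields are later masked/rescaled).
gaussianSmooth3d <- function(a, sigma) {
  n <- dim(a)
  freq <- lapply(n, function(m) {
    f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) / m
    f
  })
  k2 <- outer(outer(freq[[1]]^2, freq[[2]]^2, `+`), freq[[3]]^2, `+`)
  transfer <- exp(-2 * pi^2 * sigma^2 * k2)
  Re(stats::fft(stats::fft(a) * transfer, inverse = TRUE)) / prod(n)
}

#' Generate a smooth fold-free displacement field
#'
#' Gaussian-filtered white-noise vector field, rescaled so the maximum
#' displacement magnitude equals the spec's amplitude. The generator checks
#' the Jacobian determinant and damps the amplitude (factor 0.7) until the
#' field is fold-free, so det(∇y) > 0 is guaranteed by construction.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{DisplacementField} on the spec's 1 mm grid.
#' @export
generateSmoothField <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  n <- spec@size
  if (spec@amplitude == 0)
    return(DisplacementField(shape = c(n, n, n)))
  u <- array(0, c(n, n, n, 3))
  for (k in 1:3)
    u[, , , k] <- gaussianSmooth3d(array(stats::rnorm(n^3), c(n, n, n)),
                                   spec@smoothness)
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u <- u * (spec@amplitude / max(mag))
  field <- DisplacementField(u)
  tries <- 0L
  while (min(volumeData(jacobianDeterminant(field))) <= 0.05 && tries < 25L) {
    u <- u * 0.7
    field <- DisplacementField(u)
    tries <- tries + 1L
  }
  if (min(volumeData(jacobianDeterminant(field))) <= 0)
    stop("could not generate a fold-free field for this spec", call. = FALSE)
  field
}

# Brain-like base anatomy in [0, 1]: ellipsoidal head with a brighter
# cortical shell, darker interior, two ventricle-like cavities and
# band-passed noise texture standing in for sulci/gyri detail.
phantomBase <- function(n) {
  idx <- seq_len(n) - 1
  ctr <- (n - 1) / 2
  X <- array(rep(idx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(idx, each = n), times = n), c(n, n, n))
  Z <- array(rep(idx, each = n * n), c(n, n, n))
  rell <- sqrt(((X - ctr) / (0.42 * n))^2 + ((Y - ctr) / (0.38 * n))^2 +
                 ((Z - ctr) / (0.40 * n))^2)
  head <- 1 / (1 + exp((rell - 1) * 24))          # soft head boundary
  cortex <- exp(-((rell - 0.82) / 0.10)^2)        # bright shell
  vent <- pmax(
    1 / (1 + exp((sqrt(((X - ctr - 0.10 * n) / (0.08 * n))^2 +
                         ((Y - ctr) / (0.06 * n))^2 +
                         ((Z - ctr) / (0.10 * n))^2) - 1) * 20)),
    1 / (1 + exp((sqrt(((X - ctr + 0.10 * n) / (0.08 * n))^2 +
                         ((Y - ctr) / (0.06 * n))^2 +
                         ((Z - ctr) / (0.10 * n))^2) - 1) * 20)))
  texture <- gaussianSmooth3d(array(stats::rnorm(n^3), c(n, n, n)), 1.2) -
    gaussianSmooth3d(array(stats::rnorm(n^3), c(n, n, n)), 2.8)
  texture <- texture / stats::sd(texture)
  base <- head * (0.55 + 0.35 * cortex - 0.4 * vent + 0.08 * texture)
  pmin(pmax(base, 0), 1)
}

# Monotone per-sequence intensity remappings of the shared anatomy; the
# exponents mimic the different tissue contrasts of T1 / T1-CE / T2 /
# FLAIR without simulating MR physics.
sequenceRemap <- function(base, s, contrast) {
  g <- c(1, 0.6, 1.6, 2.4)[s]
  contrast * base^g
}

#' Generate a longitudinal phantom pair
#'
#' Builds a pre-operative ("moving") multi-sequence volume from shared
#' brain-like anatomy and constructs the post-operative ("fixed") volume by
#' warping it with a known smooth field, so that warping the moving image
#' by `truth` reproduces the fixed image on healthy tissue up to
#' interpolation and noise. When `cavityRadius > 0` a resection cavity
#' (background interior with a thin bright rim) is inserted into the fixed
#' image only, and the pathology mask is the cavity dilated by one voxel.
#' Moving landmarks are fixed landmarks mapped through `truth` exactly, so
#' the baseline TRE equals the mean true displacement at the landmarks.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements `fixed`, `moving`
#'   (\linkS4class{MultiSequenceVolume}), `mask`
#'   (\linkS4class{PathologyMask}), `truth`
#'   (\linkS4class{DisplacementField}), `fixedLandmarks`,
#'   `movingLandmarks` (\linkS4class{LandmarkSet}) and `spec`.
#' @examples
#' ph <- generatePhantomPair(PhantomSpec(seed = 7, size = 32, nLandmarks = 6))
#' treBaselineMean(computeTRE(ph$fixedLandmarks, ph$movingLandmarks))
#' @export
generatePhantomPair <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  truth <- generateSmoothField(spec)        # seeds the RNG with spec@seed
  n <- spec@size
  base <- phantomBase(n)
  noiseSigma <- rep_len(spec@noiseSigma, spec@nSequences)
  contrast <- rep_len(spec@contrast, spec@nSequences)

  # cavity geometry (fixed/post-operative space)
  ctr <- (n - 1) / 2
  hasCavity <- spec@cavityRadius > 0
  cavityCenter <- if (all(is.finite(spec@cavityCenter)))
    spec@cavityCenter else ctr + c(0.14, 0.06, -0.05) * n
  if (hasCavity && spec@cavityRadius > 0.35 * n)
    stop("cavity larger than the phantom head", call. = FALSE)
  idx <- seq_len(n) - 1
  X <- array(rep(idx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(idx, each = n), times = n), c(n, n, n))
  Z <- array(rep(idx, each = n * n), c(n, n, n))
  dcav <- sqrt((X - cavityCenter[1])^2 + (Y - cavityCenter[2])^2 +
                 (Z - cavityCenter[3])^2)

  movingCh <- vector("list", spec@nSequences)
  fixedCh <- vector("list", spec@nSequences)
  fixedClean1 <- NULL
  for (s in seq_len(spec@nSequences)) {
    mclean <- sequenceRemap(base, s, contrast[s])
    mvol <- ScalarVolume(mclean)
    fclean <- volumeData(warpImage(mvol, truth))
    if (hasCavity) {
      rim <- dcav >= spec@cavityRadius & dcav < spec@cavityRadius + 1.5
      fclean[dcav < spec@cavityRadius] <- 0
      fclean[rim] <- 0.95 * contrast[s]
    }
    if (s == 1L) fixedClean1 <- fclean
    sd_s <- noiseSigma[s] * contrast[s]
    movingCh[[s]] <- ScalarVolume(mclean + array(stats::rnorm(n^3, sd = sd_s),
                                                 c(n, n, n)))
    fixedCh[[s]] <- ScalarVolume(fclean + array(stats::rnorm(n^3, sd = sd_s),
                                                c(n, n, n)))
  }
  labels <- c("T1", "T1CE", "T2", "FLAIR")[seq_len(spec@nSequences)]
  fixed <- MultiSequenceVolume(fixedCh, labels)
  moving <- MultiSequenceVolume(movingCh, labels)
  maskData <- array(0, c(n, n, n))
  if (hasCavity) maskData[dcav < spec@cavityRadius + 1] <- 1
  mask <- PathologyMask(maskData)

  # landmarks: high-gradient healthy-tissue voxels away from border and
  # cavity, within the near-pathology band when a cavity exists
  gm <- spatialGradient(ScalarVolume(fixedClean1))
  gmag <- sqrt(gm[, , , 1]^2 + gm[, , , 2]^2 + gm[, , , 3]^2)
  margin <- 3
  eligible <- fixedClean1 > 0.1 * max(fixedClean1) &
    X >= margin & X <= n - 1 - margin &
    Y >= margin & Y <= n - 1 - margin &
    Z >= margin & Z <= n - 1 - margin
  if (hasCavity) {
    eligible <- eligible & dcav > spec@cavityRadius + 3
    if (is.finite(spec@landmarkMaxDist))
      eligible <- eligible & dcav <= spec@landmarkMaxDist
  }
  eligible <- eligible & gmag >= stats::quantile(gmag[eligible], 0.7)
  cand <- which(eligible)
  if (length(cand) < spec@nLandmarks)
    stop("not enough eligible landmark locations; relax the spec",
         call. = FALSE)
  pick <- sort(sample(cand, spec@nLandmarks))
  p <- cbind(X[pick], Y[pick], Z[pick])     # world mm (1 mm spacing, origin 0)
  uAt <- cbind(truth@u[, , , 1][pick], truth@u[, , , 2][pick],
               truth@u[, , , 3][pick])
  fixedLandmarks <- LandmarkSet(p)
  movingLandmarks <- LandmarkSet(p + uAt, labels = fixedLandmarks@labels)

  list(fixed = fixed, moving = moving, mask = mask, truth = truth,
       fixedLandmarks = fixedLandmarks, movingLandmarks = movingLandmarks,
       spec = spec)
}
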
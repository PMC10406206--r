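#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core S4 containers. All grids follow one convention: voxel indices are
# 0-based, world coordinates are millimetres at voxel centers,
# world = origin + index * spacing.
# ---------------------------------------------------------------------------

#' ScalarVolume: a 3D intensity grid with geometry
#'
#' Holds one MRI sequence (or any scalar 3D image) together with its voxel
#' spacing and the world position of the first voxel center. Axis
#' orientation is fixed to the identity: loading code reorients data before
#' constructing the object.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), per-axis voxel size in mm, all > 0.
#' @slot origin numeric(3), world position (mm) of the center of voxel
#'   (0,0,0).
#' @aliases ScalarVolume-class
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (anyNA(object@data) || any(is.infinite(object@data)))
      msg <- c(msg, "data must not contain NaN/Inf voxels")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param spacing per-axis voxel size in mm.
#' @param origin world position (mm) of the center of voxel (0,0,0).
#' @return A \linkS4class{ScalarVolume}.
#' @examples
#' v <- ScalarVolume(array(0, c(4, 4, 4)))
#' gridShape(v)
#' @export
ScalarVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ScalarVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' PathologyMask: binary exclusion mask on the fixed image's grid
#'
#' Marks the pathological tissues (resection cavity, tumor remnants) of the
#' fixed image. Voxels with value 1 are excluded from the image distance.
#'
#' @aliases PathologyMask-class
#' @exportClass PathologyMask
setClass("PathologyMask", contains = "ScalarVolume",
  validity = function(object) {
    if (!all(object@data %in% c(0, 1)))
      return("mask values must all be 0 or 1")
    TRUE
  })

#' Construct a PathologyMask
#'
#' Non-binary input is binarized at > 0.5.
#'
#' @param data 3D array (anything > 0.5 becomes 1).
#' @param spacing,origin grid geometry as for [ScalarVolume()].
#' @return A \linkS4class{PathologyMask}.
#' @export
PathologyMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  b <- array(as.numeric(data > 0.5), dim = dim(data))
  new("PathologyMask", data = b, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' MultiSequenceVolume: channels sharing one grid
#'
#' An ordered set of \linkS4class{ScalarVolume} channels (e.g. T1, T1-CE,
#' T2, FLAIR of one time point) on a single common grid.
#'
#' @slot channels list of \linkS4class{ScalarVolume}, all on one grid.
#' @slot labels character, one sequence label per channel.
#' @aliases MultiSequenceVolume-class
#' @exportClass MultiSequenceVolume
setClass("MultiSequenceVolume",
  representation(channels = "list", labels = "character"),
  validity = function(object) {
    if (length(object@channels) < 1L)
      return("at least one channel is required")
    if (!all(vapply(object@channels, is, logical(1), "ScalarVolume")))
      return("channels must all be ScalarVolume objects")
    if (length(object@labels) != length(object@channels))
      return("one label per channel is required")
    ref <- object@channels[[1L]]
    for (ch in object@channels[-1L]) {
      if (!identical(dim(ch@data), dim(ref@data)) ||
          any(abs(ch@spacing - ref@spacing) > 1e-9) ||
          any(abs(ch@origin - ref@origin) > 1e-9))
        return("all channels must share shape, spacing and origin")
    }
    TRUE
  })

#' Construct a MultiSequenceVolume
#'
#' @param channels a \linkS4class{ScalarVolume} or a list of them.
#' @param labels sequence labels; defaults to \code{seq1, seq2, ...}.
#' @return A \linkS4class{MultiSequenceVolume}.
#' @export
MultiSequenceVolume <- function(channels, labels = NULL) {
  if (is(channels, "ScalarVolume")) channels <- list(channels)
  if (is.null(labels)) labels <- paste0("seq", seq_along(channels))
  new("MultiSequenceVolume", channels = channels, labels = as.character(labels))
}

#' DisplacementField: per-voxel displacement u with y(x) = x + u(x)
#'
#' Displacements are stored in world millimetres at every resolution level,
#' so moving a field between levels never rescales magnitudes.
#'
#' @slot u 4D numeric array (nx, ny, nz, 3) of mm displacements.
#' @slot spacing,origin grid geometry of the (fixed-image) grid the field
#'   lives on.
#' @aliases DisplacementField-class
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(u = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@u)
    if (length(d) != 4L || d[4L] != 3L)
      return("u must be a 4D array with 3 components in the last dimension")
    if (anyNA(object@u) || any(is.infinite(object@u)))
      return("u must be finite everywhere")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite values")
    TRUE
  })

#' Construct a DisplacementField
#'
#' @param u 4D array (nx, ny, nz, 3), mm; or NULL with `shape` given to
#'   build a zero field.
#' @param spacing,origin grid geometry.
#' @param shape integer(3), used when `u` is NULL.
#' @return A \linkS4class{DisplacementField}.
#' @examples
#' u <- DisplacementField(shape = c(8, 8, 8))
#' foldingFraction(u)
#' @export
DisplacementField <- function(u = NULL, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), shape = NULL) {
  if (is.null(u)) {
    stopifnot(length(shape) == 3L)
    u <- array(0, c(shape, 3L))
  }
  new("DisplacementField", u = u, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LandmarkSet: ordered, labelled 3D world points
#'
#' Landmarks paired across time points must have identical labels in
#' identical order.
#'
#' @slot labels character vector of landmark names.
#' @slot coords numeric matrix (n, 3) of world-mm coordinates.
#' @aliases LandmarkSet-class
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(labels = "character", coords = "matrix"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (nrow(object@coords) != length(object@labels))
      return("one label per point is required")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    TRUE
  })

#' Construct a LandmarkSet
#'
#' @param coords numeric matrix (n, 3), world mm.
#' @param labels landmark names; default \code{L01, L02, ...}.
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(nrow(coords)))
  new("LandmarkSet", labels = as.character(labels),
      coords = unname(coords))
}

#' EdgeParameters: NGF noise-suppression constants
#'
#' The additive constants in the normalized-gradient-fields similarity that
#' damp the influence of gradients at or below the noise level; one for the
#' reference (fixed) and one for the template (moving) image.
#'
#' @slot epsR,epsT positive scalars in intensity-gradient units.
#' @aliases EdgeParameters-class
#' @exportClass EdgeParameters
setClass("EdgeParameters", representation(epsR = "numeric", epsT = "numeric"),
  validity = function(object) {
    if (length(object@epsR) != 1L || length(object@epsT) != 1L ||
        !is.finite(object@epsR) || !is.finite(object@epsT) ||
        object@epsR <= 0 || object@epsT <= 0)
      return("epsR and epsT must be positive finite scalars")
    TRUE
  })

#' Construct EdgeParameters
#' @param epsR,epsT positive edge parameters for reference and template.
#' @return An \linkS4class{EdgeParameters}.
#' @export
EdgeParameters <- function(epsR, epsT = epsR) {
  new("EdgeParameters", epsR = as.numeric(epsR), epsT = as.numeric(epsT))
}

#' StoppingCriteria for the quasi-Newton solve
#'
#' The optimizer stops at the first satisfied criterion. `minProgress` is
#' the absolute objective decrease per accepted iteration;
#' `minRelativeGradient` compares the current gradient norm to the norm at
#' the level's starting iterate; `minStepLength` bounds the largest
#' displacement update (mm) of an accepted step.
#'
#' @slot minProgress,minGradient,minRelativeGradient,minStepLength positive
#'   thresholds (all default 0.001).
#' @slot maxIterations positive integer (default 100).
#' @aliases StoppingCriteria-class
#' @exportClass StoppingCriteria
setClass("StoppingCriteria",
  representation(minProgress = "numeric", minGradient = "numeric",
                 minRelativeGradient = "numeric", minStepLength = "numeric",
                 maxIterations = "integer"),
  validity = function(object) {
    th <- c(object@minProgress, object@minGradient,
            object@minRelativeGradient, object@minStepLength)
    if (length(th) != 4L || any(!is.finite(th)) || any(th <= 0))
      return("all thresholds must be positive")
    if (object@maxIterations < 1L)
      return("maxIterations must be >= 1")
    TRUE
  })

#' Construct StoppingCriteria
#' @param minProgress,minGradient,minRelativeGradient,minStepLength positive
#'   thresholds.
#' @param maxIterations maximum accepted iterations per level.
#' @return A \linkS4class{StoppingCriteria}.
#' @export
StoppingCriteria <- function(minProgress = 0.001, minGradient = 0.001,
                             minRelativeGradient = 0.001,
                             minStepLength = 0.001, maxIterations = 100L) {
  new("StoppingCriteria", minProgress = minProgress, minGradient = minGradient,
      minRelativeGradient = minRelativeGradient, minStepLength = minStepLength,
      maxIterations = as.integer(maxIterations))
}

#' RegistrationConfig: all tunables of the multi-level solve
#'
#' @slot alpha curvature weight (default 0.1).
#' @slot gamma volume-change-control weight (default 0.01).
#' @slot volumeControl logical; add the Jacobian-determinant barrier term
#'   (default FALSE).
#' @slot levels number of resolution levels L (default 3).
#' @slot workingSize edge length of the cubic working grid the inputs are
#'   resampled to (default 160); NA keeps the input grid.
#' @slot eps \linkS4class{EdgeParameters} or NULL for automatic per-level
#'   estimation.
#' @slot epsEta fraction of the mean gradient magnitude used by the
#'   automatic edge-parameter estimate (default 0.8, an empirical
#'   calibration placing the edge parameter above the noise-gradient
#'   scale).
#' @slot maskDistance logical; use the pathology mask in the distance when
#'   one is supplied (default TRUE).
#' @slot stopping \linkS4class{StoppingCriteria}.
#' @slot verbose logical; print the per-iteration trace.
#' @aliases RegistrationConfig-class
#' @exportClass RegistrationConfig
setClass("RegistrationConfig",
  representation(alpha = "numeric", gamma = "numeric",
                 volumeControl = "logical", levels = "integer",
                 workingSize = "integer", eps = "ANY", epsEta = "numeric",
                 maskDistance = "logical", stopping = "StoppingCriteria",
                 verbose = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha < 0 || object@gamma < 0)
      msg <- c(msg, "alpha and gamma must be >= 0")
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (!is.na(object@workingSize)) {
      if (object@workingSize < 8L)
        msg <- c(msg, "workingSize must be >= 8")
      if (object@workingSize %% 2L^(object@levels - 1L) != 0L)
        msg <- c(msg, "workingSize must be divisible by 2^(levels-1)")
    }
    if (!is.null(object@eps) && !is(object@eps, "EdgeParameters"))
      msg <- c(msg, "eps must be NULL (auto) or EdgeParameters")
    if (object@epsEta <= 0 || object@epsEta > 1)
      msg <- c(msg, "epsEta must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RegistrationConfig
#'
#' Defaults follow the study conditions: curvature weight `alpha = 0.1`,
#' three levels, a 160-voxel cubic working grid, automatic edge parameters,
#' all stopping thresholds 0.001 with at most 100 iterations, and masking
#' enabled whenever a mask is given. Volume-change control is off by default
#' for the iterative solve and can be switched on with `volumeControl =
#' TRUE` (weight `gamma = 0.01`).
#'
#' @param alpha,gamma,volumeControl,levels,workingSize,eps,epsEta,maskDistance,stopping,verbose
#'   see \linkS4class{RegistrationConfig}.
#' @return A \linkS4class{RegistrationConfig}.
#' @examples
#' cfg <- RegistrationConfig(levels = 2, workingSize = 32)
#' cfg
#' @export
RegistrationConfig <- function(alpha = 0.1, gamma = 0.01,
                               volumeControl = FALSE, levels = 3L,
                               workingSize = 160L, eps = NULL, epsEta = 0.8,
                               maskDistance = TRUE,
                               stopping = StoppingCriteria(),
                               verbose = FALSE) {
  new("RegistrationConfig", alpha = alpha, gamma = gamma,
      volumeControl = volumeControl, levels = as.integer(levels),
      workingSize = as.integer(workingSize), eps = eps, epsEta = epsEta,
      maskDistance = maskDistance, stopping = stopping, verbose = verbose)
}

#' RegistrationResult
#'
#' @slot field estimated \linkS4class{DisplacementField} on the input
#'   volumes' original grid.
#' @slot workingField the field on the working grid the solve ran on.
#' @slot history list with one data.frame of the accepted-iterate trace per
#'   level (coarsest first), plus termination reasons.
#' @slot components named numeric: final distance, curvature and volume
#'   terms and the total objective at the finest working level.
#' @aliases RegistrationResult-class
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(field = "DisplacementField", workingField = "DisplacementField",
                 history = "list", components = "numeric"))

#' TREReport: landmark registration errors for one case
#'
#' @slot labels landmark names.
#' @slot distances per-landmark Euclidean errors in mm (after mapping
#'   through the field, when one was given).
#' @slot mean mean of `distances`.
#' @slot baselineMean mean error without any field.
#' @aliases TREReport-class
#' @exportClass TREReport
setClass("TREReport",
  representation(labels = "character", distances = "numeric",
                 mean = "numeric", baselineMean = "numeric"),
  validity = function(object) {
    if (any(object@distances < 0)) return("distances must be >= 0")
    if (abs(object@mean - mean(object@distances)) > 1e-8)
      return("mean must equal the mean of distances")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic longitudinal phantom
#'
#' The generator emulates the study conditions: skull-stripped brain-like
#' volumes on an isotropic 1 mm grid, a smooth ground-truth deformation of
#' bounded amplitude, per-sequence contrast differences, an optional
#' non-corresponding resection cavity present only in the post-operative
#' image, and paired landmarks in healthy tissue near the pathology.
#'
#' @slot seed RNG seed; every output is deterministic given the seed.
#' @slot size cubic edge length in voxels (1 mm spacing).
#' @slot nSequences number of simulated MRI sequences (1-4).
#' @slot amplitude maximum ground-truth displacement magnitude in mm.
#' @slot smoothness Gaussian length-scale of the deformation in voxels.
#' @slot cavityRadius resection-cavity radius in mm (0 = no cavity).
#' @slot cavityCenter world-mm cavity center, or NA for an automatic
#'   position inside the brain.
#' @slot nLandmarks number of paired landmarks.
#' @slot noiseSigma per-sequence iid noise, as a fraction of the intensity
#'   range (recycled over sequences).
#' @slot contrast per-sequence intensity-range scale (recycled), used to
#'   emulate contrast-to-noise differences between sequences.
#' @slot landmarkMaxDist landmarks are kept within this distance (mm) of the
#'   cavity when one exists (the near-pathology evaluation geometry).
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(seed = "integer", size = "integer", nSequences = "integer",
                 amplitude = "numeric", smoothness = "numeric",
                 cavityRadius = "numeric", cavityCenter = "numeric",
                 nLandmarks = "integer", noiseSigma = "numeric",
                 contrast = "numeric", landmarkMaxDist = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@size < 16L) msg <- c(msg, "size must be >= 16")
    if (object@nSequences < 1L || object@nSequences > 4L)
      msg <- c(msg, "nSequences must be between 1 and 4")
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@smoothness <= 0) msg <- c(msg, "smoothness must be > 0")
    if (object@cavityRadius < 0) msg <- c(msg, "cavityRadius must be >= 0")
    if (object@nLandmarks < 1L) msg <- c(msg, "nLandmarks must be >= 1")
    if (any(object@noiseSigma < 0)) msg <- c(msg, "noiseSigma must be >= 0")
    if (any(object@contrast <= 0)) msg <- c(msg, "contrast must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PhantomSpec
#'
#' @param seed,size,nSequences,amplitude,smoothness,cavityRadius,cavityCenter,nLandmarks,noiseSigma,contrast,landmarkMaxDist
#'   see \linkS4class{PhantomSpec}.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- PhantomSpec(seed = 1, size = 32, nLandmarks = 10)
#' @export
PhantomSpec <- function(seed = 1L, size = 64L, nSequences = 1L,
                        amplitude = 4, smoothness = 8, cavityRadius = 0,
                        cavityCenter = NA_real_, nLandmarks = 20L,
                        noiseSigma = 0.02, contrast = 1,
                        landmarkMaxDist = 40) {
  new("PhantomSpec", seed = as.integer(seed), size = as.integer(size),
      nSequences = as.integer(nSequences), amplitude = amplitude,
      smoothness = smoothness, cavityRadius = cavityRadius,
      cavityCenter = as.numeric(cavityCenter),
      nLandmarks = as.integer(nLandmarks), noiseSigma = noiseSigma,
      contrast = contrast, landmarkMaxDist = landmarkMaxDist)
}
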
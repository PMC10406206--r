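# Accessors and show methods. Slots are never touched directly by user code.

#' @name accessors
#' @title Accessors for grid-based objects
#'
#' @description `volumeData` returns the raw array, `voxelSpacing` the
#' per-axis voxel size in mm, `worldOrigin` the world position (mm) of the
#' first voxel center, `gridShape` the grid dimensions, `displacement` the
#' (nx, ny, nz, 3) displacement array of a field, `channels`/`seqLabels` the
#' channel list and labels of a multi-sequence volume, and
#' `landmarkCoords`/`landmarkLabels` the coordinate matrix and labels of a
#' landmark set.
#'
#' @param x the object.
#' @return The corresponding slot content.
#' @examples
#' v <- ScalarVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxelSpacing(v)
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))
#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setGeneric("seqLabels", function(x) standardGeneric("seqLabels"))
#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))
#' @rdname accessors
#' @export
setGeneric("landmarkLabels", function(x) standardGeneric("landmarkLabels"))

#' @rdname accessors
setMethod("volumeData", "ScalarVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "ScalarVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("worldOrigin", "ScalarVolume", function(x) x@origin)
#' @rdname accessors
setMethod("gridShape", "ScalarVolume", function(x) dim(x@data))
#' @rdname accessors
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @rdname accessors
setMethod("worldOrigin", "DisplacementField", function(x) x@origin)
#' @rdname accessors
setMethod("gridShape", "DisplacementField", function(x) dim(x@u)[1:3])
#' @rdname accessors
setMethod("displacement", "DisplacementField", function(x) x@u)
#' @rdname accessors
setMethod("channels", "MultiSequenceVolume", function(x) x@channels)
#' @rdname accessors
setMethod("seqLabels", "MultiSequenceVolume", function(x) x@labels)
#' @rdname accessors
setMethod("gridShape", "MultiSequenceVolume",
          function(x) dim(x@channels[[1L]]@data))
#' @rdname accessors
setMethod("voxelSpacing", "MultiSequenceVolume",
          function(x) x@channels[[1L]]@spacing)
#' @rdname accessors
setMethod("worldOrigin", "MultiSequenceVolume",
          function(x) x@channels[[1L]]@origin)
#' @rdname accessors
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)
#' @rdname accessors
setMethod("landmarkLabels", "LandmarkSet", function(x) x@labels)

#' @name result-accessors
#' @title Accessors for registration results and TRE reports
#' @param x the object.
#' @return `resultField` the estimated field at the original input grid,
#'   `workingField` the field at the working grid, `solveHistory` the
#'   per-level iteration traces, `objectiveComponents` the final objective
#'   terms; `treDistances` the per-landmark errors (mm), `treMean` their
#'   mean, `treBaselineMean` the mean without registration.
NULL

#' @rdname result-accessors
#' @export
setGeneric("resultField", function(x) standardGeneric("resultField"))
#' @rdname result-accessors
#' @export
setGeneric("workingField", function(x) standardGeneric("workingField"))
#' @rdname result-accessors
#' @export
setGeneric("solveHistory", function(x) standardGeneric("solveHistory"))
#' @rdname result-accessors
#' @export
setGeneric("objectiveComponents",
           function(x) standardGeneric("objectiveComponents"))
#' @rdname result-accessors
#' @export
setGeneric("treDistances", function(x) standardGeneric("treDistances"))
#' @rdname result-accessors
#' @export
setGeneric("treMean", function(x) standardGeneric("treMean"))
#' @rdname result-accessors
#' @export
setGeneric("treBaselineMean", function(x) standardGeneric("treBaselineMean"))

#' @rdname result-accessors
setMethod("resultField", "RegistrationResult", function(x) x@field)
#' @rdname result-accessors
setMethod("workingField", "RegistrationResult", function(x) x@workingField)
#' @rdname result-accessors
setMethod("solveHistory", "RegistrationResult", function(x) x@history)
#' @rdname result-accessors
setMethod("objectiveComponents", "RegistrationResult", function(x) x@components)
#' @rdname result-accessors
setMethod("treDistances", "TREReport", function(x) {
  stats::setNames(x@distances, x@labels)
})
#' @rdname result-accessors
setMethod("treMean", "TREReport", function(x) x@mean)
#' @rdname result-accessors
setMethod("treBaselineMean", "TREReport", function(x) x@baselineMean)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %dx%dx%d, spacing %s mm, origin %s mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "MultiSequenceVolume", function(object) {
  d <- gridShape(object)
  cat(sprintf("MultiSequenceVolume %dx%dx%d, %d channel(s): %s\n",
              d[1], d[2], d[3], length(object@channels),
              paste(object@labels, collapse = ", ")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@u)
  mag <- sqrt(object@u[, , , 1]^2 + object@u[, , , 2]^2 + object@u[, , , 3]^2)
  cat(sprintf("DisplacementField %dx%dx%d, spacing %s mm, |u| mean %.3g / max %.3g mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = "x"),
              mean(mag), max(mag)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet with %d point(s)\n", nrow(object@coords)))
  if (nrow(object@coords) > 0) {
    df <- data.frame(label = object@labels,
                     x = object@coords[, 1], y = object@coords[, 2],
                     z = object@coords[, 3])
    print(utils::head(df, 6))
    if (nrow(df) > 6) cat("...\n")
  }
})

setMethod("show", "RegistrationConfig", function(object) {
  cat("RegistrationConfig\n")
  cat(sprintf("  alpha: %g, gamma: %g (volume control %s)\n", object@alpha,
              object@gamma, if (object@volumeControl) "on" else "off"))
  cat(sprintf("  levels: %d, working size: %s\n", object@levels,
              if (is.na(object@workingSize)) "input grid" else object@workingSize))
  cat(sprintf("  edge parameters: %s\n",
              if (is.null(object@eps)) sprintf("auto (eta = %g)", object@epsEta)
              else sprintf("epsR = %g, epsT = %g", object@eps@epsR,
                           object@eps@epsT)))
  s <- object@stopping
  cat(sprintf("  stopping: progress %g, gradient %g, rel. gradient %g, step %g, max iter %d\n",
              s@minProgress, s@minGradient, s@minRelativeGradient,
              s@minStepLength, s@maxIterations))
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult\n")
  for (l in seq_along(object@history)) {
    h <- object@history[[l]]
    cat(sprintf("  level %d (%s): %d iteration(s), objective %.6g -> %.6g, stopped on %s\n",
                l, paste(h$shape, collapse = "x"), nrow(h$trace) - 1L,
                h$trace$objective[1L], h$trace$objective[nrow(h$trace)],
                h$reason))
  }
  cmp <- object@components
  cat(sprintf("  final terms: distance %.6g, curvature %.6g, volume %.6g\n",
              cmp["distance"], cmp["curvature"], cmp["volume"]))
  show(object@field)
})

setMethod("show", "TREReport", function(object) {
  cat(sprintf("TREReport: %d landmark(s), mean TRE %.4g mm (baseline %.4g mm)\n",
              length(object@distances), object@mean, object@baselineMean))
})
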
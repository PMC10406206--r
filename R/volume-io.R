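# NIfTI and landmark-table input/output, plus resampling onto the cubic
# working grid. Geometry convention after loading: axes are reordered to a
# canonical (RAS) order, world = origin + index * spacing with 0-based
# indices; any residual rotation in the stored transform is discarded.

niftiGeometry <- function(img) {
  x <- unclass(RNifti::xform(img))
  list(spacing = abs(RNifti::pixdim(img))[1:3], origin = as.numeric(x[1:3, 4]))
}

#' Read a NIfTI volume or pathology mask
#'
#' Loads a 3D NIfTI-1 image, reorients it to the canonical RAS axis order
#' and extracts spacing and origin from the header. Masks are binarized at
#' > 0.5; intensity volumes must be finite everywhere.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind `"intensity"` for a \linkS4class{ScalarVolume},
#'   `"mask"` for a \linkS4class{PathologyMask}.
#' @return A \linkS4class{ScalarVolume} or \linkS4class{PathologyMask}.
#' @seealso [writeVolume()], [resampleToCube()]
#' @export
readVolume <- function(path, kind = c("intensity", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path, call. = FALSE)
  ort <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ort, "try-error") && !is.na(ort) && nzchar(ort) && ort != "RAS")
    RNifti::orientation(img) <- "RAS"
  geo <- niftiGeometry(img)
  a <- array(as.numeric(img), dim = dim(img))
  if (kind == "mask")
    return(PathologyMask(a, spacing = geo$spacing, origin = geo$origin))
  if (anyNA(a) || any(is.infinite(a)))
    stop("intensity volume contains non-finite voxels: ", path, call. = FALSE)
  ScalarVolume(a, spacing = geo$spacing, origin = geo$origin)
}

niftiWithGeometry <- function(a, spacing, origin) {
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(a)) - 3L))
  aff <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  img
}

#' Write a volume or mask to NIfTI
#'
#' @param v a \linkS4class{ScalarVolume} (or \linkS4class{PathologyMask}).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "ScalarVolume"))
  img <- niftiWithGeometry(v@data, v@spacing, v@origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a displacement field as 5D NIfTI
#'
#' The field is stored in the common (nx, ny, nz, 1, 3) vector-image
#' dialect with components in world millimetres, so it interoperates with
#' standard registration toolchains.
#'
#' @param u a \linkS4class{DisplacementField}, finite everywhere.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDisplacementField <- function(u, path) {
  stopifnot(is(u, "DisplacementField"))
  if (anyNA(u@u) || any(is.infinite(u@u)))
    stop("displacement field contains non-finite components", call. = FALSE)
  d <- dim(u@u)
  a <- array(u@u, c(d[1:3], 1L, 3L))
  img <- niftiWithGeometry(a, u@spacing, u@origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field written by [writeDisplacementField()]
#'
#' @param path path to a 5D (nx, ny, nz, 1, 3) NIfTI.
#' @return A \linkS4class{DisplacementField}.
#' @export
readDisplacementField <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 5L || d[4] != 1L || d[5] != 3L)
    stop("expected a 5D (nx, ny, nz, 1, 3) displacement field: ", path,
         call. = FALSE)
  geo <- niftiGeometry(img)
  a <- array(as.numeric(img), dim = c(d[1:3], 3L))
  DisplacementField(a, spacing = geo$spacing,
                    origin = geo$origin)
}

#' Resample a volume onto a cubic grid
#'
#' Returns the volume on an `n`-cubed grid covering the same world extent,
#' with per-axis spacing rescaled accordingly — the working-grid preparation
#' step (clinical volumes are typically brought to a 160-cubed grid before
#' registration). Intensities use trilinear interpolation; masks must use
#' nearest-neighbour.
#'
#' @param v a \linkS4class{ScalarVolume} or \linkS4class{PathologyMask}.
#' @param n target edge length in voxels (>= 8).
#' @param order `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   masks and `"linear"` otherwise.
#' @return The resampled volume, same class as `v`.
#' @export
resampleToCube <- function(v, n, order = NULL) {
  stopifnot(is(v, "ScalarVolume"))
  n <- as.integer(n)
  if (n < 8L) stop("target edge length must be >= 8", call. = FALSE)
  isMask <- is(v, "PathologyMask")
  if (is.null(order)) order <- if (isMask) "nearest" else "linear"
  order <- match.arg(order, c("linear", "nearest"))
  if (isMask && order != "nearest")
    stop("masks must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  shape <- gridShape(v)
  extent <- shape * v@spacing                # covered world length per axis
  newSpacing <- extent / n
  newOrigin <- v@origin - v@spacing / 2 + newSpacing / 2
  pts <- gridPointsMatrix(c(n, n, n), newSpacing, newOrigin)
  res <- c_interp_points(as.numeric(v@data), as.integer(shape), v@spacing,
                         v@origin, pts, order == "nearest", FALSE)
  a <- array(res$values, c(n, n, n))
  if (isMask) PathologyMask(a, spacing = newSpacing, origin = newOrigin)
  else ScalarVolume(a, spacing = newSpacing, origin = newOrigin)
}

#' Read landmarks from CSV
#'
#' Expects a header `label,x,y,z` with world-mm coordinates, one row per
#' landmark; paired files must use the same labels in the same order.
#'
#' @param path CSV path.
#' @return A \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns label,x,y,z: ", path, call. = FALSE)
  LandmarkSet(as.matrix(df[, c("x", "y", "z")]), labels = as.character(df$label))
}

#' Write landmarks to CSV
#'
#' @param pts a \linkS4class{LandmarkSet}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(pts, path) {
  stopifnot(is(pts, "LandmarkSet"))
  df <- data.frame(label = pts@labels, x = pts@coords[, 1],
                   y = pts@coords[, 2], z = pts@coords[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
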
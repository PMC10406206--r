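# Deformations y(x) = x + u(x): warping, pyramid transfer, and field
# regularity analysis.

#' Warp an image by a displacement field
#'
#' Samples `t` at y(x) = x + u(x) for every voxel of the field's (fixed)
#' grid, using trilinear interpolation with clamp-to-edge extension outside
#' the template's domain.
#'
#' @param t the template (moving) \linkS4class{ScalarVolume}.
#' @param u a \linkS4class{DisplacementField} on the target grid.
#' @return The warped image T(y) as a \linkS4class{ScalarVolume} on `u`'s
#'   grid.
#' @examples
#' v <- ScalarVolume(array(rnorm(64), c(4, 4, 4)))
#' u <- DisplacementField(shape = c(4, 4, 4))
#' identical(volumeData(warpImage(v, u)), volumeData(v))
#' @export
warpImage <- function(t, u) {
  stopifnot(is(t, "ScalarVolume"), is(u, "DisplacementField"))
  shape <- gridShape(u)
  pts <- gridPointsMatrix(shape, u@spacing, u@origin)
  pts <- pts + matrix(u@u, ncol = 3L)
  res <- c_interp_points(as.numeric(t@data), as.integer(gridShape(t)),
                         t@spacing, t@origin, pts, FALSE, FALSE)
  ScalarVolume(array(res$values, shape), spacing = u@spacing,
               origin = u@origin)
}

#' Restrict a volume to the next-coarser pyramid level
#'
#' Halves every edge by 2x2x2 average pooling; spacing doubles and the
#' origin moves to the new cell centers so the covered world extent is
#' unchanged.
#'
#' @param v a \linkS4class{ScalarVolume} with even edges >= 2.
#' @return The coarsened \linkS4class{ScalarVolume}.
#' @export
restrictVolume <- function(v) {
  stopifnot(is(v, "ScalarVolume"))
  shape <- gridShape(v)
  if (any(shape < 2L) || any(shape %% 2L != 0L))
    stop("all edge lengths must be even and >= 2", call. = FALSE)
  a <- array(c_restrict_volume(as.numeric(v@data), as.integer(shape)),
             shape %/% 2L)
  ScalarVolume(a, spacing = 2 * v@spacing, origin = v@origin + v@spacing / 2)
}

#' Restrict a pathology mask across levels
#'
#' Average-pools the binary mask and re-binarizes at >= 0.5, approximately
#' preserving the pathology volume.
#'
#' @param m a \linkS4class{PathologyMask} with even edges.
#' @return The coarsened \linkS4class{PathologyMask}.
#' @export
restrictMask <- function(m) {
  stopifnot(is(m, "PathologyMask"))
  r <- restrictVolume(ScalarVolume(m@data, m@spacing, m@origin))
  PathologyMask(array(as.numeric(r@data >= 0.5), gridShape(r)),
                spacing = r@spacing, origin = r@origin)
}

#' Prolong a displacement field to a finer grid
#'
#' Trilinearly upsamples each component to the target grid. Displacements
#' are stored in world millimetres, so magnitudes are preserved without
#' rescaling. The target grid must cover the same world extent as the
#' field's grid (up to one coarse voxel).
#'
#' @param u a \linkS4class{DisplacementField}.
#' @param shape integer(3) target grid shape.
#' @param spacing,origin target grid geometry (mm).
#' @return The field resampled to the target grid.
#' @export
prolongField <- function(u, shape, spacing, origin) {
  stopifnot(is(u, "DisplacementField"))
  shape <- as.integer(shape)
  extC <- worldExtent(gridShape(u), u@spacing, u@origin)
  extF <- worldExtent(shape, spacing, origin)
  if (any(abs(extC - extF) > max(u@spacing) + 1e-6))
    stop("target grid does not cover the same world extent", call. = FALSE)
  pts <- gridPointsMatrix(shape, spacing, origin)
  out <- array(0, c(shape, 3L))
  for (k in 1:3) {
    res <- c_interp_points(as.numeric(u@u[, , , k]),
                           as.integer(gridShape(u)), u@spacing, u@origin,
                           pts, FALSE, FALSE)
    out[, , , k] <- res$values
  }
  DisplacementField(out, spacing = spacing, origin = origin)
}

# 3x3 determinant of F = I + Du from the stacked per-component gradients.
# du is a list of three (nvox, 3) matrices, du[[a]][, b] = d u_a / d x_b.
jacobianFromGradients <- function(du) {
  F11 <- 1 + du[[1]][, 1]; F12 <- du[[1]][, 2]; F13 <- du[[1]][, 3]
  F21 <- du[[2]][, 1]; F22 <- 1 + du[[2]][, 2]; F23 <- du[[2]][, 3]
  F31 <- du[[3]][, 1]; F32 <- du[[3]][, 2]; F33 <- 1 + du[[3]][, 3]
  F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}

displacementGradients <- function(u) {
  shape <- gridShape(u)
  lapply(1:3, function(a) {
    matrix(c_spatial_gradient(as.numeric(u@u[, , , a]), as.integer(shape),
                              u@spacing), ncol = 3L)
  })
}

#' Jacobian determinant of a deformation
#'
#' Computes det(∇y) = det(I + ∇u) voxelwise, with spacing-aware central
#' differences in the interior and one-sided differences on the boundary
#' faces. Values <= 0 indicate foldings (locally non-injective
#' deformation).
#'
#' @param u a \linkS4class{DisplacementField} with edges >= 3.
#' @return A \linkS4class{ScalarVolume} of determinants.
#' @seealso [foldingFraction()]
#' @export
jacobianDeterminant <- function(u) {
  stopifnot(is(u, "DisplacementField"))
  shape <- gridShape(u)
  if (any(shape < 3L)) stop("all edge lengths must be >= 3", call. = FALSE)
  det <- jacobianFromGradients(displacementGradients(u))
  ScalarVolume(array(det, shape), spacing = u@spacing, origin = u@origin)
}

#' Fraction of folded voxels
#'
#' @param u a \linkS4class{DisplacementField}.
#' @return The fraction of voxels with det(∇y) <= 0, in [0, 1].
#' @export
foldingFraction <- function(u) {
  det <- volumeData(jacobianDeterminant(u))
  mean(det <= 0)
}
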
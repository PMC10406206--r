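# Internal grid helpers.

gridOf <- function(x) {
  list(shape = gridShape(x), spacing = voxelSpacing(x),
       origin = worldOrigin(x))
}

sameGrid <- function(a, b, tol = 1e-6) {
  identical(as.integer(gridShape(a)), as.integer(gridShape(b))) &&
    all(abs(voxelSpacing(a) - voxelSpacing(b)) <= tol) &&
    all(abs(worldOrigin(a) - worldOrigin(b)) <= tol)
}

stopIfGridMismatch <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b))
    stop(what, " must share the same grid (shape, spacing, origin)",
         call. = FALSE)
  invisible(TRUE)
}

# World coordinates of all voxel centers as an (nvox, 3) matrix, fastest
# index first (matching R's array layout).
gridPointsMatrix <- function(shape, spacing, origin) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  cbind(rep(ax[[1]], times = shape[2] * shape[3]),
        rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
        rep(ax[[3]], each = shape[1] * shape[2]))
}

# Cell-covered world interval per axis: [origin - h/2, origin + (n-1/2) h].
worldExtent <- function(shape, spacing, origin) {
  rbind(low = origin - spacing / 2,
        high = origin + (shape - 0.5) * spacing)
}

voxelVolume <- function(spacing) prod(spacing)

fieldMagnitude <- function(u) {
  sqrt(u@u[, , , 1]^2 + u@u[, , , 2]^2 + u@u[, , , 3]^2)
}
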
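# Curvature regularization and volume-change control, with analytic
# gradients.

#' Curvature regularization energy
#'
#' Midpoint-rule sum over voxels of the squared discrete Laplacian of each
#' displacement component (the Laplacian of y = x + u equals that of u).
#' The 7-point spacing-aware stencil uses a natural boundary treatment —
#' second differences are only formed at interior points along each axis —
#' so every affine field has exactly zero energy and nonzero boundary
#' displacements are not penalized per se.
#'
#' @param u a \linkS4class{DisplacementField} with edges >= 3.
#' @return `list(value = nonnegative scalar, gradient = 4D array)` with the
#'   exact gradient of the energy.
#' @export
curvatureEnergy <- function(u) {
  stopifnot(is(u, "DisplacementField"))
  shape <- gridShape(u)
  if (any(shape < 3L)) stop("all edge lengths must be >= 3", call. = FALSE)
  res <- c_curvature(as.numeric(u@u), as.integer(shape), u@spacing)
  list(value = res$value, gradient = array(res$gradient, c(shape, 3L)))
}

#' Volume-change penalty function
#'
#' psi(t) = (t - 1)^2 / t for t > 0 and Inf for t <= 0: zero exactly at
#' volume preservation (t = 1), a barrier at folding (t <= 0), convex on
#' t > 0.
#'
#' @param t numeric vector of Jacobian determinants.
#' @return psi evaluated elementwise (Inf sentinel for t <= 0).
#' @examples
#' psi(c(1, 2, -0.5))  # 0, 0.5, Inf
#' @export
psi <- function(t) {
  out <- rep(Inf, length(t))
  pos <- is.finite(t) & t > 0
  out[pos] <- (t[pos] - 1)^2 / t[pos]
  out
}

psiPrime <- function(t) 1 - 1 / t^2

#' Volume-change control energy
#'
#' Midpoint-rule sum of psi(det ∇y) over the grid. Any voxel with a
#' non-positive determinant makes the energy the Inf sentinel (the line
#' search treats such steps as rejected); otherwise the exact analytic
#' gradient is returned, obtained through the cofactors of ∇y and the
#' adjoints of the difference stencils.
#'
#' @param u a \linkS4class{DisplacementField} with edges >= 3.
#' @return `list(value = scalar or Inf, gradient = 4D array or NULL when
#'   the value is Inf)`.
#' @export
volumeControlEnergy <- function(u) {
  stopifnot(is(u, "DisplacementField"))
  shape <- gridShape(u)
  if (any(shape < 3L)) stop("all edge lengths must be >= 3", call. = FALSE)
  h3 <- voxelVolume(u@spacing)
  du <- displacementGradients(u)
  det <- jacobianFromGradients(du)
  if (any(det <= 0)) return(list(value = Inf, gradient = NULL))
  value <- h3 * sum(psi(det))

  wp <- h3 * psiPrime(det)
  F11 <- 1 + du[[1]][, 1]; F12 <- du[[1]][, 2]; F13 <- du[[1]][, 3]
  F21 <- du[[2]][, 1]; F22 <- 1 + du[[2]][, 2]; F23 <- du[[2]][, 3]
  F31 <- du[[3]][, 1]; F32 <- du[[3]][, 2]; F33 <- 1 + du[[3]][, 3]
  # cofactor matrix C_ab = d det(F) / d F_ab
  cof <- list(
    cbind(F22 * F33 - F23 * F32, F23 * F31 - F21 * F33, F21 * F32 - F22 * F31),
    cbind(F13 * F32 - F12 * F33, F11 * F33 - F13 * F31, F12 * F31 - F11 * F32),
    cbind(F12 * F23 - F13 * F22, F13 * F21 - F11 * F23, F11 * F22 - F12 * F21))

  gradient <- array(0, c(shape, 3L))
  ishape <- as.integer(shape)
  for (a in 1:3) {
    w <- cof[[a]] * wp                       # (nvox, 3): weights on d u_a/d x_b
    gradient[, , , a] <- c_gradient_adjoint(as.numeric(w), ishape, u@spacing)
  }
  list(value = value, gradient = gradient)
}
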
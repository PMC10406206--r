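# Shared fixtures: small analytic volumes and fields, and a finite-
# difference gradient oracle used against the analytic derivatives.

# f(x) = slope * world-coordinate along `axis`
rampVolume <- function(n, axis = 1, slope = 1, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  idx <- list(seq_len(n) - 1, seq_len(n) - 1, seq_len(n) - 1)
  w <- origin[axis] + idx[[axis]] * spacing[axis]
  a <- array(0, c(n, n, n))
  perm <- slice.index(a, axis)
  a[] <- slope * w[perm]
  ScalarVolume(a, spacing = spacing, origin = origin)
}

smoothNoiseVolume <- function(n, seed = 1, sd = 1, passes = 2) {
  set.seed(seed)
  a <- array(rnorm(n^3, sd = sd), c(n, n, n))
  for (p in seq_len(passes)) {
    a <- (a +
            a[c(2:n, n), , ] + a[c(1, 1:(n - 1)), , ] +
            a[, c(2:n, n), ] + a[, c(1, 1:(n - 1)), ] +
            a[, , c(2:n, n)] + a[, , c(1, 1:(n - 1))]) / 7
  }
  ScalarVolume(a)
}

# random displacement with fractional voxel parts away from 0/1 so the
# trilinear interpolant is differentiable at every sample point
smoothTestField <- function(n, seed = 1, lo = 0.1, hi = 0.4) {
  set.seed(seed)
  DisplacementField(array(runif(n^3 * 3, lo, hi), c(n, n, n, 3)))
}

# central finite differences of fn (returning a scalar) at selected
# coordinates of a 4D displacement array
fdGradientAt <- function(fn, u0, idx, h = 1e-4) {
  vapply(idx, function(j) {
    up <- u0; up[j] <- up[j] + h
    um <- u0; um[j] <- um[j] - h
    (fn(up) - fn(um)) / (2 * h)
  }, numeric(1))
}

maxRelError <- function(analytic, reference) {
  max(abs(analytic - reference)) / max(max(abs(reference)), 1e-12)
}

affineField <- function(n, A, b = c(0, 0, 0), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  pts <- cbind(rep(origin[1] + (seq_len(n) - 1) * spacing[1],
                   times = n * n),
               rep(rep(origin[2] + (seq_len(n) - 1) * spacing[2], each = n),
                   times = n),
               rep(origin[3] + (seq_len(n) - 1) * spacing[3],
                   each = n * n))
  u <- pts %*% t(A)
  u <- sweep(u, 2, b, `+`)
  DisplacementField(array(u, c(n, n, n, 3)), spacing = spacing,
                    origin = origin)
}
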
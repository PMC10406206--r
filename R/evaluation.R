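# Landmark-based target registration error and the paired nonparametric
# comparison of registration conditions.

#' Map landmarks through a displacement field
#'
#' Each fixed-space point p is mapped to p + u(p), with u interpolated
#' trilinearly at p — the same direction in which the field warps the
#' moving image onto the fixed grid.
#'
#' @param pts a \linkS4class{LandmarkSet} in fixed (post-operative) space.
#' @param u a \linkS4class{DisplacementField}; all points must lie inside
#'   its world extent.
#' @return The mapped \linkS4class{LandmarkSet}.
#' @export
transformLandmarks <- function(pts, u) {
  stopifnot(is(pts, "LandmarkSet"), is(u, "DisplacementField"))
  ext <- worldExtent(gridShape(u), u@spacing, u@origin)
  for (a in 1:3)
    if (any(pts@coords[, a] < ext["low", a] - 1e-9 |
            pts@coords[, a] > ext["high", a] + 1e-9))
      stop("landmark outside the displacement field's world extent",
           call. = FALSE)
  shape <- as.integer(gridShape(u))
  shift <- vapply(1:3, function(k) {
    c_interp_points(as.numeric(u@u[, , , k]), shape, u@spacing, u@origin,
                    pts@coords, FALSE, FALSE)$values
  }, numeric(nrow(pts@coords)))
  LandmarkSet(pts@coords + matrix(shift, ncol = 3L), labels = pts@labels)
}

#' Target registration error of one case
#'
#' Per-landmark Euclidean distances between (optionally field-mapped)
#' fixed-space landmarks and their moving-space counterparts, plus their
#' mean. Without a field the result is the baseline error.
#'
#' @param fixedPts,movingPts paired \linkS4class{LandmarkSet}s (equal
#'   length, matching labels in order).
#' @param u optional \linkS4class{DisplacementField} applied to `fixedPts`
#'   before computing distances.
#' @return A \linkS4class{TREReport}.
#' @examples
#' a <- LandmarkSet(matrix(c(0, 0, 0, 1, 1, 1), 2, byrow = TRUE))
#' b <- LandmarkSet(matrix(c(3, 0, 0, 4, 1, 1), 2, byrow = TRUE))
#' treMean(computeTRE(a, b))  # 3
#' @export
computeTRE <- function(fixedPts, movingPts, u = NULL) {
  stopifnot(is(fixedPts, "LandmarkSet"), is(movingPts, "LandmarkSet"))
  if (nrow(fixedPts@coords) != nrow(movingPts@coords))
    stop("paired landmark sets must have equal length", call. = FALSE)
  if (!identical(fixedPts@labels, movingPts@labels))
    stop("paired landmark sets must have matching labels in order",
         call. = FALSE)
  baseline <- sqrt(rowSums((fixedPts@coords - movingPts@coords)^2))
  mapped <- if (is.null(u)) fixedPts else transformLandmarks(fixedPts, u)
  d <- sqrt(rowSums((mapped@coords - movingPts@coords)^2))
  new("TREReport", labels = fixedPts@labels, distances = as.numeric(d),
      mean = mean(d), baselineMean = mean(baseline))
}

#' Cohort mean target registration error
#'
#' The mTRE over a test cohort: the arithmetic mean of the per-case mean
#' errors.
#'
#' @param reports a nonempty list of \linkS4class{TREReport}s.
#' @param baseline use the baseline means instead of the post-registration
#'   means.
#' @return Scalar mTRE in mm.
#' @export
mtreOverCohort <- function(reports, baseline = FALSE) {
  if (length(reports) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(reports, is, logical(1), "TREReport")))
  if (baseline) mean(vapply(reports, treBaselineMean, numeric(1)))
  else mean(vapply(reports, treMean, numeric(1)))
}

#' Wilcoxon signed-rank test for paired registration errors
#'
#' Two-sided test of zero median difference between paired samples (e.g.
#' per-case TREs of two registration conditions). Zero differences are
#' discarded; ties get midranks. For n <= 25 retained pairs the p-value is
#' exact over the full sign-assignment distribution; beyond that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @return `list(statistic = V (sum of positive ranks), pValue, n, exact)`.
#' @examples
#' a <- c(1, 2, 3, 4, 5, 6, 7, 8)
#' wilcoxonSignedRank(a, a + 1)$pValue  # 2 / 2^8
#' @export
wilcoxonSignedRank <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  if (n < 5) stop("fewer than 5 nonzero differences", call. = FALSE)
  r <- rank(abs(d))                     # midranks for ties
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of V over the 2^n equiprobable sign assignments,
    # via the rank generating function on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))     # counts[w + 1] = #assignments with 2V = w
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- as.integer(round(2 * v))
    pLow <- sum(counts[seq_len(v2 + 1L)]) / total
    pHigh <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(statistic = v, pValue = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tieTable <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tieTable^3 - tieTable) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = v, pValue = min(1, p), n = n, exact = FALSE)
}
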
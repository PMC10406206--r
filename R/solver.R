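# Objective assembly and the multi-level quasi-Newton solve.
#
# J(u) = D(R, T(y)) + alpha * S(u) [+ gamma * V(u)], minimized with
# limited-memory BFGS (memory 5, Armijo backtracking) per level,
# coarsest-to-finest, with the prolonged field as each finer level's
# starting iterate.

#' Registration objective and gradient
#'
#' Assembles the full objective — masked multi-channel NGF distance plus
#' `alpha` times the curvature energy, plus `gamma` times the
#' volume-change control when enabled — and its analytic gradient.
#'
#' @param u \linkS4class{DisplacementField} on the fixed grid.
#' @param fixed,moving \linkS4class{MultiSequenceVolume}s on that grid.
#' @param mask optional \linkS4class{PathologyMask} (ignored when
#'   `config@maskDistance` is FALSE).
#' @param config a \linkS4class{RegistrationConfig}; NULL `config@eps`
#'   triggers automatic estimation from `fixed`/`moving`.
#' @return `list(value, gradient, components)` where `components` is the
#'   named vector of the distance, curvature and volume terms (unweighted).
#' @export
registrationObjective <- function(u, fixed, moving, mask = NULL, config) {
  if (is(fixed, "ScalarVolume")) fixed <- MultiSequenceVolume(fixed)
  if (is(moving, "ScalarVolume")) moving <- MultiSequenceVolume(moving)
  localObjective(u, fixed, moving, mask, config,
                 resolveEps(config, fixed, moving))
}

resolveEps <- function(config, fixed, moving) {
  if (!is.null(config@eps)) return(config@eps)
  lapply(seq_along(fixed@channels), function(ch) {
    EdgeParameters(
      epsR = estimateEdgeParameter(fixed@channels[[ch]], config@epsEta),
      epsT = estimateEdgeParameter(moving@channels[[ch]], config@epsEta))
  })
}

#' Limited-memory BFGS with Armijo backtracking
#'
#' Minimizes `fn` (which must return `list(value, gradient)` over a numeric
#' vector) with the two-loop l-BFGS recursion (memory 5). The line search
#' backtracks by halving with an Armijo slope of 1e-4 and rejects
#' non-finite objective values (the Inf sentinel of the volume-change
#' barrier). The iteration terminates on the first satisfied stopping
#' criterion; accepted iterates have strictly non-increasing objective.
#'
#' @param fn objective closure: `fn(x)` returns `list(value, gradient)`.
#' @param x0 numeric starting vector (finite objective required).
#' @param stopping a \linkS4class{StoppingCriteria}.
#' @param verbose print a per-iteration trace.
#' @return `list(x, value, gradientNorm, iterations, reason, trace)`;
#'   `trace` is a data.frame with one row per accepted iterate (row 1 is
#'   the start), `reason` one of `min_progress`, `min_gradient`,
#'   `min_relative_gradient`, `min_step_length`, `max_iterations`,
#'   `line_search_failure`.
#' @examples
#' quad <- function(x) list(value = 0.5 * sum((x - 2)^2), gradient = x - 2)
#' fit <- lbfgsMinimize(quad, rep(0, 5), StoppingCriteria())
#' fit$x
#' @export
lbfgsMinimize <- function(fn, x0, stopping = StoppingCriteria(),
                          verbose = FALSE) {
  m <- 5L
  x <- as.numeric(x0)
  ev <- fn(x)
  if (!is.finite(ev$value))
    stop("objective is not finite at the starting point", call. = FALSE)
  f <- ev$value
  g <- as.numeric(ev$gradient)
  g0norm <- sqrt(sum(g^2))
  trace <- list(data.frame(iteration = 0L, objective = f,
                           gradientNorm = g0norm, step = NA_real_))
  S <- list(); Y <- list(); RHO <- list()
  reason <- NULL
  iter <- 0L

  if (g0norm < stopping@minGradient) {
    reason <- "min_gradient"
  } else {
    repeat {
      # two-loop recursion
      q <- g
      np <- length(S)
      alpha <- numeric(np)
      if (np > 0) {
        for (i in np:1) {
          alpha[i] <- RHO[[i]] * sum(S[[i]] * q)
          q <- q - alpha[i] * Y[[i]]
        }
        gammaScale <- sum(S[[np]] * Y[[np]]) / sum(Y[[np]] * Y[[np]])
        q <- gammaScale * q
        for (i in 1:np) {
          beta <- RHO[[i]] * sum(Y[[i]] * q)
          q <- q + (alpha[i] - beta) * S[[i]]
        }
      }
      d <- -q
      slope <- sum(d * g)
      if (!is.finite(slope) || slope >= 0) {      # not a descent direction
        S <- list(); Y <- list(); RHO <- list()
        d <- -g
        slope <- -sum(g^2)
      }

      # Armijo backtracking; reject non-finite (barrier) values
      t <- 1
      accepted <- FALSE
      dmax <- max(abs(d))
      repeat {
        xn <- x + t * d
        en <- fn(xn)
        if (is.finite(en$value) && en$value <= f + 1e-4 * t * slope) {
          accepted <- TRUE
          break
        }
        t <- t / 2
        if (t * dmax < stopping@minStepLength / 2 || t < 1e-14) break
      }
      if (!accepted) {
        reason <- if (t * dmax < stopping@minStepLength / 2)
          "min_step_length" else "line_search_failure"
        break
      }

      iter <- iter + 1L
      s <- t * d
      gn <- as.numeric(en$gradient)
      y <- gn - g
      progress <- f - en$value
      stepLen <- t * dmax
      x <- xn; f <- en$value; g <- gn
      sy <- sum(s * y)
      if (sy > 1e-12) {
        S <- c(S, list(s)); Y <- c(Y, list(y)); RHO <- c(RHO, list(1 / sy))
        if (length(S) > m) { S <- S[-1]; Y <- Y[-1]; RHO <- RHO[-1] }
      }
      gnorm <- sqrt(sum(g^2))
      trace[[length(trace) + 1L]] <-
        data.frame(iteration = iter, objective = f, gradientNorm = gnorm,
                   step = stepLen)
      if (verbose)
        message(sprintf("  iter %3d  J = %.6g  |g| = %.4g  step = %.4g",
                        iter, f, gnorm, stepLen))

      if (gnorm < stopping@minGradient) { reason <- "min_gradient"; break }
      if (gnorm / g0norm < stopping@minRelativeGradient) {
        reason <- "min_relative_gradient"; break
      }
      if (progress < stopping@minProgress) { reason <- "min_progress"; break }
      if (stepLen < stopping@minStepLength) {
        reason <- "min_step_length"; break
      }
      if (iter >= stopping@maxIterations) { reason <- "max_iterations"; break }
    }
  }
  list(x = x, value = f, gradientNorm = sqrt(sum(g^2)), iterations = iter,
       reason = reason, trace = do.call(rbind, trace))
}

restrictChannels <- function(ms) {
  MultiSequenceVolume(lapply(ms@channels, restrictVolume), ms@labels)
}

#' Multi-level deformable registration
#'
#' Registers a moving (pre-operative) volume onto a fixed (post-operative)
#' volume by minimizing masked NGF distance plus curvature regularization
#' (and optionally volume-change control) with l-BFGS on a coarse-to-fine
#' pyramid. Inputs are resampled to the cubic working grid, restricted
#' `levels - 1` times (the coarsest level is downsampled by
#' 2^(levels - 1)), and the zero-initialized coarsest solve is prolonged as
#' the starting iterate of each finer level. The final field is prolonged
#' back to the input volumes' original grid. The whole solve is
#' deterministic: identical inputs and config give identical results.
#'
#' @param fixed,moving \linkS4class{MultiSequenceVolume} (or single
#'   \linkS4class{ScalarVolume}) with matching channel counts; assumed
#'   rigidly pre-aligned.
#' @param mask optional \linkS4class{PathologyMask} on the fixed grid,
#'   marking fixed-image tissue without a counterpart in the moving image.
#' @param config a \linkS4class{RegistrationConfig}.
#' @return A \linkS4class{RegistrationResult}.
#' @examples
#' \donttest{
#' ph <- generatePhantomPair(PhantomSpec(seed = 1, size = 32, nLandmarks = 5))
#' cfg <- RegistrationConfig(levels = 2, workingSize = 32)
#' res <- registerPair(ph$fixed, ph$moving, config = cfg)
#' res
#' }
#' @export
registerPair <- function(fixed, moving, mask = NULL,
                         config = RegistrationConfig()) {
  if (is(fixed, "ScalarVolume")) fixed <- MultiSequenceVolume(fixed)
  if (is(moving, "ScalarVolume")) moving <- MultiSequenceVolume(moving)
  stopifnot(is(fixed, "MultiSequenceVolume"), is(moving, "MultiSequenceVolume"),
            is(config, "RegistrationConfig"))
  if (length(fixed@channels) != length(moving@channels))
    stop("fixed and moving must have the same number of channels",
         call. = FALSE)
  if (!is.null(mask)) {
    stopifnot(is(mask, "PathologyMask"))
    stopIfGridMismatch(fixed@channels[[1L]], mask, "fixed volume and mask")
  }
  for (ch in fixed@channels)
    if (max(ch@data) - min(ch@data) <= 0)
      stop("fixed image is constant; registration is degenerate",
           call. = FALSE)

  originalGrid <- gridOf(fixed@channels[[1L]])

  # bring inputs onto the cubic working grid
  n <- config@workingSize
  if (!is.na(n) &&
      !(all(gridShape(fixed) == n) &&
        length(unique(voxelSpacing(fixed))) == 1L)) {
    fixed <- MultiSequenceVolume(lapply(fixed@channels, resampleToCube, n = n),
                                 fixed@labels)
    moving <- MultiSequenceVolume(lapply(moving@channels, resampleToCube,
                                         n = n), moving@labels)
    if (!is.null(mask)) mask <- resampleToCube(mask, n)
  }
  L <- config@levels
  workShape <- gridShape(fixed)
  if (any(workShape %% 2L^(L - 1L) != 0L))
    stop("working grid must be divisible by 2^(levels - 1)", call. = FALSE)

  fixedPyr <- vector("list", L); movingPyr <- vector("list", L)
  maskPyr <- vector("list", L)
  fixedPyr[[1L]] <- fixed; movingPyr[[1L]] <- moving
  maskPyr[1L] <- list(mask)
  if (L > 1L) for (l in 2:L) {
    fixedPyr[[l]] <- restrictChannels(fixedPyr[[l - 1L]])
    movingPyr[[l]] <- restrictChannels(movingPyr[[l - 1L]])
    maskPyr[l] <- list(if (is.null(mask)) NULL
                       else restrictMask(maskPyr[[l - 1L]]))
  }

  history <- vector("list", L)
  u <- NULL
  for (l in L:1) {
    fx <- fixedPyr[[l]]; mv <- movingPyr[[l]]; mk <- maskPyr[[l]]
    grid <- gridOf(fx@channels[[1L]])
    u <- if (is.null(u)) {
      DisplacementField(shape = grid$shape, spacing = grid$spacing,
                        origin = grid$origin)
    } else {
      prolongField(u, grid$shape, grid$spacing, grid$origin)
    }
    eps <- resolveEps(config, fx, mv)
    shape4 <- c(grid$shape, 3L)
    grCache <- lapply(fx@channels, function(ch)
      c_spatial_gradient(as.numeric(ch@data), as.integer(grid$shape),
                         ch@spacing))
    fn <- function(xvec) {
      uf <- DisplacementField(array(xvec, shape4), spacing = grid$spacing,
                              origin = grid$origin)
      ob <- localObjective(uf, fx, mv, mk, config, eps, grCache)
      list(value = ob$value, gradient = ob$gradient)
    }
    if (config@verbose)
      message(sprintf("level %d/%d (%s)", L - l + 1L, L,
                      paste(grid$shape, collapse = "x")))
    sol <- lbfgsMinimize(fn, as.numeric(u@u), config@stopping,
                         verbose = config@verbose)
    u <- DisplacementField(array(sol$x, shape4), spacing = grid$spacing,
                           origin = grid$origin)
    history[[L - l + 1L]] <- list(shape = grid$shape, trace = sol$trace,
                                  reason = sol$reason,
                                  iterations = sol$iterations)
  }

  finalObj <- localObjective(u, fixedPyr[[1L]], movingPyr[[1L]],
                             maskPyr[[1L]], config,
                             resolveEps(config, fixedPyr[[1L]],
                                        movingPyr[[1L]]))
  components <- c(finalObj$components, objective = finalObj$value)

  fieldOriginal <- if (identical(as.integer(originalGrid$shape),
                                 as.integer(gridShape(u))) &&
                       all(abs(originalGrid$spacing - u@spacing) < 1e-9))
    u
  else
    prolongField(u, originalGrid$shape, originalGrid$spacing,
                 originalGrid$origin)

  new("RegistrationResult", field = fieldOriginal, workingField = u,
      history = history, components = components)
}

# Objective with a pre-resolved eps (avoids re-estimating per evaluation).
localObjective <- function(u, fixed, moving, mask, config, eps,
                           grCache = NULL) {
  if (!config@maskDistance) mask <- NULL
  d <- multichannelDistance(fixed, moving, u, mask = mask, eps = eps,
                            grCache = grCache)
  cv <- curvatureEnergy(u)
  value <- d$value + config@alpha * cv$value
  vterm <- 0
  if (config@volumeControl && config@gamma > 0) {
    vc <- volumeControlEnergy(u)
    vterm <- vc$value
    if (!is.finite(vc$value))
      return(list(value = Inf, gradient = NULL,
                  components = c(distance = d$value, curvature = cv$value,
                                 volume = Inf)))
    value <- value + config@gamma * vc$value
    gradient <- d$gradient + config@alpha * cv$gradient +
      config@gamma * vc$gradient
    return(list(value = value, gradient = gradient,
                components = c(distance = d$value, curvature = cv$value,
                               volume = vterm)))
  }
  list(value = value, gradient = d$gradient + config@alpha * cv$gradient,
       components = c(distance = d$value, curvature = cv$value,
                      volume = vterm))
}
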
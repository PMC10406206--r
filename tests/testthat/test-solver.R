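# Solver tests run on small grids with reduced iteration caps; the full
# study conditions are exercised by the acceptance suite.

test_that("objective equals the sum of its component terms", {
  n <- 10
  fixed <- smoothNoiseVolume(n, seed = 60)
  moving <- smoothNoiseVolume(n, seed = 61)
  u <- smoothTestField(n, seed = 62, lo = -0.3, hi = 0.3)
  eps <- EdgeParameters(0.05)
  cfg <- RegistrationConfig(alpha = 0.2, gamma = 0.05, volumeControl = TRUE,
                            workingSize = NA, eps = eps)
  ob <- registrationObjective(u, fixed, moving, NULL, cfg)
  d <- ngfDistanceGradient(fixed, moving, u, eps = eps)
  cv <- curvatureEnergy(u)
  vc <- volumeControlEnergy(u)
  expect_equal(ob$value, d$value + 0.2 * cv$value + 0.05 * vc$value,
               tolerance = 1e-12)
  expect_equal(ob$gradient,
               d$gradient + 0.2 * cv$gradient + 0.05 * vc$gradient,
               tolerance = 1e-12)
  expect_equal(unname(ob$components["distance"]), d$value)
})

test_that("degenerate objectives vanish", {
  n <- 8
  v <- smoothNoiseVolume(n, seed = 63)
  m <- PathologyMask(array(1, c(n, n, n)))
  u <- DisplacementField(shape = c(n, n, n))
  cfg0 <- RegistrationConfig(alpha = 0, workingSize = NA,
                             eps = EdgeParameters(0.05))
  ob <- registrationObjective(u, v, v, m, cfg0)
  expect_equal(ob$value, 0)
  expect_equal(max(abs(ob$gradient)), 0)

  cst <- ScalarVolume(array(1, c(n, n, n)))
  cfg1 <- RegistrationConfig(alpha = 0.5, workingSize = NA,
                             eps = EdgeParameters(0.05))
  ob2 <- registrationObjective(u, cst, cst, NULL, cfg1)
  expect_equal(ob2$value, 0)
})

test_that("l-BFGS minimizes a convex quadratic", {
  c0 <- seq(-2, 2, length.out = 20)
  quad <- function(x) list(value = 0.5 * sum((x - c0)^2), gradient = x - c0)
  fit <- lbfgsMinimize(quad, rep(0, 20), StoppingCriteria())
  expect_lt(sqrt(sum((fit$x - c0)^2)), 1e-2)
  expect_lte(fit$iterations, 5)
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
})

test_that("l-BFGS stopping criteria trigger as specified", {
  quad <- function(x) list(value = 0.5 * sum(x^2), gradient = x)
  atMin <- lbfgsMinimize(quad, rep(1e-5, 10), StoppingCriteria())
  expect_equal(atMin$iterations, 0)
  expect_equal(atMin$reason, "min_gradient")

  # ill-conditioned quadratic cannot finish in one step
  q <- c(100, rep(0.01, 9))
  hard <- function(x) list(value = 0.5 * sum(q * x^2), gradient = q * x)
  one <- lbfgsMinimize(hard, rep(1, 10),
                       StoppingCriteria(maxIterations = 1L,
                                        minProgress = 1e-12,
                                        minGradient = 1e-12,
                                        minRelativeGradient = 1e-12,
                                        minStepLength = 1e-12))
  expect_equal(one$iterations, 1L)
  expect_equal(one$reason, "max_iterations")
  expect_error(lbfgsMinimize(function(x) list(value = Inf, gradient = x),
                             rep(1, 3), StoppingCriteria()), "finite")
})

test_that("line search rejects barrier (Inf) values", {
  # f has a pole barrier at x = 1; the step toward it must be damped
  f <- function(x) {
    if (any(x >= 1)) return(list(value = Inf, gradient = NULL))
    list(value = sum(-log(1 - x) + 10 * x^2) - 0,
         gradient = 1 / (1 - x) + 20 * x)
  }
  fit <- lbfgsMinimize(f, rep(0.9, 4), StoppingCriteria(maxIterations = 50))
  expect_true(all(fit$x < 1))
  expect_true(is.finite(fit$value))
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
})

test_that("self-registration stays at the identity", {
  ph <- generatePhantomPair(PhantomSpec(seed = 8, size = 32, nLandmarks = 5,
                                        amplitude = 3, smoothness = 6))
  cfg <- RegistrationConfig(levels = 2, workingSize = NA,
                            stopping = StoppingCriteria(maxIterations = 25L))
  res <- registerPair(ph$fixed, ph$fixed, config = cfg)
  u <- displacement(resultField(res))
  meanMag <- mean(sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
  expect_lt(meanMag, 0.1)
  for (h in solveHistory(res)) {
    expect_true(all(diff(h$trace$objective) <= 1e-12))
    expect_lte(h$trace$objective[nrow(h$trace)], h$trace$objective[1])
  }
})

test_that("registration is deterministic", {
  ph <- generatePhantomPair(PhantomSpec(seed = 12, size = 24, nLandmarks = 5,
                                        amplitude = 2, smoothness = 5))
  cfg <- RegistrationConfig(levels = 2, workingSize = NA,
                            stopping = StoppingCriteria(maxIterations = 10L))
  r1 <- registerPair(ph$fixed, ph$moving, config = cfg)
  r2 <- registerPair(ph$fixed, ph$moving, config = cfg)
  expect_identical(displacement(resultField(r1)),
                   displacement(resultField(r2)))
  expect_identical(solveHistory(r1)[[1]]$trace, solveHistory(r2)[[1]]$trace)
})

test_that("a single-level run equals the direct finest-level solve", {
  ph <- generatePhantomPair(PhantomSpec(seed = 13, size = 24, nLandmarks = 5,
                                        amplitude = 2, smoothness = 5))
  stopping <- StoppingCriteria(maxIterations = 15L)
  cfg <- RegistrationConfig(levels = 1, workingSize = NA,
                            stopping = stopping)
  res <- registerPair(ph$fixed, ph$moving, config = cfg)

  # direct solve of the same objective from the zero field
  eps <- list(EdgeParameters(
    estimateEdgeParameter(channels(ph$fixed)[[1]]),
    estimateEdgeParameter(channels(ph$moving)[[1]])))
  shape4 <- c(24, 24, 24, 3)
  fn <- function(x) {
    ob <- registrationObjective(DisplacementField(array(x, shape4)),
                                ph$fixed, ph$moving, NULL,
                                RegistrationConfig(workingSize = NA,
                                                   eps = eps[[1]]))
    list(value = ob$value, gradient = ob$gradient)
  }
  direct <- lbfgsMinimize(fn, numeric(24^3 * 3), stopping)
  expect_identical(as.numeric(displacement(resultField(res))), direct$x)
})

test_that("stronger curvature weighting yields smoother fields", {
  ph <- generatePhantomPair(PhantomSpec(seed = 14, size = 24, nLandmarks = 5,
                                        amplitude = 3, smoothness = 5))
  stopping <- StoppingCriteria(maxIterations = 30L)
  rLow <- registerPair(ph$fixed, ph$moving,
                       config = RegistrationConfig(alpha = 0.1, levels = 2,
                                                   workingSize = NA,
                                                   stopping = stopping))
  rHigh <- registerPair(ph$fixed, ph$moving,
                        config = RegistrationConfig(alpha = 10, levels = 2,
                                                    workingSize = NA,
                                                    stopping = stopping))
  cLow <- curvatureEnergy(workingField(rLow))$value
  cHigh <- curvatureEnergy(workingField(rHigh))$value
  expect_lt(cHigh, cLow)
})

test_that("volume-change control keeps the deformation fold-free", {
  ph <- generatePhantomPair(PhantomSpec(seed = 15, size = 24, nLandmarks = 5,
                                        amplitude = 3, smoothness = 5))
  cfg <- RegistrationConfig(levels = 2, workingSize = NA,
                            volumeControl = TRUE,
                            stopping = StoppingCriteria(maxIterations = 30L))
  res <- registerPair(ph$fixed, ph$moving, config = cfg)
  expect_equal(foldingFraction(workingField(res)), 0)
  expect_true(is.finite(objectiveComponents(res)["volume"]))
})

test_that("inconsistent inputs are rejected", {
  ph <- generatePhantomPair(PhantomSpec(seed = 16, size = 24, nLandmarks = 5,
                                        nSequences = 2, amplitude = 2,
                                        smoothness = 5))
  single <- MultiSequenceVolume(channels(ph$moving)[1])
  expect_error(registerPair(ph$fixed, single,
                            config = RegistrationConfig(workingSize = NA)),
               "channels")
  cst <- MultiSequenceVolume(ScalarVolume(array(1, c(24, 24, 24))))
  expect_error(registerPair(cst, cst,
                            config = RegistrationConfig(workingSize = NA)),
               "constant")
  badMask <- PathologyMask(array(0, c(12, 12, 12)))
  expect_error(registerPair(ph$fixed, ph$moving, mask = badMask,
                            config = RegistrationConfig(workingSize = NA)),
               "grid")
})
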
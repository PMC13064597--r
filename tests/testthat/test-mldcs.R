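test_that("training sets have the advertised shape, prior and determinism", {
  cfg <- trainingConfig(nTrain = 200, seed = 81)
  ds <- generateTrainingSet(cfg)
  expect_equal(dim(ds$windows), c(1000L, 200L))
  expect_true(all(ds$tauC > 0 & ds$tauC <= 2))
  # per-window normalization: zero mean, unit (population) variance
  expect_lt(max(abs(colMeans(ds$windows))), 1e-12)
  expect_lt(max(abs(colMeans(ds$windows^2) - 1)), 1e-9)

  ds2 <- generateTrainingSet(cfg)
  expect_identical(ds, ds2)

  # labels approximately uniform on (0, 2]
  big <- generateTrainingSet(trainingConfig(nTrain = 4000, seed = 82))
  ks <- stats::ks.test(big$tauC, "punif", 0, 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("the Butterworth denoiser is a zero-phase low-pass", {
  # DC passthrough
  expect_equal(butterworthLowpass(rep(7, 100)), rep(7, 100), tolerance = 1e-10)

  # a sinusoid well above the cutoff is attenuated as the squared
  # first-order magnitude response (forward-backward = |H|^2); the digital
  # (bilinear, prewarped) closed form uses tangents of the frequencies
  n <- 1000; fRel <- 0.45  # fraction of Nyquist; cutoff is 0.1
  x <- sin(pi * fRel * seq_len(n))
  y <- butterworthLowpass(x)
  core <- 101:900  # ignore edges
  gain <- sqrt(mean(y[core]^2) / mean(x[core]^2))
  analytic <- 1 / (1 + (tan(pi * fRel / 2) / tan(pi * 0.1 / 2))^2)
  expect_lt(abs(gain - analytic) / analytic, 0.05)
  expect_lt(gain, 1)

  # low-pass energy reduction on white noise
  set.seed(83)
  w <- stats::rnorm(2000)
  expect_lt(stats::var(butterworthLowpass(w)), stats::var(w))

  expect_error(butterworthLowpass(c(1, 2, 3)), "too short")
})

test_that("training succeeds on a separable set and fails on shuffled labels", {
  # two widely separated decorrelation times are learnt almost immediately
  n <- 300
  tau <- rep(c(0.1, 1.9), n / 2)
  X <- vapply(tau, function(tc) simulatePixelIntensity(tc, 1000, 100),
              numeric(1000))
  set.seed(84)
  ds <- list(windows = speckleRheo:::.normalizeWindows(X)$windows, tauC = tau)
  cfg <- trainingConfig(nTrain = n, seed = 85, maxEpochs = 6L)
  mdl <- trainRegressor(ds, cfg)
  expect_true(mdl@targetReached)
  expect_lt(utils::tail(mdl@history$valMAPE, 1), 5)

  # shuffled labels: no signal, the target is not reached
  dsShuf <- list(windows = ds$windows,
                 tauC = ds$tauC[c(seq(2, n, 2), seq(1, n, 2))])
  mdlShuf <- trainRegressor(dsShuf, cfg)
  expect_false(mdlShuf@targetReached)
  expect_gt(utils::tail(mdlShuf@history$valMAPE, 1), 5)
})

test_that("the regressor serializes losslessly and enforces its input schema", {
  mdl <- sharedRegressor()
  f <- tempfile(fileext = ".rds")
  saveRegressor(mdl, f)
  m2 <- loadRegressor(f)
  w <- cbind(simulatePixelIntensity(0.5, 1000, 100, seed = 86),
             simulatePixelIntensity(1.5, 1000, 100, seed = 87))
  expect_identical(predictTauC(mdl, w), predictTauC(m2, w))
  expect_equal(m2@history, mdl@history)

  expect_error(predictTauC(mdl, matrix(1, 500, 2)), "length")
})

test_that("predictions increase with the true decorrelation time", {
  mdl <- sharedRegressor()
  grid <- c(0.1, 0.5, 1.0, 1.8)
  meanPred <- vapply(seq_along(grid), function(i) {
    ph <- simulateStack(phantomSpec(1, 60, 1000, fps = 100, exposureUs = 0,
                                    backgroundTauC = grid[i], seed = 90L + i))
    X <- frames(ph$stack); dim(X) <- c(1000, 60)
    mean(predictTauC(mdl, X))
  }, 0)
  expect_true(all(diff(meanPred) > 0))
  expect_true(all(meanPred > 0 & meanPred <= 2))
})

test_that("mldcsMap tiles, averages and validates correctly", {
  mdl <- sharedRegressor()

  # 60 s at 100 fps: exactly 6 non-overlapping windows per pixel
  ph <- simulateStack(phantomSpec(2, 2, 6000, backgroundTauC = 0.5, seed = 95))
  tm <- mldcsMap(ph$stack, mdl)
  expect_equal(attr(tm, "nWindows"), 6L)
  expect_equal(methodTag(tm), "mldcs")
  expect_true(all(validMask(tm)))

  # the across-window mean equals the mean of per-window predictions
  X <- frames(ph$stack); dim(X) <- c(6000, 4)
  Xf <- butterworthLowpass(X)
  w1 <- predictTauC(mdl, Xf[1:1000, 1])
  w <- vapply(0:5, function(k) predictTauC(mdl, Xf[(k * 1000 + 1):((k + 1) * 1000), 1]), 0)
  expect_equal(tauC(tm)[1, 1], mean(w))

  # duration and frame-rate contracts
  short <- simulateStack(phantomSpec(2, 2, 500, backgroundTauC = 0.5, seed = 96))
  expect_error(mldcsMap(short$stack, mdl), "below one model window")
  wrongFps <- SpeckleStack(frames(ph$stack), fps = 50, exposureUs = 9500)
  expect_error(mldcsMap(wrongFps, mdl), "frame rate")

  # a static (constant) pixel is flagged invalid, not propagated as a number
  f <- frames(ph$stack); f[, 1, 1] <- 3
  tm2 <- mldcsMap(SpeckleStack(f, fps = 100, exposureUs = 9500), mdl)
  expect_false(validMask(tm2)[1, 1])
  expect_equal(reasonCodes(tm2)[1, 1], "constant series")
  expect_true(all(validMask(tm2)[-1]))
})

test_that("averaging windows reduces prediction variance", {
  mdl <- sharedRegressor()
  nRep <- 30
  singles <- numeric(nRep); means6 <- numeric(nRep)
  for (r in seq_len(nRep)) {
    x <- simulatePixelIntensity(0.5, 6000, 100, seed = 200L + r)
    X <- matrix(x[1:6000], 1000, 6)
    p <- predictTauC(mdl, X)
    singles[r] <- p[1]
    means6[r] <- mean(p)
  }
  expect_lt(stats::var(means6), stats::var(singles))
})
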
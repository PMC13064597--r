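# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# The standard lesion phantom: stiff (slow) elliptical lesion in the upper
# hemisphere on a faster background, >= 1000 pixels per ROI, with the
# mirrored control ROI in the lower hemisphere not overlapping the lesion.
standardPhantomSpec <- function(nFrames, backgroundTauC = 0.39, lesionTauC = 0.67,
                                seed = 101L) {
  phantomSpec(64, 48, nFrames, fps = 100, exposureUs = 9500,
              backgroundTauC = backgroundTauC,
              lesions = list(list(row = 17, col = 24, a = 15, b = 22,
                                  tauC = lesionTauC)),
              beta = 1, meanIntensity = 100, seed = seed)
}

# 60 s standard phantom acquisition (simulated once, shared).
standardPhantom60s <- function() {
  .cached("phantom60", function() simulateStack(standardPhantomSpec(6000)))
}

# 10 s acquisition of the same scene.
standardPhantom10s <- function() {
  .cached("phantom10", function() simulateStack(standardPhantomSpec(1000)))
}

# A small trained regressor shared by the ML tests (modest training set:
# enough to learn the monotone mapping, quick enough for a test run).
sharedRegressor <- function() {
  .cached("regressor", function() {
    cfg <- trainingConfig(nTrain = 2500, seed = 404L, maxEpochs = 16L)
    trainRegressor(generateTrainingSet(cfg), cfg)
  })
}

# Brute-force O(T*L) double-loop g2 oracle (independent of the package's
# FFT-based implementation).
bruteForceG2 <- function(series, maxLagFrames) {
  T <- length(series)
  vapply(0:maxLagFrames, function(k) {
    acc <- 0
    for (t in 1:(T - k)) acc <- acc + series[t] * series[t + k]
    (acc / (T - k)) / mean(series)^2
  }, 0)
}

# Median relative recovery error of the conventional pipeline for a given
# true decorrelation time and acquisition length, over nPixels independent
# pixels of one simulated stack.
dcsRecoveryErrors <- function(tauCTrue, seconds, nPixels = 100, fps = 100,
                              seed = 1L) {
  spec <- phantomSpec(1, nPixels, round(seconds * fps), fps = fps,
                      exposureUs = 0, backgroundTauC = tauCTrue, seed = seed)
  ph <- simulateStack(spec)
  tm <- dcsMap(ph$stack)
  est <- tauC(tm)[validMask(tm)]
  abs(est - tauCTrue) / tauCTrue
}
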
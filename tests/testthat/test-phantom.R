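test_that("ground-truth map honours background, lesions and last-wins overlap", {
  # no lesions: uniform background, empty mask
  gt <- makePhantomTauMap(phantomSpec(8, 8, 10, backgroundTauC = 0.4))
  expect_true(all(tauC(gt) == 0.4))
  expect_false(any(gt@lesionMask))

  # one centred ellipse: exactly two distinct values, mask matches
  gt <- makePhantomTauMap(phantomSpec(32, 32, 10, backgroundTauC = 0.39,
    lesions = list(list(row = 16, col = 16, a = 6, b = 8, tauC = 0.67))))
  expect_setequal(unique(as.vector(tauC(gt))), c(0.39, 0.67))
  expect_true(all(tauC(gt)[gt@lesionMask] == 0.67))
  expect_true(all(tauC(gt)[!gt@lesionMask] == 0.39))

  # overlapping lesions: the later one wins on the overlap
  gt <- makePhantomTauMap(phantomSpec(32, 32, 10, backgroundTauC = 0.2,
    lesions = list(list(row = 16, col = 14, a = 5, b = 5, tauC = 0.5),
                   list(row = 16, col = 18, a = 5, b = 5, tauC = 0.8))))
  overlap <- ((row(tauC(gt)) - 16) / 5)^2 + ((col(tauC(gt)) - 14) / 5)^2 <= 1 &
             ((row(tauC(gt)) - 16) / 5)^2 + ((col(tauC(gt)) - 18) / 5)^2 <= 1
  expect_true(any(overlap))
  expect_true(all(tauC(gt)[overlap] == 0.8))
})

test_that("invalid phantom specs are rejected with descriptive errors", {
  expect_error(phantomSpec(16, 16, 10,
    lesions = list(list(row = 2, col = 8, a = 5, b = 5, tauC = 0.5))),
    "outside")
  expect_error(phantomSpec(16, 16, 10, beta = 1.5), "beta")
  expect_error(phantomSpec(16, 16, 10, fps = 100, exposureUs = 20000), "exposure")
  expect_error(simulatePixelIntensity(-1, 100, 100), "positive")
})

test_that("static pixels give a constant nonnegative speckle value", {
  x <- simulatePixelIntensity("static", 200, 100, seed = 3)
  expect_equal(stats::var(x), 0)
  expect_true(all(x >= 0))
  y <- simulatePixelIntensity(Inf, 200, 100, seed = 3)
  expect_identical(x, y)
})

test_that("simulated speckle obeys the Siegert relation at the requested beta", {
  # mean zero-lag contrast over many pixels approximates beta
  for (beta in c(1, 0.8)) {
    ph <- simulateStack(phantomSpec(10, 10, 4000, fps = 100, exposureUs = 0,
                                    backgroundTauC = 0.05, beta = beta, seed = 7))
    X <- frames(ph$stack); dim(X) <- c(4000, 100)
    g20 <- colMeans(X^2) / colMeans(X)^2
    expect_lt(abs(mean(g20) - (1 + beta)), 0.02)
  }
})

test_that("sample g2 converges to the calibrated exponential 1 + beta exp(-tau/tauC)", {
  tauCTrue <- 0.5
  ph <- simulateStack(phantomSpec(10, 10, 6000, fps = 100, exposureUs = 0,
                                  backgroundTauC = tauCTrue, seed = 11))
  X <- frames(ph$stack); dim(X) <- c(6000, 100)
  K <- 200L  # lags up to 2 s
  g2bar <- rowMeans(vapply(seq_len(ncol(X)), function(j)
    g2Values(computeG2(X[, j], fps = 100, maxLag = 2)), numeric(K + 1L)))
  lags <- (0:K) / 100
  expect_lt(max(abs(g2bar - (1 + exp(-lags / tauCTrue)))), 0.05)
})

test_that("seeded simulation is bit-for-bit reproducible", {
  spec <- phantomSpec(2, 1, 10, backgroundTauC = 0.3, seed = 42)
  a <- simulateStack(spec)
  b <- simulateStack(spec)
  expect_identical(frames(a$stack), frames(b$stack))
  expect_identical(simulatePixelIntensity(0.5, 50, 100, seed = 9),
                   simulatePixelIntensity(0.5, 50, 100, seed = 9))
})

test_that("the memory budget is enforced before allocation", {
  expect_error(simulateStack(phantomSpec(1000, 1000, 1000), memoryBudget = 1e6),
               "memory budget")
})

test_that("camera noise model has the advertised moments", {
  base <- SpeckleStack(array(100, c(10000, 1, 1)), fps = 100, exposureUs = 0)

  # all off: exact identity
  expect_identical(addCameraNoise(base, noiseSpec(), seed = 1), base)

  # read noise: sample sd ~ sigma
  rn <- addCameraNoise(base, noiseSpec(readNoiseSigma = 5), seed = 2)
  expect_lt(abs(sd(frames(rn)) - 5), 0.2)

  # shot noise: variance ~ mean (Poisson)
  sn <- addCameraNoise(base, noiseSpec(shotNoise = TRUE), seed = 3)
  expect_lt(abs(stats::var(as.vector(frames(sn))) - 100) / 100, 0.1)

  # quantization: nonnegative integers below 2^12
  qz <- addCameraNoise(base, noiseSpec(shotNoise = TRUE, readNoiseSigma = 5,
                                       bitDepth = 12L), seed = 4)
  f <- frames(qz)
  expect_true(all(f == round(f)))
  expect_true(all(f >= 0 & f < 2^12))
})

test_that("noisy quantized phantom stacks stay within the quantization contract", {
  sim <- simulateStack(phantomSpec(4, 4, 100, backgroundTauC = 0.3, seed = 5),
                       noiseSpec(shotNoise = TRUE, bitDepth = 12L))
  f <- frames(sim$stack)
  expect_true(all(f == round(f) & f >= 0 & f < 2^12))
})

test_that("longer acquisitions recover tau more accurately (100 tauC vs 10 tauC)", {
  tauCTrue <- 0.5
  errLong <- median(dcsRecoveryErrors(tauCTrue, seconds = 100 * tauCTrue,
                                      nPixels = 100, seed = 21))
  errShort <- median(dcsRecoveryErrors(tauCTrue, seconds = 10 * tauCTrue,
                                       nPixels = 100, seed = 22))
  expect_lt(errLong, errShort)
})
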
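test_that("mirroring reflects about the horizontal midline and is an involution", {
  m <- matrix(FALSE, 10, 4); m[1, 2] <- TRUE
  mir <- mirrorROI(roiMask(m))
  expect_equal(unname(which(mir@mask, arr.ind = TRUE)), cbind(10L, 2L))
  expect_equal(mir@label, "control")
  expect_equal(sum(mir@mask), sum(m))

  # double mirroring is the identity
  expect_equal(mirrorROI(mir)@mask, m)

  # a mask symmetric about the midline maps onto itself (overlap warned)
  sym <- matrix(FALSE, 10, 4); sym[c(1, 10), 3] <- TRUE
  expect_warning(mir2 <- mirrorROI(roiMask(sym)), "overlap")
  expect_equal(mir2@mask, sym)
})

test_that("roiSummary computes sample statistics over valid masked pixels", {
  vals <- matrix(c(2, 4, 6, 99), 2, 2)
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  s <- roiSummary(vals, roiMask(m))
  expect_equal(s@mean, 4)
  expect_equal(s@sd, 2)
  expect_equal(s@n, 3L)

  # invalid (NA) pixels are excluded and n reflects only valid ones
  vals[2, 1] <- NA
  s2 <- roiSummary(vals, roiMask(m))
  expect_equal(s2@n, 2L)
  expect_equal(s2@mean, 4)

  allNA <- matrix(NA_real_, 2, 2)
  expect_error(roiSummary(allNA, roiMask(m)), "no valid pixels")
  expect_error(roiSummary(vals, roiMask(matrix(TRUE, 3, 3))), "shapes differ")
})

test_that("computeSNR reproduces the mean/sd ratio", {
  expect_equal(round(computeSNR(roiSummaryStats(0.67, 0.206, 100, "s")), 1), 3.3)
  expect_equal(computeSNR(roiSummaryStats(5, 5, 10)), 1)
  expect_error(computeSNR(roiSummaryStats(1, 0, 10)), "undefined")
})

test_that("welchTTest matches the raw-sample Welch test", {
  # hand-computed example
  st <- roiSummaryStats(6, stats::sd(c(5, 5, 7, 7)), 4)
  sc <- roiSummaryStats(2, stats::sd(c(1, 1, 3, 3)), 4)
  expect_equal(welchTTest(st, sc)$t, 4 / sqrt(2 / 3), tolerance = 1e-12)

  # identical populations: t = 0, p = 1
  r0 <- welchTTest(st, st)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # random draws: agree with stats::t.test(var.equal = FALSE)
  set.seed(71)
  for (i in 1:25) {
    n <- sample(3:50, 1); m <- sample(3:50, 1)
    x <- stats::rnorm(n, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(m, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.5, 3))
    got <- welchTTest(roiSummaryStats(mean(x), stats::sd(x), n),
                      roiSummaryStats(mean(y), stats::sd(y), m))
    ref <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("SNR and t have the expected invariances", {
  set.seed(72)
  x <- stats::rexp(40) + 1; y <- stats::rexp(30) + 2
  sx <- function(v) roiSummaryStats(mean(v), stats::sd(v), length(v))
  snr1 <- computeSNR(sx(x))
  expect_equal(computeSNR(sx(x * 13.7)), snr1, tolerance = 1e-12)

  t1 <- welchTTest(sx(x), sx(y))$t
  a <- 3.1; b <- -0.7
  t2 <- welchTTest(sx(a * x + b), sx(a * y + b))$t
  expect_equal(t2, t1, tolerance = 1e-10)
})

test_that("difference maps subtract element-wise and propagate invalidity", {
  a <- matrix(1:6, 2, 3); b <- matrix(0.5, 2, 3)
  expect_equal(differenceMap(a, a), matrix(0, 2, 3))
  expect_equal(differenceMap(a, b), a - 0.5)
  expect_error(differenceMap(a, matrix(1, 3, 2)), "shapes")

  pre <- a; pre[1, 1] <- NA
  d <- differenceMap(a, pre)
  expect_true(is.na(d[1, 1]))
  expect_false(anyNA(d[-1]))
})

test_that("pre/post difference concentrates in the lesion", {
  specPre <- phantomSpec(16, 16, 2500, backgroundTauC = 0.3, seed = 73)
  specPost <- phantomSpec(16, 16, 2500, backgroundTauC = 0.3, seed = 74,
    lesions = list(list(row = 8, col = 8, a = 4, b = 4, tauC = 1.0)))
  pre <- simulateStack(specPre); post <- simulateStack(specPost)
  d <- differenceMap(dcsMap(post$stack), dcsMap(pre$stack))
  les <- post$groundTruth@lesionMask
  expect_gt(mean(abs(d[les]), na.rm = TRUE), mean(abs(d[!les]), na.rm = TRUE))
})

test_that("polygon ROIs rasterize with even-odd fill", {
  # an axis-aligned rectangle (vertices in (row, col))
  v <- rbind(c(2.5, 1.5), c(2.5, 5.5), c(6.5, 5.5), c(6.5, 1.5))
  roi <- polygonROI(v, 8, 8)
  expect_equal(sum(roi@mask), 4 * 4)
  expect_true(all(roi@mask[3:6, 2:5]))
})

test_that("modalityTable assembles the comparison row", {
  ph <- standardPhantom10s()
  roi <- roiMask(ph$groundTruth@lesionMask)
  tab <- modalityTable(lsciMap(ph$stack), roi, modality = "lsci")
  expect_named(tab, c("modality", "muC", "sigmaC", "muT", "sigmaT", "snrT", "t", "p"))
  expect_lt(tab$muT, tab$muC)  # slower lesion -> lower temporal contrast
})
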
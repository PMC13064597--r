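#' @include AllClasses.R utils.R dcs.R
NULL

#' Training configuration for the machine-learned decorrelation regressor
#'
#' Bundles the acquisition and training parameters: sampling rate, window
#' length, the uniform decorrelation-time prior, training-set size, the
#' train/validation split, the stopping threshold on validation MAPE (mean
#' absolute percentage error) and the epoch cap.
#'
#' @param fps sampling rate in frames/second (default 100).
#' @param windowSeconds window length in seconds (default 10); the input
#'   length in samples is \code{fps * windowSeconds}.
#' @param tauRange range of the uniform decorrelation-time prior in seconds
#'   (default \code{c(0, 2)}; the lower end is open: labels are > 0).
#' @param nTrain total number of series to generate (train + validation).
#' @param valFraction validation fraction (default 0.1, i.e. a 90:10
#'   split).
#' @param stopMape stop training once validation MAPE falls below this
#'   percentage (default 5).
#' @param maxEpochs epoch cap (default 40; each epoch is one block of
#'   boosting rounds).
#' @param roundsPerEpoch boosting rounds per epoch (default 25).
#' @param seed master seed.
#' @return A named list (class \code{"speckleTrainingConfig"}).
#' @export
trainingConfig <- function(fps = 100, windowSeconds = 10, tauRange = c(0, 2),
                           nTrain = 5000, valFraction = 0.1, stopMape = 5,
                           maxEpochs = 40L, roundsPerEpoch = 25L, seed = 1L) {
  stopifnot(fps > 0, windowSeconds > 0, length(tauRange) == 2,
            tauRange[1] >= 0, tauRange[2] > tauRange[1],
            valFraction > 0, valFraction < 1, stopMape > 0,
            maxEpochs >= 1, nTrain >= 10)
  structure(list(fps = fps, windowSeconds = windowSeconds, tauRange = tauRange,
                 nTrain = as.integer(nTrain), valFraction = valFraction,
                 stopMape = stopMape, maxEpochs = as.integer(maxEpochs),
                 roundsPerEpoch = as.integer(roundsPerEpoch),
                 seed = as.integer(seed)),
            class = "speckleTrainingConfig")
}

#' Butterworth denoising filter configuration
#'
#' @param order filter order (default 1).
#' @param criticalFrequency low-pass critical frequency as a fraction of
#'   the Nyquist frequency, in (0, 1) (default 0.1).
#' @param zeroPhase apply the filter forward-backward for zero phase lag
#'   (default TRUE); FALSE gives a single causal pass.
#' @return A named list (class \code{"speckleFilterConfig"}).
#' @export
filterConfig <- function(order = 1L, criticalFrequency = 0.1, zeroPhase = TRUE) {
  stopifnot(order >= 1, criticalFrequency > 0, criticalFrequency < 1)
  structure(list(order = as.integer(order), criticalFrequency = criticalFrequency,
                 zeroPhase = zeroPhase),
            class = "speckleFilterConfig")
}

## --- zero-phase IIR filtering --------------------------------------------
##
## Direct-form-II-transposed IIR filter over the columns of X, with initial
## state set to the steady-state response to a constant input equal to the
## first sample (so a constant series passes through exactly). Zero-phase
## filtering applies the pass forward and backward over an odd-extension
## padding of the series, which suppresses edge transients.

.dfiltMat <- function(b, a, X, scaleRow) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, numeric(m + 1L - length(b)))
  a <- c(a, numeric(m + 1L - length(a)))
  G <- sum(b) / sum(a)
  ## steady-state state vector coefficients (per unit constant input)
  ziCoef <- numeric(m)
  if (m > 0) {
    acc <- 0
    for (i in m:1) {
      acc <- acc + (b[i + 1L] - a[i + 1L] * G)
      ziCoef[i] <- acc
    }
  }
  n <- nrow(X); P <- ncol(X)
  Z <- matrix(0, max(m, 1L), P)
  if (m > 0) Z[seq_len(m), ] <- outer(ziCoef, scaleRow)
  Y <- matrix(0, n, P)
  for (t in seq_len(n)) {
    xt <- X[t, ]
    yt <- b[1] * xt + Z[1, ]
    if (m > 1) {
      for (i in seq_len(m - 1L))
        Z[i, ] <- b[i + 1L] * xt + Z[i + 1L, ] - a[i + 1L] * yt
      Z[m, ] <- b[m + 1L] * xt - a[m + 1L] * yt
    } else if (m == 1) {
      Z[1, ] <- b[2] * xt - a[2] * yt
    }
    Y[t, ] <- yt
  }
  Y
}

.filtfiltMat <- function(b, a, X) {
  n <- nrow(X)
  np <- min(3L * max(length(a), length(b)), n - 1L)
  ## odd extension: front rows are 2*x1 - x[np+1 .. 2], back rows 2*xn - x[n-1 .. n-np]
  front <- 2 * matrix(X[1, ], np, ncol(X), byrow = TRUE) - X[(np + 1L):2L, , drop = FALSE]
  back <- 2 * matrix(X[n, ], np, ncol(X), byrow = TRUE) - X[(n - 1L):(n - np), , drop = FALSE]
  Xe <- rbind(front, X, back)
  Y <- .dfiltMat(b, a, Xe, scaleRow = Xe[1, ])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y <- .dfiltMat(b, a, Y, scaleRow = Y[1, ])
  Y <- Y[nrow(Y):1, , drop = FALSE]
  Y[(np + 1L):(np + n), , drop = FALSE]
}

#' Low-pass Butterworth denoising
#'
#' Applies a low-pass Butterworth filter (default order 1, critical
#' frequency 0.1 of Nyquist) to one series or to each column of a matrix.
#' By default the filter is applied forward-backward (zero phase), so a
#' constant series is returned unchanged up to floating-point tolerance.
#'
#' @param series numeric vector, or matrix with one series per column.
#' @param cfg a [filterConfig()].
#' @return Filtered series, same shape as the input.
#' @examples
#' butterworthLowpass(rep(7, 50))[1:3]
#' @export
butterworthLowpass <- function(series, cfg = filterConfig()) {
  stopifnot(inherits(cfg, "speckleFilterConfig"))
  vec <- is.null(dim(series))
  X <- if (vec) cbind(series) else series
  if (nrow(X) <= 3L * cfg$order)
    stop("series too short for the filter (need length > 3 * order)")
  bt <- signal::butter(cfg$order, cfg$criticalFrequency, type = "low")
  Y <- if (cfg$zeroPhase) .filtfiltMat(bt$b, bt$a, X)
       else .dfiltMat(bt$b, bt$a, X, scaleRow = X[1, ])
  if (vec) Y[, 1] else Y
}

## --- feature extraction ---------------------------------------------------
##
## The regressor operates on the autocorrelation signature of the
## normalized window: the empirical autocorrelation at a fixed lag grid,
## threshold-crossing lags, and truncated integrals of the autocorrelation
## (integral-scale estimates). The schema is versioned; train and inference
## must use the same version.

.featureVersion <- 1L

.featureLagGrid <- function(L) {
  g <- c(1:60, seq(62L, 200L, by = 2L), seq(205L, 400L, by = 5L))
  g[g <= L - 1L]
}

## Xn: L x n matrix of normalized windows. Returns n x F feature matrix.
.speckleFeatures <- function(Xn, fps) {
  L <- nrow(Xn); n <- ncol(Xn)
  grid <- .featureLagGrid(L)
  K <- max(grid)
  nfft <- 2^ceiling(log2(2 * L))
  S <- matrix(0, K + 1L, n)
  chunk <- 1024L
  for (j0 in seq(1L, n, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, n)
    Z <- matrix(0, nfft, length(jj))
    Z[1:L, ] <- Xn[, jj, drop = FALSE]
    F <- stats::mvfft(Z)
    S[, jj] <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[1:(K + 1L), , drop = FALSE] / nfft
  }
  A <- S[-1L, , drop = FALSE] / (L - seq_len(K))     # acf at lags 1..K
  v0 <- S[1L, ] / L                                   # lag-0 variance (~1)
  A <- sweep(A, 2L, ifelse(v0 > 0, v0, 1), "/")
  dt <- 1 / fps
  Ag <- A[grid, , drop = FALSE]                       # grid x n
  CS <- apply(A, 2L, cumsum) * dt                     # running integral
  intIdx <- c(5L, 10L, 20L, 40L, 80L, 150L, 300L)
  intIdx <- intIdx[intIdx <= K]
  I <- t(CS[intIdx, , drop = FALSE])
  colnames(I) <- paste0("int", intIdx)
  crossLag <- function(th) {
    idx <- apply(A, 2L, function(r) { i <- which(r <= th)[1]; if (is.na(i)) K + 1L else i })
    idx * dt
  }
  th <- c(0.8, 0.6, exp(-1), 0.25, 0.15)
  C <- matrix(vapply(th, crossLag, numeric(n)), nrow = n)
  colnames(C) <- paste0("cross", seq_along(th))
  k10 <- apply(A, 2L, function(r) { i <- which(r <= 0.1)[1]; if (is.na(i)) K else i })
  Iad <- CS[cbind(k10, seq_len(n))] / 0.9
  out <- cbind(t(Ag), I, C, intAdaptive = Iad)
  colnames(out)[seq_along(grid)] <- paste0("acf", grid)
  out
}

.normalizeWindows <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(colMeans(X^2) - mu^2)
  ok <- sd > 0
  Xn <- sweep(X, 2L, mu, "-")
  Xn[, ok] <- sweep(Xn[, ok, drop = FALSE], 2L, sd[ok], "/")
  list(windows = Xn, ok = ok)
}

#' Generate a synthetic training set of Brownian-motion speckle windows
#'
#' Draws decorrelation-time labels i.i.d. uniform on the (open-ended)
#' prior range and simulates one noiseless speckle window per label
#' (coherence factor 1) with the calibrated Ornstein-Uhlenbeck speckle
#' model. Each window is normalized to zero mean and unit variance before
#' storage, exactly as at inference time. Deterministic given the
#' configuration seed.
#'
#' @param cfg a [trainingConfig()].
#' @return A list: \code{windows} (L x n matrix of normalized series),
#'   \code{tauC} (labels in seconds), \code{config}.
#' @export
generateTrainingSet <- function(cfg) {
  stopifnot(inherits(cfg, "speckleTrainingConfig"))
  L <- as.integer(round(cfg$fps * cfg$windowSeconds))
  n <- cfg$nTrain
  .withSeed(cfg$seed, {
    lo <- cfg$tauRange[1]; hi <- cfg$tauRange[2]
    tau <- lo + (hi - lo) * stats::runif(n)
    tau[tau == lo] <- lo + (hi - lo) * 1e-9   # open lower end
    a <- exp(-(1 / cfg$fps) / (2 * tau)); s <- sqrt(1 - a^2)
    er <- stats::rnorm(n, sd = sqrt(0.5)); ei <- stats::rnorm(n, sd = sqrt(0.5))
    X <- matrix(0, L, n)
    X[1, ] <- er^2 + ei^2
    for (t in 2:L) {
      er <- a * er + s * stats::rnorm(n, sd = sqrt(0.5))
      ei <- a * ei + s * stats::rnorm(n, sd = sqrt(0.5))
      X[t, ] <- er^2 + ei^2
    }
    list(windows = .normalizeWindows(X)$windows, tauC = tau, config = cfg)
  })
}

.mape <- function(pred, truth) mean(abs(pred - truth) / truth) * 100

.clipPredictions <- function(pred, tauRange) {
  lo <- max(tauRange[1], 1e-4)
  pmin(pmax(pred, lo), tauRange[2])
}

#' Train the decorrelation-time regressor
#'
#' Fits a gradient-boosted regressor on autocorrelation-signature features
#' of the normalized windows, with the label on the log scale (so the
#' squared-error boosting objective approximates a relative-error loss,
#' matching the MAPE stopping metric). Training proceeds in epochs (blocks
#' of boosting rounds) under a 90:10 train/validation split until the
#' validation MAPE falls below \code{cfg$stopMape}, stalls, or the epoch
#' cap is reached; failure to reach the target is recorded in the
#' \code{targetReached} flag, not raised as an error.
#'
#' @param dataset output of [generateTrainingSet()] (or a list with the
#'   same fields).
#' @param cfg a [trainingConfig()]; defaults to \code{dataset$config}.
#' @return A [SpeckleRegressor-class].
#' @export
trainRegressor <- function(dataset, cfg = dataset$config) {
  stopifnot(inherits(cfg, "speckleTrainingConfig"))
  X <- dataset$windows; tau <- dataset$tauC
  L <- as.integer(round(cfg$fps * cfg$windowSeconds))
  if (nrow(X) != L)
    stop(sprintf("dataset window length %d does not match config (%d samples)", nrow(X), L))
  feats <- .speckleFeatures(X, cfg$fps)
  n <- length(tau)
  idx <- .withSeed(cfg$seed + 1L, sample.int(n))
  nVal <- max(1L, round(cfg$valFraction * n))
  vi <- idx[seq_len(nVal)]; ti <- idx[-seq_len(nVal)]
  y <- log(pmax(tau, 1e-4))
  dTrain <- xgboost::xgb.DMatrix(feats[ti, , drop = FALSE], label = y[ti])
  dVal <- xgboost::xgb.DMatrix(feats[vi, , drop = FALSE], label = y[vi])
  params <- list(objective = "reg:squarederror", eta = 0.05, max_depth = 6,
                 subsample = 0.8, colsample_bytree = 0.8, min_child_weight = 5,
                 nthread = 1, seed = cfg$seed)
  bst <- NULL
  hist <- data.frame(epoch = integer(), trainMAPE = numeric(), valMAPE = numeric())
  reached <- FALSE
  best <- Inf; stall <- 0L
  for (ep in seq_len(cfg$maxEpochs)) {
    bst <- xgboost::xgb.train(params, dTrain, nrounds = cfg$roundsPerEpoch,
                              xgb_model = bst, verbose = 0)
    pt <- .clipPredictions(exp(predict(bst, dTrain)), cfg$tauRange)
    pv <- .clipPredictions(exp(predict(bst, dVal)), cfg$tauRange)
    mTr <- .mape(pt, tau[ti]); mVa <- .mape(pv, tau[vi])
    hist <- rbind(hist, data.frame(epoch = ep, trainMAPE = mTr, valMAPE = mVa))
    if (mVa < cfg$stopMape) { reached <- TRUE; break }
    if (mVa < best - 1e-3) { best <- mVa; stall <- 0L } else stall <- stall + 1L
    if (stall >= 8L) break
  }
  new("SpeckleRegressor",
      modelRaw = xgboost::xgb.save.raw(bst),
      history = hist,
      config = unclass(cfg),
      schema = list(inputLength = L, fps = cfg$fps,
                    normalization = "per-window zero mean, unit variance",
                    featureVersion = .featureVersion),
      targetReached = reached)
}

#' @rdname predictTauC
#' @export
setMethod("predictTauC", "SpeckleRegressor", function(object, windows) {
  if (is.null(dim(windows))) windows <- cbind(windows)
  if (nrow(windows) != object@schema$inputLength)
    stop(sprintf("window length %d does not match the training window length %d",
                 nrow(windows), object@schema$inputLength))
  nz <- .normalizeWindows(windows)
  feats <- .speckleFeatures(nz$windows, object@schema$fps)
  bst <- xgboost::xgb.load.raw(object@modelRaw)
  pred <- .clipPredictions(exp(predict(bst, feats)), object@config$tauRange)
  pred[!nz$ok] <- NA_real_
  pred
})

#' Machine-learned decorrelation-time map
#'
#' Per pixel: denoise the full series with the Butterworth filter, cut it
#' into consecutive non-overlapping windows of the model's training length
#' (\code{floor(duration / windowSeconds)} of them), normalize each window
#' as in training, predict a decorrelation time per window and return the
#' across-window mean (averaging improves the SNR of the output image).
#' Out-of-range predictions are clipped to the training prior range; the
#' number of clipped windows is attached as attribute \code{"nClipped"}.
#'
#' @param stack a [SpeckleStack-class] whose frame rate matches the model
#'   and whose duration covers at least one window.
#' @param model a [SpeckleRegressor-class].
#' @param filterCfg a [filterConfig()]; \code{NULL} skips denoising (e.g.
#'   for already-noiseless synthetic stacks).
#' @return A [TauCMap-class] with \code{methodTag = "mldcs"}.
#' @export
mldcsMap <- function(stack, model, filterCfg = filterConfig()) {
  validObject(stack); stopifnot(is(model, "SpeckleRegressor"))
  if (!isTRUE(all.equal(fps(stack), model@schema$fps)))
    stop(sprintf("stack frame rate (%g fps) does not match the model (%g fps)",
                 fps(stack), model@schema$fps))
  L <- model@schema$inputLength
  T <- nFrames(stack)
  if (T < L)
    stop(sprintf("stack duration (%.3g s) is below one model window (%.3g s)",
                 T / fps(stack), L / fps(stack)))
  d <- frameDim(stack); h <- d[1]; w <- d[2]
  X <- .stackMatrix(stack)
  if (!is.null(filterCfg)) X <- butterworthLowpass(X, filterCfg)
  nWin <- T %/% L
  P <- ncol(X)
  Xw <- X[seq_len(nWin * L), , drop = FALSE]
  dim(Xw) <- c(L, nWin * P)
  pred <- predictTauC(model, Xw)
  lo <- max(model@config$tauRange[1], 1e-4); hi <- model@config$tauRange[2]
  nClipped <- sum(pred <= lo | pred >= hi, na.rm = TRUE)
  predM <- matrix(pred, nWin, P)
  tau <- colMeans(predM, na.rm = TRUE)
  allBad <- colSums(!is.na(predM)) == 0
  tau[allBad] <- NA_real_
  why <- rep("", P); why[allBad] <- "constant series"
  out <- new("TauCMap", tauC = .pixelMatrix(tau, h, w),
             valid = .pixelMatrix(!allBad, h, w),
             reason = .pixelMatrix(why, h, w), methodTag = "mldcs")
  attr(out, "nClipped") <- nClipped
  attr(out, "nWindows") <- nWin
  out
}

#' Save / load a trained regressor
#'
#' The regressor is written as a single-file bundle (serialized weights,
#' configuration, schema fingerprint and training history). A reloaded
#' model produces bit-identical predictions.
#'
#' @param model a [SpeckleRegressor-class].
#' @param path file path.
#' @return \code{loadRegressor} returns the [SpeckleRegressor-class];
#'   \code{saveRegressor} returns \code{path} invisibly.
#' @export
saveRegressor <- function(model, path) {
  stopifnot(is(model, "SpeckleRegressor"))
  saveRDS(list(modelRaw = model@modelRaw, history = model@history,
               config = model@config, schema = model@schema,
               targetReached = model@targetReached, format = "speckleRheo-regressor-1"),
          path)
  invisible(path)
}

#' @rdname saveRegressor
#' @export
loadRegressor <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "speckleRheo-regressor-1"))
    stop("not a speckleRheo regressor bundle")
  new("SpeckleRegressor", modelRaw = obj$modelRaw, history = obj$history,
      config = obj$config, schema = obj$schema, targetReached = obj$targetReached)
}
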
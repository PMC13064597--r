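#' @include AllClasses.R utils.R
NULL

## --- g2 engine ------------------------------------------------------------
##
## For each column x of X (T x P), the lagged product sums
##   S_k = sum_t x(t) x(t+k),  k = 0..K
## are computed with one FFT-based autocorrelation per column (chunked over
## columns to bound memory). The g2 estimate at lag k is then
##   g2(k) = (S_k / (T - k)) / mean(x)^2,
## i.e. the time-averaged lagged product normalized by the FULL-series mean
## squared (the literal reading of the definition; a symmetric per-lag
## normalization is available via `normalization = "symmetric"`).
.g2Matrix <- function(X, maxLagFrames, normalization = c("full", "symmetric"),
                      chunk = 512L) {
  normalization <- match.arg(normalization)
  T <- nrow(X); P <- ncol(X); K <- maxLagFrames
  nfft <- 2^ceiling(log2(2 * T))
  out <- matrix(NA_real_, K + 1L, P)
  mu <- colMeans(X)
  for (j0 in seq(1L, P, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, P)
    Z <- matrix(0, nfft, length(jj))
    Z[1:T, ] <- X[, jj, drop = FALSE]
    F <- stats::mvfft(Z)
    S <- Re(stats::mvfft(F * Conj(F), inverse = TRUE))[1:(K + 1L), , drop = FALSE] / nfft
    num <- S / (T - 0:K)
    if (normalization == "full") {
      den <- matrix(mu[jj]^2, K + 1L, length(jj), byrow = TRUE)
    } else {
      ## per-lag means of the two overlapping segments
      cs <- apply(X[, jj, drop = FALSE], 2, cumsum)
      tot <- cs[T, ]
      den <- matrix(NA_real_, K + 1L, length(jj))
      for (k in 0:K) {
        m1 <- cs[T - k, ] / (T - k)
        m2 <- (tot - if (k == 0) 0 else cs[k, ]) / (T - k)
        den[k + 1L, ] <- m1 * m2
      }
    }
    out[, jj] <- num / den
  }
  out
}

#' Compute the normalized intensity autocorrelation (g2) of a pixel series
#'
#' Estimates \eqn{g_2(\tau) = \langle I(t) I(t+\tau)\rangle / \langle
#' I(t)\rangle^2} over the native lag grid (multiples of the frame period)
#' from 0 up to \code{maxLag}. Angle brackets are time averages; the
#' denominator uses the full-series mean. A constant nonzero series yields
#' \eqn{g_2 \equiv 1}; an all-zero series is an error (the normalization is
#' undefined).
#'
#' @param series numeric intensity series (length >= 2, nonnegative).
#' @param fps sampling rate in frames/second.
#' @param maxLag maximum lag in seconds (default \code{min(2,
#'   duration/3)}): covers the decorrelation-time range of interest while
#'   bounding estimator variance. Must be below the series duration.
#' @param normalization \code{"full"} (full-series mean squared, the
#'   default) or \code{"symmetric"} (per-lag overlapping-segment means).
#' @return A [G2Curve-class].
#' @examples
#' computeG2(c(2, 4, 6, 4, 2), fps = 100, maxLag = 0.02)
#' @export
computeG2 <- function(series, fps, maxLag = NULL,
                      normalization = c("full", "symmetric")) {
  if (length(series) < 2L) stop("series must have length >= 2")
  if (anyNA(series) || any(!is.finite(series)) || any(series < 0))
    stop("series must be finite and nonnegative")
  .assertScalarNumber(fps, "fps", positive = TRUE)
  duration <- length(series) / fps
  if (is.null(maxLag)) maxLag <- min(2, duration / 3)
  if (maxLag * fps >= length(series))
    stop("maxLag must be smaller than the series duration")
  if (all(series == 0)) stop("all-zero series: g2 normalization is undefined")
  K <- max(1L, floor(maxLag * fps))
  vals <- .g2Matrix(cbind(series), K, normalization = match.arg(normalization))[, 1]
  new("G2Curve", lags = (0:K) / fps, values = vals)
}

#' Extract the decorrelation time from a g2 curve (1/e criterion)
#'
#' Computes the threshold \eqn{\theta = 1 + (g_2(0) - 1)/e} and returns the
#' lag (over \eqn{\tau > 0}) minimizing \eqn{|g_2(\tau) - \theta|}, with
#' ties broken toward the smallest lag. Pixels whose zero-lag contrast
#' \eqn{g_2(0) - 1} falls below \code{dynamicRangeFloor} are flagged
#' invalid (\code{"low dynamic range"}, or \code{"constant series"} when the
#' curve is exactly flat); curves that never decay to the threshold within
#' the lag range are flagged \code{"no threshold crossing"}.
#'
#' @param curve a [G2Curve-class] (at least two lags).
#' @param dynamicRangeFloor minimum \eqn{g_2(0) - 1} for a reliable
#'   estimate (default 0.01, i.e. ~1\% contrast).
#' @param interpolate if TRUE, refine the discrete argmin by linear
#'   interpolation of the threshold crossing between neighbouring lags
#'   (default FALSE: the discrete grid value is returned).
#' @return A list with elements \code{tauC} (seconds, NA if invalid),
#'   \code{valid} (logical) and \code{reason} (\code{""} if valid).
#' @examples
#' lags <- seq(0, 2, by = 0.01)
#' cv <- new("G2Curve", lags = lags, values = 1 + 0.5 * exp(-lags / 0.3))
#' extractTauC(cv)$tauC
#' @export
extractTauC <- function(curve, dynamicRangeFloor = 0.01, interpolate = FALSE) {
  validObject(curve)
  g <- curve@values; lg <- curve@lags
  g0m1 <- g[1] - 1
  if (g0m1 < dynamicRangeFloor) {
    flat <- max(abs(g - g[1])) <= 1e-10 * max(1, abs(g[1]))
    reason <- if (flat) "constant series" else "low dynamic range"
    return(list(tauC = NA_real_, valid = FALSE, reason = reason))
  }
  theta <- 1 + g0m1 / exp(1)
  body <- g[-1]
  if (min(body) > theta)
    return(list(tauC = NA_real_, valid = FALSE, reason = "no threshold crossing"))
  i <- which.min(abs(body - theta))   # first minimum: smallest-lag tie-break
  tau <- lg[i + 1L]
  if (interpolate) {
    ## linear interpolation across the first downward crossing of theta
    j <- which(g <= theta)[1]
    if (!is.na(j) && j > 1L) {
      tau <- lg[j - 1L] + (lg[j] - lg[j - 1L]) * (g[j - 1L] - theta) / (g[j - 1L] - g[j])
    }
  }
  list(tauC = tau, valid = TRUE, reason = "")
}

#' Pixel-wise conventional DCS decorrelation-time map
#'
#' Applies [computeG2()] and [extractTauC()] independently to every pixel
#' time series of the stack. Per-pixel failures (constant series, low
#' dynamic range, no threshold crossing) are recorded as invalid pixels
#' with a reason code, never raised as errors and never silently filled.
#'
#' @param stack a [SpeckleStack-class].
#' @param maxLag maximum autocorrelation lag in seconds (default
#'   \code{min(2, duration/3)}).
#' @param dynamicRangeFloor,interpolate passed to [extractTauC()].
#' @param normalization passed to [computeG2()].
#' @return A [TauCMap-class] with \code{methodTag = "dcs"}.
#' @examples
#' ph <- simulateStack(phantomSpec(3, 3, 600, backgroundTauC = 0.2, seed = 2))
#' dcsMap(ph$stack)
#' @export
dcsMap <- function(stack, maxLag = NULL, dynamicRangeFloor = 0.01,
                   interpolate = FALSE, normalization = c("full", "symmetric")) {
  validObject(stack)
  d <- dim(frames(stack)); T <- d[1]; h <- d[2]; w <- d[3]
  duration <- T / fps(stack)
  if (is.null(maxLag)) maxLag <- min(2, duration / 3)
  if (maxLag * fps(stack) >= T)
    stop("maxLag must be smaller than the stack duration")
  K <- max(1L, floor(maxLag * fps(stack)))
  X <- .stackMatrix(stack)
  P <- ncol(X)
  tau <- rep(NA_real_, P); ok <- logical(P); why <- character(P)
  zero <- colSums(X) == 0
  why[zero] <- "constant series"
  if (any(!zero)) {
    G <- .g2Matrix(X[, !zero, drop = FALSE], K, normalization = match.arg(normalization))
    lags <- (0:K) / fps(stack)
    res <- apply(G, 2, function(v)
      extractTauC(new("G2Curve", lags = lags, values = v),
                  dynamicRangeFloor = dynamicRangeFloor, interpolate = interpolate))
    tau[!zero] <- vapply(res, `[[`, 0, "tauC")
    ok[!zero] <- vapply(res, `[[`, TRUE, "valid")
    why[!zero] <- vapply(res, `[[`, "", "reason")
  }
  new("TauCMap", tauC = .pixelMatrix(tau, h, w), valid = .pixelMatrix(ok, h, w),
      reason = .pixelMatrix(why, h, w), methodTag = "dcs")
}
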
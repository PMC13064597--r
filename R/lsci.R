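#' @include AllClasses.R utils.R
NULL

#' Temporal speckle contrast of a single window
#'
#' Computes \eqn{K = \sigma / \langle I \rangle} for one window of a pixel
#' time series, where \eqn{\sigma} is the population standard deviation
#' (divide by W) and \eqn{\langle I \rangle} the mean of the window.
#'
#' @param window numeric vector of intensities (length >= 2).
#' @return The dimensionless contrast K.
#' @examples
#' temporalContrast(1:7)   # mean 4, population sd 2 -> 0.5
#' @export
temporalContrast <- function(window) {
  if (length(window) < 2L) stop("window must have length >= 2")
  m <- mean(window)
  if (m == 0) stop("zero-mean window: contrast is undefined")
  s <- sqrt(mean((window - m)^2))
  s / m
}

## Rolling window population mean/sd per pixel via cumulative sums.
## X: T x P. Returns the per-pixel mean of K over all window positions.
.lsciMatrix <- function(X, W, stride) {
  T <- nrow(X)
  S1 <- apply(X, 2, cumsum)
  S2 <- apply(X^2, 2, cumsum)
  pad <- function(S) rbind(0, S)
  S1 <- pad(S1); S2 <- pad(S2)
  starts <- seq(1L, T - W + 1L, by = stride)
  acc <- 0
  for (t0 in starts) {
    mu <- (S1[t0 + W, ] - S1[t0, ]) / W
    va <- (S2[t0 + W, ] - S2[t0, ]) / W - mu^2
    va[va < 0] <- 0                      # guard against cancellation
    K <- ifelse(mu > 0, sqrt(va) / mu, 0) # constant-zero windows: K = 0
    ## exactly constant windows must give exactly 0
    K[va == 0] <- 0
    acc <- acc + K
  }
  acc / length(starts)
}

#' Temporal laser speckle contrast map
#'
#' Computes the temporal speckle contrast \eqn{K = \sigma/\langle I\rangle}
#' per pixel in a moving time window (default seven frames, stride one) and
#' averages K over all window positions for the final image. Slower
#' dynamics (larger decorrelation time) give lower temporal contrast at
#' short exposure.
#'
#' @param stack a [SpeckleStack-class] with at least \code{windowLen}
#'   frames.
#' @param windowLen window length in frames (default 7).
#' @param stride window stride in frames (default 1: maximally overlapping
#'   windows).
#' @return A [ContrastMap-class].
#' @examples
#' ph <- simulateStack(phantomSpec(4, 4, 100, backgroundTauC = 0.1, seed = 3))
#' lsciMap(ph$stack)
#' @export
lsciMap <- function(stack, windowLen = 7L, stride = 1L) {
  validObject(stack)
  windowLen <- as.integer(windowLen); stride <- as.integer(stride)
  if (windowLen < 2L) stop("windowLen must be >= 2")
  if (stride < 1L) stop("stride must be >= 1")
  T <- nFrames(stack)
  if (windowLen > T) stop("windowLen exceeds the number of frames")
  d <- frameDim(stack)
  K <- .lsciMatrix(.stackMatrix(stack), windowLen, stride)
  new("ContrastMap", K = .pixelMatrix(K, d[1], d[2]),
      windowLen = windowLen, stride = stride)
}

#' Window-length sweep of the temporal contrast separation
#'
#' Recomputes the contrast map for a range of temporal window lengths and
#' reports, per length, the tumour- and control-ROI mean contrast and the
#' Welch t separation statistic between the two pixel populations. Used to
#' choose the window length (the default map uses seven frames).
#'
#' A degenerate length (both ROIs constant, e.g. a static stack) yields a
#' zero/undefined separation, flagged in the \code{degenerate} column.
#'
#' @param stack a [SpeckleStack-class].
#' @param lengths integer vector of window lengths (default \code{seq(3,
#'   51, 2)}).
#' @param tumourROI,controlROI [ROIMask-class] objects; \code{controlROI}
#'   defaults to the mirror of \code{tumourROI} about the horizontal
#'   midline.
#' @param stride window stride (default 1).
#' @return A data.frame with one row per length: \code{windowLen},
#'   \code{tumourK}, \code{controlK}, \code{t}, \code{p},
#'   \code{degenerate}.
#' @export
windowSweep <- function(stack, lengths = seq(3L, 51L, by = 2L), tumourROI,
                        controlROI = mirrorROI(tumourROI), stride = 1L) {
  validObject(stack)
  lengths <- as.integer(lengths)
  if (max(lengths) > nFrames(stack)) stop("largest window length exceeds the number of frames")
  rows <- lapply(lengths, function(W) {
    cm <- lsciMap(stack, windowLen = W, stride = stride)
    st <- roiSummary(cm, tumourROI)
    sc <- roiSummary(cm, controlROI)
    degenerate <- st@sd == 0 && sc@sd == 0
    if (degenerate) {
      tt <- list(t = 0, p = NA_real_)
    } else {
      tt <- welchTTest(st, sc)
    }
    data.frame(windowLen = W, tumourK = st@mean, controlK = sc@mean,
               t = tt$t, p = tt$p, degenerate = degenerate)
  })
  do.call(rbind, rows)
}
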
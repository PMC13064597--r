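#' @include AllClasses.R utils.R
NULL

## --- dynamics model -------------------------------------------------------
##
## Each pixel is an independent complex Gaussian speckle field E(t) evolving
## as a stationary Ornstein-Uhlenbeck process with field correlation
## g1(tau) = exp(-tau/tau_f). The intensity is I = |E|^2, so by the Siegert
## relation g2(tau) - 1 = beta |g1(tau)|^2 = beta exp(-2 tau/tau_f).
## The simulator is CALIBRATED to the 1/e definition of the decorrelation
## time: tau_f = 2 * tauC, so that g2(tau) - 1 = beta exp(-tau/tauC) and the
## 1/e point of g2 - 1 is exactly the requested tauC.
##
## Partial coherence beta < 1 is modelled by mixing in a static intensity
## offset: I = sqrt(beta) M |E|^2 + (1 - sqrt(beta)) M, which leaves the
## mean at M and scales g2 - 1 by beta.

.ouCoefficients <- function(tauC, fps) {
  a <- exp(-(1 / fps) / (2 * tauC))   # tau_f = 2 tauC calibration
  list(a = a, s = sqrt(1 - a^2))
}

#' Build the ground-truth decorrelation-time field of a phantom
#'
#' Rasterizes the phantom description into a per-pixel map of true
#' decorrelation times: the background value everywhere, overwritten inside
#' each elliptical lesion (in listed order, so overlapping lesions resolve
#' by last-listed-wins) by the lesion's value.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [GroundTruth-class] with the H x W true decorrelation-time map
#'   and the lesion mask.
#' @examples
#' gt <- makePhantomTauMap(phantomSpec(32, 32, 100,
#'   lesions = list(list(row = 16, col = 16, a = 6, b = 8, tauC = 0.67))))
#' table(tauC(gt))
#' @export
makePhantomTauMap <- function(spec) {
  validObject(spec)
  h <- spec@height; w <- spec@width
  tau <- matrix(spec@backgroundTauC, h, w)
  mask <- matrix(FALSE, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (les in spec@lesions) {
    inside <- ((rows - les$row) / les$a)^2 + ((cols - les$col) / les$b)^2 <= 1
    tau[inside] <- les$tauC
    mask <- mask | inside
  }
  new("GroundTruth", tauCMap = tau, lesionMask = mask)
}

#' Simulate a single-pixel speckle intensity time series
#'
#' Generates a stationary nonnegative intensity series whose normalized
#' autocorrelation satisfies, in expectation,
#' \eqn{g_2(\tau) - 1 = \beta e^{-\tau/\tau_c}}: the simulator is calibrated
#' so that the 1/e decorrelation-time estimator applied to the ideal curve
#' recovers exactly the requested \code{tauC}. A static pixel
#' (\code{tauC = Inf} or \code{"static"}) returns a constant-in-time speckle
#' value drawn from the exponential intensity distribution.
#'
#' @param tauC decorrelation time in seconds (> 0), \code{Inf} or
#'   \code{"static"}.
#' @param nFrames number of samples (>= 2).
#' @param fps sampling rate in frames/second.
#' @param beta Siegert coherence factor in (0, 1].
#' @param meanIntensity mean intensity (photoelectrons/pixel/frame).
#' @param seed RNG seed; \code{NULL} uses the current RNG state.
#' @return Numeric vector of length \code{nFrames}.
#' @examples
#' x <- simulatePixelIntensity(0.5, 1000, 100, seed = 1)
#' mean(x)
#' @export
simulatePixelIntensity <- function(tauC, nFrames, fps, beta = 1,
                                   meanIntensity = 100, seed = NULL) {
  if (identical(tauC, "static")) tauC <- Inf
  if (is.na(tauC) || tauC <= 0)
    stop("tauC must be positive (or Inf/'static' for a static pixel)")
  if (nFrames < 2) stop("nFrames must be >= 2")
  .assertScalarNumber(fps, "fps", positive = TRUE)
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  run <- function() {
    if (is.infinite(tauC)) {
      d <- rep(stats::rexp(1), nFrames)
    } else {
      co <- .ouCoefficients(tauC, fps)
      er <- ei <- numeric(nFrames)
      zr <- stats::rnorm(nFrames, sd = sqrt(0.5))
      zi <- stats::rnorm(nFrames, sd = sqrt(0.5))
      er[1] <- zr[1]; ei[1] <- zi[1]
      for (t in 2:nFrames) {
        er[t] <- co$a * er[t - 1] + co$s * zr[t]
        ei[t] <- co$a * ei[t - 1] + co$s * zi[t]
      }
      d <- er^2 + ei^2
    }
    sqrt(beta) * meanIntensity * d + (1 - sqrt(beta)) * meanIntensity
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}

#' Simulate a full phantom speckle stack with ground truth
#'
#' Vectorizes the single-pixel Ornstein-Uhlenbeck speckle model over the
#' phantom's decorrelation-time field. Pixels are statistically independent
#' across space (a documented simplification: the downstream processing is
#' strictly pixel-wise). All pixels are driven from one master-seeded RNG
#' stream, advanced together frame by frame, so a given spec + seed is
#' bit-reproducible.
#'
#' @param spec a [PhantomSpec-class].
#' @param noise a [NoiseSpec-class]; the default is noiseless.
#' @param memoryBudget maximum number of array elements the stack may
#'   occupy (default 2.5e8, i.e. 2 GB of doubles); exceeding it errors
#'   before allocation.
#' @return A list with elements \code{stack} ([SpeckleStack-class]) and
#'   \code{groundTruth} ([GroundTruth-class]).
#' @examples
#' ph <- simulateStack(phantomSpec(4, 4, 50, seed = 7))
#' ph$stack
#' @export
simulateStack <- function(spec, noise = noiseSpec(), memoryBudget = 2.5e8) {
  validObject(spec); validObject(noise)
  nel <- as.numeric(spec@nFrames) * spec@height * spec@width
  if (nel > memoryBudget)
    stop(sprintf("stack of %g elements exceeds the memory budget of %g; reduce the phantom or raise memoryBudget",
                 nel, memoryBudget))
  gt <- makePhantomTauMap(spec)
  tau <- as.vector(gt@tauCMap)
  P <- length(tau); T <- spec@nFrames
  M <- spec@meanIntensity; beta <- spec@beta
  X <- .withSeed(spec@seed, {
    dyn <- is.finite(tau)
    D <- matrix(0, T, P)
    if (any(dyn)) {
      a <- exp(-(1 / spec@fps) / (2 * tau[dyn]))
      s <- sqrt(1 - a^2)
      nd <- sum(dyn)
      er <- stats::rnorm(nd, sd = sqrt(0.5))
      ei <- stats::rnorm(nd, sd = sqrt(0.5))
      Dd <- matrix(0, T, nd)
      Dd[1, ] <- er^2 + ei^2
      for (t in 2:T) {
        er <- a * er + s * stats::rnorm(nd, sd = sqrt(0.5))
        ei <- a * ei + s * stats::rnorm(nd, sd = sqrt(0.5))
        Dd[t, ] <- er^2 + ei^2
      }
      D[, dyn] <- Dd
    }
    if (any(!dyn))
      D[, !dyn] <- rep(stats::rexp(sum(!dyn)), each = T)
    sqrt(beta) * M * D + (1 - sqrt(beta)) * M
  })
  dim(X) <- c(T, spec@height, spec@width)
  stack <- SpeckleStack(X, fps = spec@fps, exposureUs = spec@exposureUs)
  if (!.isNoiseless(noise))
    stack <- addCameraNoise(stack, noise, seed = spec@seed + 1L)
  list(stack = stack, groundTruth = gt)
}

#' Apply a camera noise model to a speckle stack
#'
#' Applies, in order: Poisson shot noise to the photoelectron counts,
#' additive Gaussian read noise, and (if a bit depth is set) clipping to
#' \eqn{[0, 2^{bits} - 1]} followed by rounding to integers. An all-off
#' noise spec returns the input unchanged.
#'
#' @param stack a [SpeckleStack-class] in photoelectron units.
#' @param noise a [NoiseSpec-class].
#' @param seed RNG seed; \code{NULL} uses the current RNG state.
#' @return A [SpeckleStack-class] with the same metadata.
#' @export
addCameraNoise <- function(stack, noise, seed = NULL) {
  validObject(stack); validObject(noise)
  if (.isNoiseless(noise)) return(stack)
  run <- function() {
    f <- frames(stack)
    if (noise@shotNoise)
      f <- array(stats::rpois(length(f), lambda = f), dim = dim(f))
    if (noise@readNoiseSigma > 0)
      f <- f + stats::rnorm(length(f), sd = noise@readNoiseSigma)
    if (!is.na(noise@bitDepth)) {
      top <- 2^noise@bitDepth - 1
      f <- round(pmin(pmax(f, 0), top))
    } else {
      f <- pmax(f, 0)   # read noise can push counts negative
    }
    SpeckleStack(f, fps = fps(stack), exposureUs = exposureUs(stack))
  }
  if (is.null(seed)) run() else .withSeed(seed, run())
}
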
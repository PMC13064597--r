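#' @include AllGenerics.R
NULL

## Conventions used throughout:
##  - frames are stored as a T x H x W array (time is the first dimension,
##    so a pixel time series is a contiguous column);
##  - in-memory indices are 1-based (row, col); on-disk JSON ROIs use
##    0-based (row, col) coordinates, converted at the I/O boundary;
##  - a static pixel (no dynamics) is represented by tau_c = Inf.

#' SpeckleStack: a speckle image time series
#'
#' The universal input of all processing routines: a stack of T grayscale
#' speckle frames of size H x W, with acquisition metadata. Intensities are
#' nonnegative and finite; time is the first array dimension.
#'
#' @slot frames numeric T x H x W array of intensities.
#' @slot fps frame rate in frames per second.
#' @slot exposureUs exposure time in microseconds.
#'
#' @examples
#' st <- SpeckleStack(array(runif(20 * 4 * 4), c(20, 4, 4)), fps = 100)
#' nFrames(st); frameDim(st)
#' @export
setClass("SpeckleStack",
  representation(frames = "array", fps = "numeric", exposureUs = "numeric"))

setValidity("SpeckleStack", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3L) return("frames must be a T x H x W array")
  if (dim(f)[1] < 2L) return("need at least 2 frames")
  if (anyNA(f) || any(!is.finite(f))) return("intensities must be finite")
  if (any(f < 0)) return("intensities must be nonnegative")
  if (length(object@fps) != 1L || object@fps <= 0) return("fps must be a single positive number")
  if (length(object@exposureUs) != 1L || object@exposureUs < 0)
    return("exposureUs must be a single nonnegative number")
  if (object@exposureUs > 1e6 / object@fps)
    return("exposure cannot exceed the frame period (exposureUs <= 1e6/fps)")
  TRUE
})

#' @param frames numeric T x H x W array.
#' @param fps frames per second.
#' @param exposureUs exposure time in microseconds (default 9500, a typical
#'   short exposure well below the decorrelation times of interest).
#' @rdname SpeckleStack-class
#' @export
SpeckleStack <- function(frames, fps, exposureUs = 9500) {
  new("SpeckleStack", frames = frames, fps = fps, exposureUs = as.numeric(exposureUs))
}

#' @rdname accessors
#' @export
setMethod("frames", "SpeckleStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("fps", "SpeckleStack", function(x) x@fps)
#' @rdname accessors
#' @export
setMethod("exposureUs", "SpeckleStack", function(x) x@exposureUs)
#' @rdname accessors
#' @export
setMethod("nFrames", "SpeckleStack", function(x) dim(x@frames)[1])
#' @rdname accessors
#' @export
setMethod("frameDim", "SpeckleStack", function(x) dim(x@frames)[2:3])

setMethod("show", "SpeckleStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SpeckleStack: %d frames of %d x %d @ %g fps (exposure %g us, %.1f s)\n",
              d[1], d[2], d[3], object@fps, object@exposureUs, d[1] / object@fps))
})

#' G2Curve: a normalized intensity autocorrelation curve
#'
#' The g2 decorrelation curve of a single pixel time series over a discrete
#' lag grid starting at zero lag (native frame-period spacing).
#'
#' @slot lags numeric vector of lags in seconds, strictly increasing from 0.
#' @slot values numeric vector of g2 estimates, same length as \code{lags}.
#' @export
setClass("G2Curve", representation(lags = "numeric", values = "numeric"))

setValidity("G2Curve", function(object) {
  if (length(object@lags) != length(object@values)) return("lags/values length mismatch")
  if (length(object@lags) < 2L) return("curve needs at least two lags")
  if (object@lags[1] != 0) return("lag grid must start at 0")
  if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
  if (anyNA(object@values) || any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("g2Lags", "G2Curve", function(x) x@lags)
#' @rdname accessors
#' @export
setMethod("g2Values", "G2Curve", function(x) x@values)

setMethod("show", "G2Curve", function(object) {
  cat(sprintf("G2Curve: %d lags, 0 .. %.4g s; g2(0) = %.4f\n",
              length(object@lags), max(object@lags), object@values[1]))
})

#' TauCMap: a per-pixel speckle decorrelation time map
#'
#' Output of the conventional and machine-learned decorrelation-time
#' pipelines. Pixels that could not be estimated carry \code{NA} in
#' \code{tauC}, \code{FALSE} in \code{valid} and a reason code: one of
#' \code{"constant series"}, \code{"no threshold crossing"},
#' \code{"low dynamic range"}.
#'
#' @slot tauC numeric H x W matrix of decorrelation times (seconds); NA
#'   where invalid.
#' @slot valid logical H x W matrix.
#' @slot reason character H x W matrix, \code{""} where valid.
#' @slot methodTag either \code{"dcs"} or \code{"mldcs"}.
#' @export
setClass("TauCMap",
  representation(tauC = "matrix", valid = "matrix", reason = "matrix",
                 methodTag = "character"))

setValidity("TauCMap", function(object) {
  if (!identical(dim(object@tauC), dim(object@valid)) ||
      !identical(dim(object@tauC), dim(object@reason)))
    return("tauC/valid/reason dimensions differ")
  if (!is.logical(object@valid)) return("valid must be logical")
  v <- object@tauC[object@valid]
  if (anyNA(v) || any(v <= 0)) return("valid pixels must have finite positive tauC")
  if (anyNA(object@tauC[!object@valid]) == FALSE && any(!object@valid))
    return("invalid pixels must carry NA tauC")
  if (!object@methodTag %in% c("dcs", "mldcs")) return("methodTag must be 'dcs' or 'mldcs'")
  if (any(object@reason[object@valid] != "")) return("valid pixels must have empty reason")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("tauC", "TauCMap", function(x) x@tauC)
#' @rdname accessors
#' @export
setMethod("validMask", "TauCMap", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("reasonCodes", "TauCMap", function(x) x@reason)
#' @rdname accessors
#' @export
setMethod("methodTag", "TauCMap", function(x) x@methodTag)
#' @rdname accessors
#' @export
setMethod("pixelValues", "TauCMap", function(x) {
  v <- x@tauC
  v[!x@valid] <- NA_real_
  v
})

setMethod("show", "TauCMap", function(object) {
  d <- dim(object@tauC)
  cat(sprintf("TauCMap (%s): %d x %d, %d/%d valid; median tau_c %.3g s\n",
              object@methodTag, d[1], d[2], sum(object@valid), length(object@valid),
              stats::median(object@tauC[object@valid])))
})

#' ContrastMap: a per-pixel temporal speckle contrast map
#'
#' Temporal speckle contrast K = sd/mean computed in a moving time window
#' per pixel and averaged over window positions.
#'
#' @slot K numeric H x W matrix of contrast values (dimensionless, >= 0).
#' @slot windowLen window length in frames.
#' @slot stride window stride in frames.
#' @export
setClass("ContrastMap",
  representation(K = "matrix", windowLen = "integer", stride = "integer"))

setValidity("ContrastMap", function(object) {
  if (anyNA(object@K) || any(!is.finite(object@K))) return("K must be finite")
  if (any(object@K < 0)) return("K must be nonnegative")
  if (object@windowLen < 2L) return("windowLen must be >= 2")
  if (object@stride < 1L) return("stride must be >= 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("contrast", "ContrastMap", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("pixelValues", "ContrastMap", function(x) x@K)

setMethod("show", "ContrastMap", function(object) {
  d <- dim(object@K)
  cat(sprintf("ContrastMap: %d x %d, window %d frames (stride %d); median K %.4g\n",
              d[1], d[2], object@windowLen, object@stride, stats::median(object@K)))
})

#' PhantomSpec: parameters of a synthetic dynamic-speckle phantom
#'
#' Describes a phantom acquisition: image geometry, frame rate and exposure,
#' a background decorrelation time, elliptical lesion regions with their own
#' decorrelation times, the Siegert coherence factor beta, the mean
#' intensity (photoelectrons per pixel per frame) and the master seed.
#' A decorrelation time of \code{Inf} (or the string \code{"static"} in the
#' constructor) denotes a static region.
#'
#' Overlapping lesions resolve by last-listed-wins.
#'
#' @slot height,width image size in pixels.
#' @slot nFrames number of frames.
#' @slot fps frame rate (frames/second).
#' @slot exposureUs exposure time (microseconds); must not exceed the frame
#'   period.
#' @slot backgroundTauC background decorrelation time (seconds; Inf = static).
#' @slot lesions list of lesions, each a list with elements \code{row},
#'   \code{col} (ellipse center, 1-based pixels), \code{a}, \code{b}
#'   (semi-axes in pixels along rows and columns) and \code{tauC} (seconds).
#' @slot beta Siegert coherence factor in (0, 1].
#' @slot meanIntensity mean intensity in photoelectrons/pixel/frame.
#' @slot seed master RNG seed (integer).
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", nFrames = "integer",
                 fps = "numeric", exposureUs = "numeric",
                 backgroundTauC = "numeric", lesions = "list",
                 beta = "numeric", meanIntensity = "numeric", seed = "integer"))

.checkTauC <- function(x) length(x) == 1L && !is.na(x) && (is.infinite(x) || x > 0)

setValidity("PhantomSpec", function(object) {
  if (object@height < 1L || object@width < 1L) return("image size must be positive")
  if (object@nFrames < 2L) return("need at least 2 frames")
  if (object@fps <= 0) return("fps must be positive")
  if (object@exposureUs < 0 || object@exposureUs > 1e6 / object@fps)
    return("exposure cannot exceed the frame period (exposureUs <= 1e6/fps)")
  if (!.checkTauC(object@backgroundTauC)) return("backgroundTauC must be > 0 (or Inf for static)")
  for (les in object@lesions) {
    if (!all(c("row", "col", "a", "b", "tauC") %in% names(les)))
      return("each lesion needs row, col, a, b, tauC")
    if (!.checkTauC(les$tauC)) return("lesion tauC must be > 0 (or Inf for static)")
    if (les$a <= 0 || les$b <= 0) return("lesion semi-axes must be positive")
    if (les$row - les$a < 1 || les$row + les$a > object@height ||
        les$col - les$b < 1 || les$col + les$b > object@width)
      return(sprintf("lesion at (%g, %g) with semi-axes (%g, %g) lies outside the %d x %d image",
                     les$row, les$col, les$a, les$b, object@height, object@width))
  }
  if (object@beta <= 0 || object@beta > 1) return("beta must be in (0, 1]")
  if (object@meanIntensity <= 0) return("meanIntensity must be positive")
  TRUE
})

#' @param height,width image size in pixels.
#' @param nFrames number of frames.
#' @param fps frame rate (default 100, a typical sCMOS wide-field rate).
#' @param exposureUs exposure in microseconds (default 9500).
#' @param backgroundTauC background decorrelation time in seconds (default
#'   0.39 s, a typical fresh-tissue value); \code{"static"} or \code{Inf}
#'   for a static background.
#' @param lesions list of lesion descriptors; see slots.
#' @param beta Siegert coherence factor (default 1, ideal detection).
#' @param meanIntensity mean photoelectrons/pixel/frame (default 100).
#' @param seed master seed.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(height, width, nFrames, fps = 100, exposureUs = 9500,
                        backgroundTauC = 0.39, lesions = list(), beta = 1,
                        meanIntensity = 100, seed = 1L) {
  asTau <- function(x) if (identical(x, "static")) Inf else as.numeric(x)
  lesions <- lapply(lesions, function(l) { l$tauC <- asTau(l$tauC); l })
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nFrames = as.integer(nFrames), fps = fps, exposureUs = as.numeric(exposureUs),
      backgroundTauC = asTau(backgroundTauC), lesions = lesions, beta = beta,
      meanIntensity = meanIntensity, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d frames @ %g fps, background tau_c %g s, %d lesion(s), beta %g, seed %d\n",
              object@height, object@width, object@nFrames, object@fps,
              object@backgroundTauC, length(object@lesions), object@beta, object@seed))
})

#' NoiseSpec: camera noise model parameters
#'
#' Poisson shot noise on photoelectron counts, additive Gaussian read noise,
#' and optional clipping plus quantization to a given bit depth.
#'
#' @slot shotNoise logical; apply Poisson shot noise.
#' @slot readNoiseSigma read noise standard deviation in photoelectrons
#'   (>= 0; 0 disables).
#' @slot bitDepth integer bit depth in \{8, 10, 12, 16\}, or \code{NA} for no
#'   quantization.
#' @export
setClass("NoiseSpec",
  representation(shotNoise = "logical", readNoiseSigma = "numeric", bitDepth = "integer"))

setValidity("NoiseSpec", function(object) {
  if (object@readNoiseSigma < 0) return("readNoiseSigma must be >= 0")
  if (!is.na(object@bitDepth) && !object@bitDepth %in% c(8L, 10L, 12L, 16L))
    return("bitDepth must be one of 8, 10, 12, 16 or NA")
  TRUE
})

#' @param shotNoise apply Poisson shot noise (default FALSE).
#' @param readNoiseSigma Gaussian read noise sd in photoelectrons (default 0).
#' @param bitDepth quantization bit depth, or NA for none (default NA).
#' @rdname NoiseSpec-class
#' @export
noiseSpec <- function(shotNoise = FALSE, readNoiseSigma = 0, bitDepth = NA) {
  new("NoiseSpec", shotNoise = shotNoise, readNoiseSigma = readNoiseSigma,
      bitDepth = as.integer(bitDepth))
}

.isNoiseless <- function(noise) {
  !noise@shotNoise && noise@readNoiseSigma == 0 && is.na(noise@bitDepth)
}

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: shot %s, read sigma %g e-, bit depth %s\n",
              object@shotNoise, object@readNoiseSigma,
              ifelse(is.na(object@bitDepth), "none", object@bitDepth)))
})

#' GroundTruth: the simulated phantom's true decorrelation-time field
#'
#' @slot tauCMap numeric H x W matrix of true decorrelation times (seconds;
#'   Inf = static).
#' @slot lesionMask logical H x W matrix, TRUE exactly where a lesion
#'   decorrelation time was assigned.
#' @export
setClass("GroundTruth", representation(tauCMap = "matrix", lesionMask = "matrix"))

setValidity("GroundTruth", function(object) {
  if (!identical(dim(object@tauCMap), dim(object@lesionMask)))
    return("tauCMap/lesionMask dimensions differ")
  if (!is.logical(object@lesionMask)) return("lesionMask must be logical")
  if (any(is.na(object@tauCMap)) || any(object@tauCMap <= 0))
    return("true tau_c must be positive (Inf allowed)")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("tauC", "GroundTruth", function(x) x@tauCMap)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d x %d, %d lesion pixel(s)\n",
              nrow(object@tauCMap), ncol(object@tauCMap), sum(object@lesionMask)))
})

#' ROIMask: a labelled region-of-interest mask
#'
#' @slot mask logical H x W matrix with at least one TRUE pixel.
#' @slot label \code{"tumour"} or \code{"control"}.
#' @slot provenance free-text note on how the ROI was obtained (e.g. drawn
#'   polygon, mirrored).
#' @export
setClass("ROIMask",
  representation(mask = "matrix", label = "character", provenance = "character"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask must contain at least one pixel")
  if (!object@label %in% c("tumour", "control")) return("label must be 'tumour' or 'control'")
  TRUE
})

#' @param mask logical H x W matrix.
#' @param label ROI label, \code{"tumour"} (default) or \code{"control"}.
#' @param provenance free-text provenance note.
#' @rdname ROIMask-class
#' @export
roiMask <- function(mask, label = "tumour", provenance = "manual") {
  new("ROIMask", mask = mask, label = label, provenance = provenance)
}

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask (%s): %d x %d, %d pixel(s) [%s]\n", object@label,
              nrow(object@mask), ncol(object@mask), sum(object@mask), object@provenance))
})

#' SpeckleRegressor: a trained decorrelation-time regressor
#'
#' A gradient-boosted regressor over autocorrelation-signature features of a
#' normalized single-pixel speckle window. Carries the training history, the
#' configuration snapshot and a data-schema fingerprint; it refuses inputs
#' whose length differs from the training window.
#'
#' @slot modelRaw serialized booster (raw bytes).
#' @slot history data.frame with one row per training epoch (boosting
#'   round block): epoch, trainMAPE, valMAPE.
#' @slot config the TrainingConfig list used.
#' @slot schema list: inputLength, fps, normalization, featureVersion.
#' @slot targetReached logical; TRUE if validation MAPE fell below the
#'   stopping threshold.
#' @export
setClass("SpeckleRegressor",
  representation(modelRaw = "raw", history = "data.frame", config = "list",
                 schema = "list", targetReached = "logical"))

setMethod("show", "SpeckleRegressor", function(object) {
  cat(sprintf("SpeckleRegressor: input %d samples @ %g fps; %d epochs, final val MAPE %.2f%% (target %s)\n",
              object@schema$inputLength, object@schema$fps, nrow(object@history),
              utils::tail(object@history$valMAPE, 1),
              ifelse(object@targetReached, "reached", "not reached")))
})
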
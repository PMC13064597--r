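#' @include AllGenerics.R
NULL

#' Accessor generics for speckle data objects
#'
#' Small accessor generics shared by the container classes: the frame data,
#' acquisition metadata, per-pixel values and validity information.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("exposureUs", function(x) standardGeneric("exposureUs"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname accessors
#' @export
setGeneric("tauC", function(x) standardGeneric("tauC"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("reasonCodes", function(x) standardGeneric("reasonCodes"))

#' @rdname accessors
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' @rdname accessors
#' @export
setGeneric("contrast", function(x) standardGeneric("contrast"))

#' @rdname accessors
#' @export
setGeneric("g2Lags", function(x) standardGeneric("g2Lags"))

#' @rdname accessors
#' @export
setGeneric("g2Values", function(x) standardGeneric("g2Values"))

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(x) standardGeneric("pixelValues"))

#' Predict decorrelation times from normalized speckle windows
#'
#' @param object a trained regressor.
#' @param windows numeric matrix of normalized single-pixel windows, one
#'   window per column, with \code{nrow(windows)} equal to the training
#'   window length.
#' @return Numeric vector of predicted decorrelation times (seconds), one
#'   per column, clipped to the training range.
#' @export
setGeneric("predictTauC", function(object, windows) standardGeneric("predictTauC"))
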
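#' @include AllClasses.R utils.R
NULL

## On-disk conventions:
##  - stacks: multi-page 32-bit float grayscale TIFF, values divided by a
##    scale factor recorded in the JSON sidecar (<path>.json); integer
##    (quantized) stacks are rounded back on load, which makes them
##    lossless;
##  - maps/masks: single-page 32-bit float TIFF + JSON sidecar with units;
##  - ROIs: JSON, either a 0-based (row, col) polygon vertex list or an
##    explicit pixel list; converted to 1-based in memory.

## 32-bit grayscale storage. The TIFF backend stores 32-bit unsigned
## integer samples by truncating value * (2^32 - 1) and reads them back as
## value / 2^32. We therefore quantize explicitly to k = round(u * (2^32-1))
## and write (k + 0.5) / (2^32 - 1), which truncates robustly to k; loading
## recovers k exactly and maps it back to k / (2^32 - 1). This makes
## write -> load idempotent (bit-identical from the first cycle onward) at
## ~2.4e-10 relative precision of full scale.
.tiffGrid <- 2^32 - 1

.gridQuantize <- function(u) {
  k <- round(u * .tiffGrid)
  pmin(pmax(k, 0), .tiffGrid - 1)
}

.writeGray32 <- function(values01, path) {
  if (is.list(values01)) {
    pages <- lapply(values01, function(m) (.gridQuantize(m) + 0.5) / .tiffGrid)
  } else {
    pages <- (.gridQuantize(values01) + 0.5) / .tiffGrid
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
}

.readGray32 <- function(path, all = FALSE) {
  r <- tiff::readTIFF(path, all = all)
  back <- function(m) round(m * 2^32) / .tiffGrid
  if (all) lapply(r, back) else back(r)
}

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, fields) {
  jsonlite::write_json(fields, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a speckle stack as a multi-page TIFF with a JSON sidecar
#'
#' Frames are written as 32-bit float grayscale pages after division by a
#' scale factor (the maximum intensity); the sidecar records the scale,
#' frame rate, exposure and whether the data are integer-quantized (in
#' which case loading rounds back to exact integers).
#'
#' @param stack a [SpeckleStack-class].
#' @param path output TIFF path; the sidecar goes to \code{<path>.json}.
#' @param extra named list merged into the sidecar (e.g. seed, phantom
#'   parameters).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, extra = list()) {
  validObject(stack)
  f <- frames(stack)
  ## power-of-two scale: division and re-multiplication are exact in binary
  ## floating point, so load(write(x)) is bit-identical at float32 precision
  sc <- if (max(f) > 0) 2^ceiling(log2(max(f))) else 1
  quantized <- all(f == round(f))
  pages <- lapply(seq_len(dim(f)[1]), function(t) f[t, , ] / sc)
  .writeGray32(pages, path)
  .writeSidecar(path, c(list(format = "speckleRheo-stack-1",
                             fps = fps(stack), exposure_us = exposureUs(stack),
                             scale = sc, quantized = quantized,
                             n_frames = dim(f)[1], height = dim(f)[2],
                             width = dim(f)[3]), extra))
  invisible(path)
}

#' Load a speckle stack from a multi-page TIFF
#'
#' @param path TIFF path; a \code{<path>.json} sidecar provides the frame
#'   rate, exposure and intensity scale (written by [writeStack()]).
#' @param fps frame rate override, required if no sidecar is present.
#' @param exposureUs exposure override (default from sidecar, else 0).
#' @return A [SpeckleStack-class].
#' @export
loadStack <- function(path, fps = NULL, exposureUs = NULL) {
  if (!file.exists(path)) stop(sprintf("stack file not found: %s", path))
  pages <- .readGray32(path, all = TRUE)
  if (length(pages) < 2L) stop("a stack needs at least 2 TIFF pages")
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("TIFF pages have inconsistent sizes")
  side <- .readSidecar(path)
  if (is.null(fps)) fps <- side$fps
  if (is.null(fps))
    stop("frame rate unknown: provide fps= or a JSON sidecar with a 'fps' field")
  if (is.null(exposureUs)) exposureUs <- if (!is.null(side$exposure_us)) side$exposure_us else 0
  sc <- if (!is.null(side$scale)) side$scale else 1
  h <- dims[[1]][1]; w <- dims[[1]][2]
  f <- array(0, c(length(pages), h, w))
  for (t in seq_along(pages)) f[t, , ] <- pages[[t]] * sc
  if (isTRUE(side$quantized)) f <- round(f)
  SpeckleStack(f, fps = fps, exposureUs = exposureUs)
}

#' Write a per-pixel map (decorrelation time or contrast) to TIFF
#'
#' The values go to a single-page 32-bit float TIFF (divided by a recorded
#' scale); for decorrelation-time maps the validity mask is written next to
#' it as \code{<path>.valid.tif}. The sidecar carries the units tag
#' (seconds vs dimensionless) so that downstream statistics cannot mix
#' modalities silently.
#'
#' @param map a [TauCMap-class] or [ContrastMap-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeMap <- function(map, path) {
  if (is(map, "TauCMap")) {
    vals <- tauC(map); vals[!validMask(map)] <- 0
    units <- "s"; method <- methodTag(map)
    .writeGray32(validMask(map) * 1, paste0(path, ".valid.tif"))
  } else if (is(map, "ContrastMap")) {
    vals <- contrast(map); units <- "dimensionless"; method <- "lsci"
  } else stop("map must be a TauCMap or ContrastMap")
  sc <- if (max(vals) > 0) 2^ceiling(log2(max(vals))) else 1
  .writeGray32(vals / sc, path)
  .writeSidecar(path, list(format = "speckleRheo-map-1", units = units,
                           method = method, scale = sc))
  invisible(path)
}

#' Load a per-pixel map written by [writeMap()]
#'
#' @param path TIFF path.
#' @return A [TauCMap-class] or [ContrastMap-class] (window metadata of
#'   reloaded contrast maps is not preserved and is set to the default).
#' @export
loadMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("map file not found: %s", path))
  side <- .readSidecar(path)
  if (is.null(side) || !identical(side$format, "speckleRheo-map-1"))
    stop("missing or unrecognized map sidecar")
  vals <- .readGray32(path) * side$scale
  if (identical(side$units, "s")) {
    vp <- paste0(path, ".valid.tif")
    valid <- if (file.exists(vp)) .readGray32(vp) > 0.5 else vals > 0
    vals[!valid] <- NA_real_
    why <- matrix("", nrow(vals), ncol(vals)); why[!valid] <- "low dynamic range"
    new("TauCMap", tauC = vals, valid = valid, reason = why,
        methodTag = side$method)
  } else {
    new("ContrastMap", K = vals, windowLen = 7L, stride = 1L)
  }
}

#' Read / write a region of interest as JSON
#'
#' Two JSON layouts are accepted: \code{{"polygon": [[r, c], ...]}} with
#' 0-based row-major pixel coordinates (rasterized with even-odd fill), or
#' \code{{"pixels": [[r, c], ...], "height": H, "width": W}} listing mask
#' pixels explicitly. \code{writeROI} writes the explicit-pixel layout.
#'
#' @param path JSON path.
#' @param height,width mask size, required for polygon ROIs (overrides the
#'   file's fields when given).
#' @param roi an [ROIMask-class] (for \code{writeROI}).
#' @return \code{loadROI} returns an [ROIMask-class].
#' @export
loadROI <- function(path, height = NULL, width = NULL) {
  if (!file.exists(path)) stop(sprintf("ROI file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  label <- if (!is.null(obj$label)) obj$label else "tumour"
  if (is.null(height)) height <- obj$height
  if (is.null(width)) width <- obj$width
  if (!is.null(obj$polygon)) {
    if (is.null(height) || is.null(width))
      stop("polygon ROI needs height/width (in the file or as arguments)")
    v <- matrix(unlist(obj$polygon), ncol = 2, byrow = !is.matrix(obj$polygon))
    if (is.matrix(obj$polygon)) v <- obj$polygon
    polygonROI(v + 1, height, width, label = label,
               provenance = sprintf("polygon from %s", basename(path)))
  } else if (!is.null(obj$pixels)) {
    if (is.null(height) || is.null(width))
      stop("pixel ROI needs height/width fields")
    m <- matrix(FALSE, height, width)
    px <- if (is.matrix(obj$pixels)) obj$pixels else matrix(unlist(obj$pixels), ncol = 2, byrow = TRUE)
    m[cbind(px[, 1] + 1, px[, 2] + 1)] <- TRUE
    roiMask(m, label = label, provenance = sprintf("pixels from %s", basename(path)))
  } else stop("ROI JSON must contain a 'polygon' or 'pixels' field")
}

#' @rdname loadROI
#' @export
writeROI <- function(roi, path) {
  validObject(roi)
  px <- which(roi@mask, arr.ind = TRUE) - 1L
  jsonlite::write_json(list(pixels = unname(px), height = nrow(roi@mask),
                            width = ncol(roi@mask), label = roi@label,
                            provenance = roi@provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
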
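#' @include AllClasses.R utils.R
NULL

#' ROISummary: population summary of a region of interest
#'
#' @slot mean population mean of the valid masked pixels.
#' @slot sd sample standard deviation (divide by n - 1).
#' @slot n number of valid pixels summarized.
#' @slot units units tag: \code{"s"} for decorrelation-time maps,
#'   \code{"dimensionless"} for contrast maps, or caller-supplied (e.g.
#'   \code{"Pa"} for external stiffness tables).
#' @export
setClass("ROISummary",
  representation(mean = "numeric", sd = "numeric", n = "integer", units = "character"))

setValidity("ROISummary", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (!is.finite(object@mean) || !is.finite(object@sd)) return("mean/sd must be finite")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' @param mean,sd,n summary statistics (sd is the sample standard
#'   deviation).
#' @param units units tag.
#' @rdname ROISummary-class
#' @export
roiSummaryStats <- function(mean, sd, n, units = "dimensionless") {
  new("ROISummary", mean = mean, sd = sd, n = as.integer(n), units = units)
}

setMethod("show", "ROISummary", function(object) {
  cat(sprintf("ROISummary: mean %.4g, sd %.4g, n %d [%s]\n",
              object@mean, object@sd, object@n, object@units))
})

#' Mirror a region of interest about the horizontal midline
#'
#' Reflects the mask row-wise (row r maps to row H + 1 - r, same column),
#' producing the symmetrically located control region in the opposite
#' hemisphere. Pixel count is preserved; mirroring twice is the identity.
#' If the mirrored mask overlaps the original, a warning is issued (the
#' control region would share pixels with the tumour region) but the mask
#' is still returned.
#'
#' @param roi an [ROIMask-class].
#' @param axis mirroring axis; only \code{"horizontal-midline"} is
#'   implemented.
#' @return An [ROIMask-class] labelled \code{"control"}.
#' @examples
#' m <- matrix(FALSE, 10, 4); m[1, 2] <- TRUE
#' which(mirrorROI(roiMask(m))@mask, arr.ind = TRUE)   # row 10, col 2
#' @export
mirrorROI <- function(roi, axis = "horizontal-midline") {
  validObject(roi)
  axis <- match.arg(axis, "horizontal-midline")
  h <- nrow(roi@mask)
  flipped <- roi@mask[h:1, , drop = FALSE]
  if (any(flipped & roi@mask))
    warning("mirrored ROI overlaps the original ROI")
  roiMask(flipped, label = "control",
          provenance = sprintf("mirrored (%s) from: %s", axis, roi@provenance))
}

#' Rasterize a polygon ROI to a mask
#'
#' Converts a polygon given as (row, col) vertices to a logical mask using
#' even-odd (ray casting) point-in-polygon over pixel centers. Coordinates
#' follow the in-memory convention (1-based); the JSON ROI reader converts
#' from the on-disk 0-based convention.
#'
#' @param vertices numeric matrix with two columns (row, col), one vertex
#'   per row.
#' @param height,width mask size in pixels.
#' @param label,provenance passed to [roiMask()].
#' @return An [ROIMask-class].
#' @export
polygonROI <- function(vertices, height, width, label = "tumour",
                       provenance = "drawn polygon") {
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 (row, col) matrix with n >= 3")
  vr <- vertices[, 1]; vc <- vertices[, 2]
  n <- length(vr)
  px <- matrix(rep(seq_len(height), width), ncol = width)        # rows
  py <- matrix(rep(seq_len(width), each = height), ncol = width) # cols
  inside <- matrix(FALSE, height, width)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vc[i] > py) != (vc[j] > py)) &
      (px < (vr[j] - vr[i]) * (py - vc[i]) / (vc[j] - vc[i]) + vr[i])
    inside <- xor(inside, cross)
    j <- i
  }
  roiMask(inside, label = label, provenance = provenance)
}

#' Summarize a map over a region of interest
#'
#' Computes the mean, sample standard deviation (divide by n - 1) and count
#' of the valid pixels under the mask. Invalid pixels (e.g. decorrelation
#' failures) are excluded and do not contribute to n.
#'
#' @param map a [TauCMap-class], [ContrastMap-class] or plain numeric
#'   matrix (NA = invalid).
#' @param roi an [ROIMask-class] of the same shape.
#' @param units override the units tag (defaults to \code{"s"} for
#'   decorrelation-time maps, \code{"dimensionless"} otherwise).
#' @return An [ROISummary-class].
#' @export
roiSummary <- function(map, roi, units = NULL) {
  validObject(roi)
  if (is(map, "TauCMap")) {
    vals <- pixelValues(map)
    if (is.null(units)) units <- "s"
  } else if (is(map, "ContrastMap")) {
    vals <- pixelValues(map)
  } else if (is.matrix(map)) {
    vals <- map
  } else stop("map must be a TauCMap, ContrastMap or matrix")
  if (is.null(units)) units <- "dimensionless"
  if (!identical(dim(vals), dim(roi@mask))) stop("map and ROI shapes differ")
  v <- vals[roi@mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no valid pixels under the ROI")
  s <- if (length(v) > 1L) stats::sd(v) else 0
  roiSummaryStats(mean(v), s, length(v), units = units)
}

#' Region signal-to-noise ratio
#'
#' The modality-comparison metric \eqn{SNR_T = \mu_T / \sigma_T} of a
#' (tumour) region: the ratio of the region mean to its standard deviation,
#' chosen over \eqn{(\mu_T - \mu_C)/\sigma_T} because a single image is
#' typically all that is available in practice.
#'
#' @param summary an [ROISummary-class] with \code{sd > 0}.
#' @return The dimensionless SNR.
#' @examples
#' computeSNR(roiSummaryStats(0.67, 0.206, 100, units = "s"))   # 3.25...
#' @export
computeSNR <- function(summary) {
  validObject(summary)
  if (summary@sd == 0) stop("sd is zero: SNR is undefined")
  summary@mean / summary@sd
}

#' Welch's two-sample t test from region summaries
#'
#' Computes \eqn{t = (\mu_T - \mu_C) / \sqrt{\sigma_T^2/n +
#' \sigma_C^2/m}}, the unequal-variance two-sample statistic, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value from the
#' Student t distribution.
#'
#' @param summaryT,summaryC [ROISummary-class] objects with \code{n >= 2};
#'   at least one must have positive sd.
#' @return A list: \code{t}, \code{df}, \code{p}, \code{snrT} (the tumour
#'   region SNR, NA if its sd is 0).
#' @examples
#' st <- roiSummaryStats(6, sd(c(5, 5, 7, 7)), 4)
#' sc <- roiSummaryStats(2, sd(c(1, 1, 3, 3)), 4)
#' welchTTest(st, sc)$t    # 4.899
#' @export
welchTTest <- function(summaryT, summaryC) {
  validObject(summaryT); validObject(summaryC)
  if (summaryT@n < 2L || summaryC@n < 2L) stop("both regions need n >= 2")
  vT <- summaryT@sd^2 / summaryT@n
  vC <- summaryC@sd^2 / summaryC@n
  if (vT + vC == 0) stop("both regions have zero variance: t is undefined")
  t <- (summaryT@mean - summaryC@mean) / sqrt(vT + vC)
  df <- (vT + vC)^2 / (vT^2 / (summaryT@n - 1) + vC^2 / (summaryC@n - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  snrT <- if (summaryT@sd > 0) summaryT@mean / summaryT@sd else NA_real_
  list(t = t, df = df, p = p, snrT = snrT)
}

#' Pre/post difference image
#'
#' Element-wise \code{post - pre} of two co-registered maps of the same
#' modality and shape (no registration is performed; the caller asserts
#' alignment). Pixels invalid in either input are \code{NA} in the output.
#'
#' @param post,pre [TauCMap-class], [ContrastMap-class] or numeric
#'   matrices, both of the same shape.
#' @return A numeric matrix (same units as the inputs).
#' @export
differenceMap <- function(post, pre) {
  val <- function(m) {
    if (is(m, "TauCMap") || is(m, "ContrastMap")) pixelValues(m)
    else if (is.matrix(m)) m
    else stop("inputs must be maps or matrices")
  }
  a <- val(post); b <- val(pre)
  if (!identical(dim(a), dim(b))) stop("maps have different shapes")
  a - b
}

#' Modality comparison table for one map
#'
#' Builds one row of the modality-comparison table: control and tumour
#' means and standard deviations, the tumour-region SNR and the Welch t
#' statistic between the two pixel populations.
#'
#' @param map a map object or matrix (see [roiSummary()]).
#' @param tumourROI,controlROI [ROIMask-class] regions; the control
#'   defaults to the mirrored tumour region.
#' @param modality row label.
#' @return A one-row data.frame with columns \code{modality}, \code{muC},
#'   \code{sigmaC}, \code{muT}, \code{sigmaT}, \code{snrT}, \code{t},
#'   \code{p}.
#' @export
modalityTable <- function(map, tumourROI, controlROI = mirrorROI(tumourROI),
                          modality = "map") {
  st <- roiSummary(map, tumourROI)
  sc <- roiSummary(map, controlROI)
  tt <- welchTTest(st, sc)
  data.frame(modality = modality, muC = sc@mean, sigmaC = sc@sd,
             muT = st@mean, sigmaT = st@sd,
             snrT = computeSNR(st), t = tt$t, p = tt$p)
}
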
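#' Remove slowly varying background from a frame
#'
#' Image flattening: subtracts a wide median-filtered copy of the frame, so
#' that background structure on scales much larger than a diffraction-limited
#' spot (uneven illumination, cytosolic fluorescence gradients) is removed
#' while spot-scale structure is preserved.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param kernelRadiusPx Radius of the median kernel, pixels; must be at
#'   least the outer radius of the spot filter so spots do not leak into
#'   the background estimate (default 10).
#' @return Flattened frame (same dimensions), approximately zero-mean in
#'   background regions.
#' @export
flattenBackground <- function(frame, kernelRadiusPx = 10) {
  if (!is.matrix(frame) || !all(is.finite(frame)))
    stop("'frame' must be a finite numeric matrix")
  kernelRadiusPx <- as.integer(kernelRadiusPx)
  if (kernelRadiusPx < 1L)
    stop("'kernelRadiusPx' must be >= 1")
  if (2L * kernelRadiusPx + 1L > min(dim(frame)))
    stop("median kernel larger than the image")
  rng <- range(frame)
  if (diff(rng) == 0) return(frame - frame[1])
  scaled <- (frame - rng[1]) / diff(rng)
  bg <- EBImage::medianFilter(scaled, kernelRadiusPx) * diff(rng) + rng[1]
  frame - bg
}

# Inner-disc and annulus membership masks on the pixel-centre grid,
# Euclidean distance with <= comparisons; the centre pixel belongs to the
# inner disc.
discoidalKernel <- function(rIn, rOut) {
  r <- ceiling(rOut)
  d <- sqrt(outer((-r:r)^2, (-r:r)^2, "+"))
  inner <- d <= rIn
  annulus <- d > rIn & d <= rOut
  inner / sum(inner) - annulus / sum(annulus)
}

#' Discoidal average filter
#'
#' The spot-enhancing band-pass used for focus detection: each output pixel
#' is the mean intensity over the inner disc of radius `rIn` (Euclidean
#' pixel-centre distance, centre pixel included) minus the mean over the
#' annulus `rIn <` distance `<= rOut`. Uniform regions and exact linear
#' gradients map to zero; compact spots of roughly the inner-disc size give
#' a strong positive response. Borders are handled by mirror reflection.
#'
#' @param image Numeric matrix.
#' @param rIn Inner disc radius, pixels (default 1).
#' @param rOut Outer annulus radius, pixels (default 3); must exceed `rIn`.
#' @return Filtered matrix of the same dimensions.
#' @examples
#' img <- matrix(0, 16, 16); img[8, 8] <- 1
#' f <- discoidalFilter(img)
#' f[8, 8]  # 1 / (inner-disc pixel count) = 1/5
#' @export
discoidalFilter <- function(image, rIn = 1, rOut = 3) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  if (any(!is.finite(image))) stop("non-finite pixels in 'image'")
  if (!(rOut > rIn) || rIn < 0) stop("need rOut > rIn >= 0")
  correlate2d(image, discoidalKernel(rIn, rOut))
}

#' Detect foci in one filtered frame
#'
#' Thresholds a discoidal-filtered frame at `relativeThreshold` times the
#' robust background standard deviation (median absolute deviation scaled to
#' the Gaussian, which resists contamination by the spots themselves),
#' groups super-threshold pixels into 8-connected components, and reports
#' one focus per component at its intensity-weighted centroid. A degenerate
#' (zero-variance) frame yields zero foci.
#'
#' @param filtered Matrix as returned by [discoidalFilter()].
#' @param relativeThreshold Threshold in units of robust background SD
#'   (default 8).
#' @param minPixels Minimum component size in pixels (default 1).
#' @return data.frame with columns `x_px`, `y_px` (0-based centroid),
#'   `peak_filtered`, `n_pixels` and `background_sd`.
#' @export
detectFoci <- function(filtered, relativeThreshold = 8, minPixels = 1L) {
  if (!is.matrix(filtered)) stop("'filtered' must be a matrix")
  checkScalar(relativeThreshold, "relativeThreshold", 0)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      peak_filtered = numeric(0), n_pixels = integer(0),
                      background_sd = numeric(0))
  sdBg <- mad(filtered)
  if (!is.finite(sdBg) || sdBg == 0) return(empty)
  mask <- filtered > relativeThreshold * sdBg
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0)
  lab <- labels[idx]
  w <- filtered[idx]
  row0 <- (idx - 1L) %% nrow(filtered)       # 0-based y
  col0 <- (idx - 1L) %/% nrow(filtered)      # 0-based x
  sw <- tapply(w, lab, sum)
  out <- data.frame(
    x_px = as.numeric(tapply(w * col0, lab, sum) / sw),
    y_px = as.numeric(tapply(w * row0, lab, sum) / sw),
    peak_filtered = as.numeric(tapply(w, lab, max)),
    n_pixels = as.integer(tapply(w, lab, length)),
    background_sd = sdBg)
  out <- out[out$n_pixels >= minPixels, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect foci across the single-molecule phase of a movie
#'
#' Runs flattening, discoidal filtering and thresholded detection on every
#' single-molecule-phase frame of a [MovieStack-class]; bleach-down frames
#' are excluded. Frame indices in the output are 0-based within the full
#' stack, so the first analysed frame is `nBleachFrames`.
#'
#' @param movie A [MovieStack-class].
#' @param flattenRadiusPx Median-kernel radius for [flattenBackground()];
#'   set to 0 to skip flattening.
#' @param rIn,rOut Discoidal filter radii, pixels.
#' @param relativeThreshold Detection threshold in robust background SDs.
#' @param minPixels Minimum component size.
#' @return Focus table data.frame: `condition_id`, `frame`, `x_px`, `y_px`,
#'   `peak_filtered`, `background_sd`.
#' @export
detectStack <- function(movie, flattenRadiusPx = 10, rIn = 1, rOut = 3,
                        relativeThreshold = 8, minPixels = 1L) {
  stopifnot(is(movie, "MovieStack"))
  p <- movie@protocol
  frames <- seq(p@nBleachFrames, p@nBleachFrames + p@nFrames - 1L)
  res <- lapply(frames, function(f) {
    img <- movie@frames[, , f + 1L]
    if (flattenRadiusPx > 0) img <- flattenBackground(img, flattenRadiusPx)
    foci <- detectFoci(discoidalFilter(img, rIn, rOut),
                       relativeThreshold, minPixels)
    if (nrow(foci))
      cbind(condition_id = movie@conditionIndex, frame = f,
            foci[c("x_px", "y_px", "peak_filtered", "background_sd")])
    else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(condition_id = integer(0), frame = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      peak_filtered = numeric(0), background_sd = numeric(0))
  rownames(res) <- NULL
  res
}
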
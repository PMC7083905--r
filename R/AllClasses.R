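#' @import methods
#' @importFrom stats rexp rgeom rpois rnorm runif mad sd lm coef vcov
#'   complete.cases setNames median
#' @importFrom utils read.csv write.csv head tail
NULL

#' Dissociation kinetics model with photobleaching
#'
#' A `KineticModel` describes the ground-truth (or fitted) dissociation
#' kinetics of a DNA-binding fluorescent protein as a one- or two-component
#' exponential mixture, together with the photobleaching rate of the
#' fluorophore. Bound times are drawn from
#' \eqn{\sum_i A_i k_{off,i} e^{-k_{off,i} t}} and photobleaching proceeds at
#' rate `kb` per second of *illuminated* time only (dark intervals are
#' bleach-free, which is the premise that lets interval imaging separate the
#' two rates).
#'
#' @slot amplitudes Numeric vector (length 1 or 2) of mixture fractions;
#'   strictly positive and summing to 1.
#' @slot koff Numeric vector of dissociation rates, per second; the lifetime
#'   of component *i* is `1/koff[i]`.
#' @slot kb Photobleaching rate, per second of illuminated exposure.
#'
#' @seealso [kineticModel()], [sampleDwellTimes()], [simulateObservedFrames()]
#' @export
setClass("KineticModel",
  representation(amplitudes = "numeric", koff = "numeric", kb = "numeric"))

setValidity("KineticModel", function(object) {
  msg <- character()
  n <- length(object@amplitudes)
  if (n < 1L || n > 2L)
    msg <- c(msg, "number of components must be 1 or 2")
  if (length(object@koff) != n)
    msg <- c(msg, "amplitudes and koff must have the same length")
  if (any(object@amplitudes <= 0))
    msg <- c(msg, "amplitudes must be strictly positive")
  if (n >= 1L && abs(sum(object@amplitudes) - 1) > 1e-12)
    msg <- c(msg, "amplitudes must sum to 1 (within 1e-12)")
  if (any(object@koff < 0) || length(object@kb) != 1L || object@kb < 0)
    msg <- c(msg, "all rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a KineticModel
#'
#' @param koff Dissociation rate(s), per second (one or two components).
#' @param amplitudes Mixture fractions, summing to 1. Defaults to a single
#'   component.
#' @param kb Photobleaching rate per second of illuminated exposure
#'   (default 0).
#' @param lifetimes Alternative to `koff`: bound lifetimes in seconds
#'   (`koff = 1/lifetimes`). Supply one of `koff` or `lifetimes`.
#' @return A validated [KineticModel-class] object.
#' @examples
#' kineticModel(lifetimes = c(26, 1.1), amplitudes = c(0.32, 0.68), kb = 1)
#' @export
kineticModel <- function(koff = NULL, amplitudes = NULL, kb = 0,
                         lifetimes = NULL) {
  if (is.null(koff) == is.null(lifetimes))
    stop("supply exactly one of 'koff' or 'lifetimes'")
  if (is.null(koff)) koff <- 1 / lifetimes
  if (is.null(amplitudes)) {
    if (length(koff) != 1L)
      stop("'amplitudes' required for a two-component model")
    amplitudes <- 1
  }
  new("KineticModel", amplitudes = as.numeric(amplitudes),
      koff = as.numeric(koff), kb = as.numeric(kb))
}

#' Two-phase interval-imaging acquisition protocol
#'
#' Describes the acquisition scheme: a bleach-down phase of continuous
#' exposures followed by a single-molecule phase in which frames of exposure
#' `tauInt` are taken either back-to-back (dark interval 0, i.e. continuous
#' imaging) or separated by a dark interval `tauD`. One protocol carries the
#' whole set of dark-interval conditions used in an experiment; the frame
#' period of condition *c* is \eqn{\tau_{tl} = \tau_{int} + \tau_{d,c}}.
#'
#' @slot tauInt Exposure duration per frame, seconds.
#' @slot tauD Numeric vector of dark intervals, seconds; 0 encodes
#'   continuous imaging.
#' @slot nBleachFrames Number of continuous bleach-down frames (phase I).
#' @slot nFrames Number of frames in the single-molecule phase (phase II).
#' @slot pixelSizeNm Physical pixel size, nanometres.
#' @slot fieldShape Integer height and width of the field, pixels.
#'
#' @seealso [acquisitionProtocol()], [tauTl()]
#' @export
setClass("AcquisitionProtocol",
  representation(tauInt = "numeric", tauD = "numeric",
                 nBleachFrames = "integer", nFrames = "integer",
                 pixelSizeNm = "numeric", fieldShape = "integer"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (length(object@tauInt) != 1L || object@tauInt <= 0)
    msg <- c(msg, "tauInt must be a single positive number")
  if (length(object@tauD) < 1L || any(object@tauD < 0))
    msg <- c(msg, "every tauD must be >= 0")
  if (object@nFrames < 2L)
    msg <- c(msg, "nFrames must be >= 2")
  if (object@nBleachFrames < 0L)
    msg <- c(msg, "nBleachFrames must be >= 0")
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 1L))
    msg <- c(msg, "fieldShape must be two positive integers (height, width)")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionProtocol
#'
#' Defaults reproduce the standard interval-imaging schedule: 0.1-s
#' exposures, dark intervals 0 (continuous), 0.1, 0.2, 0.3, 0.5, 0.9, 1.9,
#' 2.9, 4.9, 7.9 and 9.9 s, a 50-frame bleach-down phase and a 100-frame
#' single-molecule phase, with 106-nm pixels.
#'
#' @param tauInt Exposure per frame, seconds.
#' @param tauD Dark intervals, seconds (0 = continuous imaging).
#' @param nBleachFrames Frames in the bleach-down phase.
#' @param nFrames Frames in the single-molecule phase.
#' @param pixelSizeNm Pixel size in nanometres.
#' @param fieldShape Image height and width in pixels.
#' @return A validated [AcquisitionProtocol-class] object.
#' @examples
#' acquisitionProtocol()                    # the full 11-condition schedule
#' acquisitionProtocol(tauD = 0, fieldShape = c(64, 64))
#' @export
acquisitionProtocol <- function(tauInt = 0.1,
                                tauD = c(0, 0.1, 0.2, 0.3, 0.5, 0.9,
                                         1.9, 2.9, 4.9, 7.9, 9.9),
                                nBleachFrames = 50L, nFrames = 100L,
                                pixelSizeNm = 106, fieldShape = c(512L, 512L)) {
  new("AcquisitionProtocol", tauInt = as.numeric(tauInt),
      tauD = as.numeric(tauD), nBleachFrames = as.integer(nBleachFrames),
      nFrames = as.integer(nFrames), pixelSizeNm = as.numeric(pixelSizeNm),
      fieldShape = as.integer(fieldShape))
}

#' Rendered fluorescence movie with acquisition metadata
#'
#' Pixel intensities for one interval condition as a `height x width x frame`
#' array (frame 1 is the first bleach-down frame), with the acquisition
#' protocol, the condition index and the rendering noise parameters attached.
#'
#' @slot frames Numeric array, `fieldShape[1] x fieldShape[2] x`
#'   `(nBleachFrames + nFrames)`; all intensities >= 0.
#' @slot protocol The [AcquisitionProtocol-class] the movie was acquired
#'   (or rendered) under.
#' @slot conditionIndex Which entry of `tauD(protocol)` this movie uses
#'   (1-based).
#' @slot noiseParams Named list of rendering parameters (background,
#'   spot amplitude, PSF sigma, camera offset, read noise).
#' @export
setClass("MovieStack",
  representation(frames = "array", protocol = "AcquisitionProtocol",
                 conditionIndex = "integer", noiseParams = "list"))

setValidity("MovieStack", function(object) {
  msg <- character()
  p <- object@protocol
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-d array (height, width, frame)")
  else {
    if (!all(d[1:2] == p@fieldShape))
      msg <- c(msg, "frame dimensions must match protocol fieldShape")
    if (d[3] != p@nBleachFrames + p@nFrames)
      msg <- c(msg, "frame count must equal nBleachFrames + nFrames")
  }
  if (any(!is.finite(object@frames)) || any(object@frames < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (object@conditionIndex < 1L ||
      object@conditionIndex > length(p@tauD))
    msg <- c(msg, "conditionIndex out of range for protocol tauD")
  if (length(msg)) msg else TRUE
})

#' Cumulative residence time distribution for one interval condition
#'
#' For the frame-period grid \eqn{t_m = m\,\tau_{tl}}, `counts[m]` is the
#' number of binding events whose apparent dwell is at least \eqn{t_m}.
#' Counts are non-increasing and `counts[1]` equals the number of events
#' when no minimum-dwell filter was applied.
#'
#' @slot conditionId Integer condition index (1-based).
#' @slot tauInt Exposure duration, seconds.
#' @slot tauD Dark interval, seconds.
#' @slot time Time grid `m * (tauInt + tauD)`, seconds, m = 1, 2, ...
#' @slot counts Survival counts on the grid.
#' @slot totalEvents Number of events the CRTD was built from.
#' @seealso [computeCrtd()], [crtdModel()], [globalFit()]
#' @export
setClass("CRTD",
  representation(conditionId = "integer", tauInt = "numeric",
                 tauD = "numeric", time = "numeric", counts = "numeric",
                 totalEvents = "integer"))

setValidity("CRTD", function(object) {
  msg <- character()
  if (length(object@time) != length(object@counts))
    msg <- c(msg, "time and counts must have equal length")
  if (length(object@counts) && any(diff(object@counts) > 0))
    msg <- c(msg, "counts must be non-increasing in time")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be >= 0")
  if (object@tauD < 0 || object@tauInt <= 0)
    msg <- c(msg, "tauInt must be > 0 and tauD >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a global photobleaching-corrected exponential fit
#'
#' Holds the parameters of a single- or bi-exponential dissociation model
#' fitted jointly across all interval conditions with a shared
#' photobleaching rate and a free scale per condition, plus (after
#' [bootstrapFit()]) the bootstrap parameter distribution and its summary.
#' Components are stored slow-first (longest lifetime first), matching the
#' usual slow/fast population labelling.
#'
#' @slot modelOrder 1 or 2 exponential components.
#' @slot kb Shared photobleaching rate, per illuminated second.
#' @slot koff Dissociation rates, per second, ordered slow-first.
#' @slot amplitudes Mixture fractions, summing to 1, aligned with `koff`.
#' @slot scales Free per-condition scale factors.
#' @slot rss Residual sum of squares of the fit objective (weighted when
#'   count weighting is on).
#' @slot rssPlain Unweighted residual sum of squares at the optimum, used
#'   for model comparison.
#' @slot nPoints Number of fitted CRTD points.
#' @slot nEvents Events per condition underlying the CRTDs.
#' @slot conditions Data frame of the fitted conditions
#'   (conditionId, tauInt, tauD, tauTl).
#' @slot converged Logical convergence flag (never silent: inspect
#'   `message` when FALSE).
#' @slot info Integer optimizer termination code.
#' @slot message Optimizer termination message.
#' @slot bootstrapSamples Data frame of per-replicate refitted parameters
#'   (empty until [bootstrapFit()] fills it).
#' @slot bootstrapSummary Data frame of mean and SD per parameter over the
#'   bootstrap distribution.
#' @export
setClass("GlobalFitResult",
  representation(modelOrder = "integer", kb = "numeric", koff = "numeric",
                 amplitudes = "numeric", scales = "numeric", rss = "numeric",
                 rssPlain = "numeric", nPoints = "integer",
                 nEvents = "numeric",
                 conditions = "data.frame", converged = "logical",
                 info = "integer", message = "character",
                 bootstrapSamples = "data.frame",
                 bootstrapSummary = "data.frame"))

setValidity("GlobalFitResult", function(object) {
  msg <- character()
  if (!(object@modelOrder %in% c(1L, 2L)))
    msg <- c(msg, "modelOrder must be 1 or 2")
  if (length(object@koff) != object@modelOrder ||
      length(object@amplitudes) != object@modelOrder)
    msg <- c(msg, "koff and amplitudes must have length modelOrder")
  if (any(object@amplitudes <= 0) ||
      abs(sum(object@amplitudes) - 1) > 1e-8)
    msg <- c(msg, "amplitudes must be positive and sum to 1")
  if (any(object@koff < 0) || any(object@kb < 0))
    msg <- c(msg, "rates must be >= 0")
  if (is.unsorted(object@koff))
    msg <- c(msg, "components must be ordered slow-first (ascending koff)")
  if (length(msg)) msg else TRUE
})
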
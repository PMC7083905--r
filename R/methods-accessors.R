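# Accessor and show methods. Kept terse: one method per slot view.

#' @describeIn accessors Lifetimes 1/koff of a kinetic model.
#' @export
setMethod("lifetimes", "KineticModel", function(object, ...) 1 / object@koff)

#' @describeIn accessors Dissociation rates of a kinetic model.
#' @export
setMethod("dissociationRates", "KineticModel",
          function(object, ...) object@koff)

#' @describeIn accessors Photobleaching rate of a kinetic model.
#' @export
setMethod("bleachRate", "KineticModel", function(object, ...) object@kb)

#' @describeIn accessors Mixture fractions of a kinetic model.
#' @export
setMethod("amplitudes", "KineticModel", function(object, ...)
  object@amplitudes)

#' @describeIn accessors Exposure duration of a protocol.
#' @export
setMethod("tauInt", "AcquisitionProtocol", function(object, ...)
  object@tauInt)

#' @describeIn accessors Dark-interval schedule of a protocol.
#' @export
setMethod("tauD", "AcquisitionProtocol", function(object, ...) object@tauD)

#' @describeIn tauTl Frame periods of a protocol (optionally one condition).
#' @export
setMethod("tauTl", "AcquisitionProtocol",
          function(object, conditionIndex = NULL, ...) {
  tl <- object@tauInt + object@tauD
  if (is.null(conditionIndex)) tl else tl[conditionIndex]
})

#' @describeIn accessors Number of phase-II frames of a protocol.
#' @export
setMethod("frames", "AcquisitionProtocol", function(object, ...)
  object@nFrames)

#' @describeIn accessors Pixel array of a movie.
#' @export
setMethod("frames", "MovieStack", function(object, ...) object@frames)

#' @describeIn accessors Protocol attached to a movie.
#' @export
setMethod("protocol", "MovieStack", function(object, ...) object@protocol)

#' @describeIn accessors Condition index of a movie.
#' @export
setMethod("conditionIndex", "MovieStack", function(object, ...)
  object@conditionIndex)

#' @describeIn tauTl Frame period of the movie's condition.
#' @export
setMethod("tauTl", "MovieStack", function(object, ...)
  tauTl(object@protocol, object@conditionIndex))

#' @describeIn accessors Condition index of a CRTD.
#' @export
setMethod("conditionIndex", "CRTD", function(object, ...)
  object@conditionId)

#' @describeIn accessors Exposure duration of a CRTD's condition.
#' @export
setMethod("tauInt", "CRTD", function(object, ...) object@tauInt)

#' @describeIn accessors Dark interval of a CRTD's condition.
#' @export
setMethod("tauD", "CRTD", function(object, ...) object@tauD)

#' @describeIn tauTl Frame period of a CRTD's condition.
#' @export
setMethod("tauTl", "CRTD", function(object, ...)
  object@tauInt + object@tauD)

#' @describeIn accessors Time grid of a CRTD.
#' @export
setMethod("timeGrid", "CRTD", function(object, ...) object@time)

#' @describeIn accessors Survival counts of a CRTD.
#' @export
setMethod("crtdCounts", "CRTD", function(object, ...) object@counts)

#' @describeIn accessors Number of events underlying a CRTD.
#' @export
setMethod("totalEvents", "CRTD", function(object, ...) object@totalEvents)

#' @describeIn accessors Lifetimes 1/koff of a fit, slow-first.
#' @export
setMethod("lifetimes", "GlobalFitResult", function(object, ...)
  1 / object@koff)

#' @describeIn accessors Dissociation rates of a fit, slow-first.
#' @export
setMethod("dissociationRates", "GlobalFitResult", function(object, ...)
  object@koff)

#' @describeIn accessors Shared photobleaching rate of a fit.
#' @export
setMethod("bleachRate", "GlobalFitResult", function(object, ...) object@kb)

#' @describeIn accessors Mixture fractions of a fit, slow-first.
#' @export
setMethod("amplitudes", "GlobalFitResult", function(object, ...)
  object@amplitudes)

#' @describeIn accessors Model order (1 or 2) of a fit.
#' @export
setMethod("modelOrder", "GlobalFitResult", function(object, ...)
  object@modelOrder)

#' @describeIn accessors Per-condition scale factors of a fit.
#' @export
setMethod("conditionScales", "GlobalFitResult", function(object, ...)
  object@scales)

#' @describeIn accessors Residual sum of squares of a fit.
#' @export
setMethod("residualSumOfSquares", "GlobalFitResult", function(object, ...)
  object@rss)

#' @describeIn accessors Convergence flag of a fit.
#' @export
setMethod("converged", "GlobalFitResult", function(object, ...)
  object@converged)

#' @describeIn accessors Bootstrap replicate parameters of a fit.
#' @export
setMethod("bootstrapSamples", "GlobalFitResult", function(object, ...)
  object@bootstrapSamples)

#' @describeIn accessors Bootstrap mean/SD summary of a fit.
#' @export
setMethod("bootstrapSummary", "GlobalFitResult", function(object, ...)
  object@bootstrapSummary)

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel with", length(object@koff), "component(s)\n")
  for (i in seq_along(object@koff))
    cat(sprintf("  component %d: amplitude %.3f, koff %.4g /s (lifetime %.4g s)\n",
                i, object@amplitudes[i], object@koff[i], 1 / object@koff[i]))
  cat(sprintf("  photobleaching kb: %.4g per illuminated s\n", object@kb))
})

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol:", length(object@tauD), "interval condition(s)\n")
  cat(sprintf("  tauInt %.3g s; tauD %s s\n", object@tauInt,
              paste(format(object@tauD), collapse = ", ")))
  cat(sprintf("  phase I %d frames, phase II %d frames; field %dx%d px (%.0f nm/px)\n",
              object@nBleachFrames, object@nFrames, object@fieldShape[1],
              object@fieldShape[2], object@pixelSizeNm))
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("MovieStack: %d x %d px, %d frames (condition %d, tauD %.3g s)\n",
              d[1], d[2], d[3], object@conditionIndex,
              object@protocol@tauD[object@conditionIndex]))
})

setMethod("show", "CRTD", function(object) {
  cat(sprintf("CRTD (condition %d, tauTl %.3g s): %d events, %d grid points\n",
              object@conditionId, object@tauInt + object@tauD,
              object@totalEvents, length(object@time)))
})

setMethod("show", "GlobalFitResult", function(object) {
  cat(sprintf("GlobalFitResult: %d-exponential global fit over %d condition(s)\n",
              object@modelOrder, nrow(object@conditions)))
  lab <- if (object@modelOrder == 2L) c("slow", "fast") else "single"
  for (i in seq_len(object@modelOrder))
    cat(sprintf("  %s: lifetime %.4g s (koff %.4g /s), amplitude %.3f\n",
                lab[i], 1 / object@koff[i], object@koff[i],
                object@amplitudes[i]))
  cat(sprintf("  shared kb %.4g per illuminated s; RSS %.4g over %d points; %s\n",
              object@kb, object@rss, object@nPoints,
              if (object@converged) "converged" else
                paste("NOT converged:", object@message)))
  if (nrow(object@bootstrapSamples))
    cat(sprintf("  bootstrap: %d replicate(s); see bootstrapSummary()\n",
                nrow(object@bootstrapSamples)))
})
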
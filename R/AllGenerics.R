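#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes; slot access in user
#' code should always go through these.
#'
#' @param object An object of one of the package's S4 classes.
#' @param ... Passed to methods.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object, ...) standardGeneric("lifetimes"))

#' @rdname accessors
#' @export
setGeneric("dissociationRates",
           function(object, ...) standardGeneric("dissociationRates"))

#' @rdname accessors
#' @export
setGeneric("bleachRate", function(object, ...) standardGeneric("bleachRate"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object, ...) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("tauInt", function(object, ...) standardGeneric("tauInt"))

#' @rdname accessors
#' @export
setGeneric("tauD", function(object, ...) standardGeneric("tauD"))

#' Frame period(s) of an acquisition
#'
#' The frame period of an interval condition is the exposure plus the dark
#' interval, \eqn{\tau_{tl} = \tau_{int} + \tau_d}; for continuous imaging
#' it equals the exposure.
#'
#' @param object An [AcquisitionProtocol-class], [CRTD-class] or
#'   [MovieStack-class].
#' @param ... For the protocol method, `conditionIndex` selects one
#'   condition; by default all periods are returned.
#' @return Frame period(s) in seconds.
#' @export
setGeneric("tauTl", function(object, ...) standardGeneric("tauTl"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object, ...) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(object, ...) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("conditionIndex",
           function(object, ...) standardGeneric("conditionIndex"))

#' @rdname accessors
#' @export
setGeneric("timeGrid", function(object, ...) standardGeneric("timeGrid"))

#' @rdname accessors
#' @export
setGeneric("crtdCounts", function(object, ...) standardGeneric("crtdCounts"))

#' @rdname accessors
#' @export
setGeneric("totalEvents", function(object, ...) standardGeneric("totalEvents"))

#' @rdname accessors
#' @export
setGeneric("modelOrder", function(object, ...) standardGeneric("modelOrder"))

#' @rdname accessors
#' @export
setGeneric("conditionScales",
           function(object, ...) standardGeneric("conditionScales"))

#' @rdname accessors
#' @export
setGeneric("residualSumOfSquares",
           function(object, ...) standardGeneric("residualSumOfSquares"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object, ...) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("bootstrapSamples",
           function(object, ...) standardGeneric("bootstrapSamples"))

#' @rdname accessors
#' @export
setGeneric("bootstrapSummary",
           function(object, ...) standardGeneric("bootstrapSummary"))
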
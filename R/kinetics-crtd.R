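#' Build the cumulative residence time distribution for one condition
#'
#' On the frame-period grid \eqn{t_m = m\,\tau_{tl}}, the CRTD counts the
#' binding events whose apparent dwell is at least \eqn{t_m}. Counts are
#' exact survival counts, non-increasing in \eqn{m}, and `counts[1]` equals
#' the number of events when no minimum-dwell filter was applied upstream.
#'
#' @param dwells Dwell table with `n_frames` (or `dwell_s`) for one
#'   condition, e.g. from [extractDwells()].
#' @param protocol An [AcquisitionProtocol-class].
#' @param conditionIndex Condition of the dwell table.
#' @param mMax Largest frame multiple of the grid; defaults to the longest
#'   observed event.
#' @return A [CRTD-class].
#' @examples
#' p <- acquisitionProtocol(tauD = 0.9)
#' d <- data.frame(condition_id = 1, n_frames = c(1, 2, 3))
#' crtdCounts(computeCrtd(d, p, 1))  # 3 2 1
#' @export
computeCrtd <- function(dwells, protocol, conditionIndex, mMax = NULL) {
  conditionIndex <- checkConditionIndex(protocol, conditionIndex)
  if (!nrow(dwells)) stop("empty dwell table")
  tl <- tauTl(protocol, conditionIndex)
  nf <- if ("n_frames" %in% names(dwells)) dwells$n_frames
        else round(dwells$dwell_s / tl)
  if (any(nf < 1)) stop("all dwells must span at least one frame")
  if (is.null(mMax)) mMax <- max(nf)
  m <- seq_len(mMax)
  counts <- vapply(m, function(k) sum(nf >= k), numeric(1))
  new("CRTD", conditionId = conditionIndex, tauInt = protocol@tauInt,
      tauD = protocol@tauD[conditionIndex], time = m * tl, counts = counts,
      totalEvents = nrow(dwells))
}

#' Predicted relative survival of the interval-imaging decay model
#'
#' The model behind the global fit: under interval imaging the apparent
#' focus-loss rate of component *i* is the dissociation rate plus the
#' photobleaching rate rescaled by the illuminated duty cycle,
#' \eqn{k_{eff,i} = k_b \tau_{int}/\tau_{tl} + k_{off,i}}, so the predicted
#' relative survival at time *t* is
#' \eqn{S(t) = \sum_i A_i e^{-k_{eff,i} t}}. Because only \eqn{k_b} is
#' multiplied by the duty cycle, acquisitions with different dark intervals
#' share the same \eqn{k_{off}} but different apparent rates, which is what
#' makes the two rates separable in a global fit.
#'
#' @param t Time(s), seconds.
#' @param tauInt Exposure duration, seconds.
#' @param tauTl Frame period, seconds; must be >= `tauInt`.
#' @param kb Photobleaching rate, per illuminated second.
#' @param koff Dissociation rate(s), per second.
#' @param amplitudes Mixture fractions (default single component).
#' @return Predicted relative survival at `t`.
#' @examples
#' crtdModel(1, tauInt = 0.1, tauTl = 10, kb = 2, koff = 0.0072)
#' @export
crtdModel <- function(t, tauInt, tauTl, kb, koff, amplitudes = NULL) {
  if (is.null(amplitudes)) {
    if (length(koff) != 1L) stop("'amplitudes' required for a mixture")
    amplitudes <- 1
  }
  checkScalar(tauInt, "tauInt", 0, strict = TRUE)
  checkScalar(tauTl, "tauTl", 0, strict = TRUE)
  if (tauTl < tauInt) stop("tauTl must be >= tauInt")
  if (kb < 0 || any(koff < 0)) stop("rates must be >= 0")
  keff <- kb * tauInt / tauTl + koff
  drop(exp(-outer(t, keff)) %*% amplitudes)
}

#' Apparent bound lifetime under one interval condition
#'
#' The reciprocal of the effective focus-loss rate
#' \eqn{k_{eff} = k_b \tau_{int}/\tau_{tl} + k_{off}}: the lifetime a
#' single-condition exponential fit would report, shorter than the true
#' bound lifetime whenever photobleaching contributes.
#'
#' @param kb Photobleaching rate, per illuminated second.
#' @param tauInt Exposure duration, seconds.
#' @param tauTl Frame period, seconds.
#' @param koff Dissociation rate, per second.
#' @return Apparent lifetime, seconds.
#' @examples
#' apparentLifetime(kb = 2, tauInt = 0.1, tauTl = 10, koff = 0.0072)  # ~36.8
#' @export
apparentLifetime <- function(kb, tauInt, tauTl, koff) {
  if (kb < 0 || koff < 0) stop("rates must be >= 0")
  if (kb == 0 && koff == 0) stop("kb and koff cannot both be zero")
  if (tauTl < tauInt) stop("tauTl must be >= tauInt")
  1 / (kb * tauInt / tauTl + koff)
}

#' Expected scanning distance of a DNA translocase
#'
#' Distance travelled along DNA during one bound residence: translocation
#' rate times residence time, rounded to the nearest nucleotide. Used to
#' convert a measured residence time into the genomic length scale a
#' translocating repair factor can patrol downstream of its loading site.
#'
#' @param rateNtPerS Translocation rate, nucleotides per second (>= 0).
#' @param residenceTimeS Bound residence time, seconds (>= 0).
#' @return Integer nucleotides.
#' @examples
#' expectedScanningDistance(4, 29)  # 116
#' @export
expectedScanningDistance <- function(rateNtPerS, residenceTimeS) {
  checkScalar(rateNtPerS, "rateNtPerS", 0)
  checkScalar(residenceTimeS, "residenceTimeS", 0)
  as.integer(round(rateNtPerS * residenceTimeS))
}

#' Per-condition effective rates and their linearization
#'
#' Fits each condition's normalized CRTD independently to a single
#' exponential (free scale, effective rate \eqn{k_{eff}}), then exploits the
#' classical linearization: \eqn{k_{eff}\tau_{tl} = k_b\tau_{int} +
#' k_{off}\tau_{tl}}, so regressing \eqn{k_{eff}\tau_{tl}} on
#' \eqn{\tau_{tl}} gives slope \eqn{k_{off}} and intercept
#' \eqn{k_b\tau_{int}}. This is an independent, nearly assumption-free
#' estimator used to cross-check the global fit on single-component data.
#'
#' @param crtds List of [CRTD-class] objects spanning several frame periods.
#' @return List with `perCondition` (data.frame of tauTl and keff), `koff`,
#'   `koffSE`, `kbTauInt`, `kbTauIntSE` from the weighted line fit.
#' @export
linearizedRates <- function(crtds) {
  if (length(crtds) < 3L)
    stop("need >= 3 conditions for the linearization")
  per <- do.call(rbind, lapply(crtds, function(cr) {
    tl <- tauTl(cr)
    y <- cr@counts / cr@counts[1]
    t <- cr@time
    fit <- minpack.lm::nls.lm(
      par = c(k = 1 / stats::median(t)),
      lower = 0, upper = 1e3,
      fn = function(p) {
        base <- exp(-p[1] * t)
        s <- sum(base * y) / sum(base^2)
        y - s * base
      },
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500))
    data.frame(conditionId = cr@conditionId, tauTl = tl,
               keff = unname(fit$par[1]))
  }))
  lf <- lm(I(keff * tauTl) ~ tauTl, data = per)
  co <- summary(lf)$coefficients
  list(perCondition = per,
       koff = unname(co["tauTl", "Estimate"]),
       koffSE = unname(co["tauTl", "Std. Error"]),
       kbTauInt = unname(co["(Intercept)", "Estimate"]),
       kbTauIntSE = unname(co["(Intercept)", "Std. Error"]))
}
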
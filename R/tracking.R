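#' Link per-frame foci into binding events
#'
#' Foci detected within `radiusPx` of each other in strictly consecutive
#' frames are considered the same binding event. Between each pair of
#' consecutive frames, candidate continuations are matched greedily in order
#' of ascending distance, each focus used at most once and only within the
#' gate; unmatched foci in the later frame start new events and unmatched
#' events terminate. There is no gap closing: a missed frame splits an
#' event.
#'
#' @param foci Focus table (detection schema), one condition, sorted or
#'   sortable by frame.
#' @param radiusPx Linking gate, pixels (default 3).
#' @return Binding-event data.frame: `condition_id`, `start_frame`,
#'   `end_frame`, `n_frames`, `x_px`, `y_px` (mean position over the
#'   event's foci).
#' @export
linkFoci <- function(foci, radiusPx = 3) {
  checkSchema(foci, c("condition_id", "frame", "x_px", "y_px"), "focus")
  checkScalar(radiusPx, "radiusPx", 0)
  if (length(unique(foci$condition_id)) > 1L)
    stop("linkFoci() expects foci from a single condition")
  if (!nrow(foci))
    return(data.frame(condition_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames = integer(0),
                      x_px = numeric(0), y_px = numeric(0)))
  foci <- foci[order(foci$frame), , drop = FALSE]
  # event state: start frame, last frame, last position, running position sum
  start <- integer(0); last <- integer(0)
  lx <- numeric(0); ly <- numeric(0)
  sx <- numeric(0); sy <- numeric(0); cnt <- integer(0)
  byFrame <- split(foci[c("x_px", "y_px")], foci$frame)
  for (fr in as.integer(names(byFrame))) {
    cur <- byFrame[[as.character(fr)]]
    m <- nrow(cur)
    open <- which(last == fr - 1L)
    assignEvent <- rep(NA_integer_, m)
    if (length(open) && m) {
      d <- outer(lx[open], cur$x_px, "-")^2 + outer(ly[open], cur$y_px, "-")^2
      ord <- order(d)
      usedEv <- rep(FALSE, length(open)); usedFo <- rep(FALSE, m)
      gate2 <- radiusPx^2
      for (k in ord) {
        if (d[k] > gate2) break
        i <- (k - 1L) %% length(open) + 1L
        j <- (k - 1L) %/% length(open) + 1L
        if (usedEv[i] || usedFo[j]) next
        usedEv[i] <- TRUE; usedFo[j] <- TRUE
        assignEvent[j] <- open[i]
      }
    }
    for (j in seq_len(m)) {
      e <- assignEvent[j]
      if (is.na(e)) {                       # new event
        start <- c(start, fr); last <- c(last, fr)
        lx <- c(lx, cur$x_px[j]); ly <- c(ly, cur$y_px[j])
        sx <- c(sx, cur$x_px[j]); sy <- c(sy, cur$y_px[j])
        cnt <- c(cnt, 1L)
      } else {                              # continuation
        last[e] <- fr
        lx[e] <- cur$x_px[j]; ly[e] <- cur$y_px[j]
        sx[e] <- sx[e] + cur$x_px[j]; sy[e] <- sy[e] + cur$y_px[j]
        cnt[e] <- cnt[e] + 1L
      }
    }
  }
  out <- data.frame(condition_id = foci$condition_id[1],
                    start_frame = start, end_frame = last,
                    n_frames = last - start + 1L,
                    x_px = sx / cnt, y_px = sy / cnt)
  out <- out[order(out$start_frame, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert binding events to apparent dwell times
#'
#' The apparent dwell of an event is its frame count times the frame period
#' of its condition, \eqn{n \times \tau_{tl}}. Events spanning fewer than
#' `minFrames` frames are removed; events whose last frame is the final
#' frame of the stack are flagged censored (their true dwell exceeds the
#' observation window) and retained unless `dropCensored` is set.
#'
#' @param events Binding-event table ([linkFoci()] schema), one condition.
#' @param protocol An [AcquisitionProtocol-class].
#' @param conditionIndex Condition the events belong to; must match the
#'   table's `condition_id`.
#' @param minFrames Minimum event length in frames (default 1).
#' @param dropCensored Drop censored events instead of flagging (default
#'   FALSE).
#' @param lastFrame 0-based index of the final analysable frame, used for
#'   the censoring flag. Defaults to the last phase-II frame of the full
#'   stack (`nBleachFrames + nFrames - 1`); pass `nFrames - 1` for events
#'   whose frames are phase-II-relative.
#' @return Dwell data.frame: `condition_id`, `start_frame`, `end_frame`,
#'   `n_frames`, `x_px`, `y_px`, `dwell_s`, `censored`.
#' @export
extractDwells <- function(events, protocol, conditionIndex, minFrames = 1L,
                          dropCensored = FALSE, lastFrame = NULL) {
  conditionIndex <- checkConditionIndex(protocol, conditionIndex)
  checkSchema(events, c("condition_id", "start_frame", "end_frame",
                        "n_frames"), "event")
  if (nrow(events) && any(events$condition_id != conditionIndex))
    stop("condition mismatch between events and the stated condition")
  if (is.null(lastFrame))
    lastFrame <- protocol@nBleachFrames + protocol@nFrames - 1L
  tl <- tauTl(protocol, conditionIndex)
  events$dwell_s <- events$n_frames * tl
  events$censored <- events$end_frame == lastFrame
  events <- events[events$n_frames >= minFrames, , drop = FALSE]
  if (dropCensored)
    events <- events[!events$censored, , drop = FALSE]
  rownames(events) <- NULL
  events
}
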
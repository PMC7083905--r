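# Shared fixture builders. All randomness is seeded by the callers.

fullProtocol <- function(...) acquisitionProtocol(...)

smallProtocol <- function(nFrames = 40L, field = c(64L, 64L),
                          tauD = c(0, 0.2, 0.9, 1.9, 4.9),
                          nBleachFrames = 5L)
  acquisitionProtocol(tauD = tauD, nFrames = nFrames,
                      nBleachFrames = nBleachFrames, fieldShape = field)

# Simulate a dwell table (condition_id, n_frames, dwell_s, censored) for
# every condition of a protocol from a known model.
simulateDwellTable <- function(model, protocol, nPerCondition, seed) {
  do.call(rbind, lapply(seq_along(tauD(protocol)), function(ci) {
    dur <- sampleDwellTimes(model, nPerCondition, seed = seed * 100 + ci)
    ev <- simulateObservedFrames(dur, model, protocol, ci,
                                 seed = seed * 100 + 50 + ci)
    data.frame(condition_id = ci, n_frames = ev$observed_n_frames,
               dwell_s = ev$observed_n_frames * tauTl(protocol, ci),
               censored = ev$censored)
  }))
}

dwellTableToCrtds <- function(dwells, protocol) {
  lapply(sort(unique(dwells$condition_id)), function(ci)
    computeCrtd(dwells[dwells$condition_id == ci, , drop = FALSE],
                protocol, ci))
}

# Noise-free CRTDs generated directly from the decay model (counts are the
# model curve scaled to `total` events).
exactCrtds <- function(protocol, kb, koff, amplitudes = 1, total = 1000,
                       mMax = 100) {
  lapply(seq_along(tauD(protocol)), function(ci) {
    tl <- tauTl(protocol, ci)
    t <- seq_len(mMax) * tl
    y <- total * crtdModel(t, tauInt(protocol), tl, kb, koff, amplitudes)
    new("CRTD", conditionId = as.integer(ci), tauInt = tauInt(protocol),
        tauD = tauD(protocol)[ci], time = t, counts = y,
        totalEvents = as.integer(total))
  })
}

# Add an integrated-intensity Gaussian spot at 0-based (x, y); written out
# directly so detection tests do not depend on the renderer.
addSpotForTest <- function(img, x, y, amp, sigma) {
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    d2 <- (r - 1 - y)^2 + (c - 1 - x)^2
    if (d2 < (5 * sigma)^2)
      img[r, c] <- img[r, c] + amp / (2 * pi * sigma^2) *
        exp(-d2 / (2 * sigma^2))
  }
  img
}

# Ground-truth events on a coarse grid (guaranteed > 2 * linking gate
# apart) so detection and linking can be scored unambiguously.
gridEvents <- function(protocol, conditionIndex, nFrames, spacing = 8,
                       margin = 6, seed = 1) {
  h <- protocol@fieldShape[1]; w <- protocol@fieldShape[2]
  gx <- seq(margin, w - 1 - margin, by = spacing)
  gy <- seq(margin, h - 1 - margin, by = spacing)
  grid <- expand.grid(x_px = gx, y_px = gy)
  withr::with_seed(seed, {
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    n <- nrow(grid)
    data.frame(
      molecule_id = seq_len(n), condition_index = conditionIndex,
      observed_first_frame = sample(0:(protocol@nFrames - nFrames), n,
                                    replace = TRUE),
      observed_n_frames = nFrames,
      x_px = grid$x_px + runif(n, -0.3, 0.3),
      y_px = grid$y_px + runif(n, -0.3, 0.3),
      censored = FALSE)
  })
}

# Turn ground-truth events into the per-frame (frame, x, y) occurrences
# they should produce; frames absolute (phase II offset applied).
truthOccurrences <- function(events, protocol) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    n <- events$observed_n_frames[i]
    if (n < 1) return(NULL)
    data.frame(frame = protocol@nBleachFrames +
                 events$observed_first_frame[i] + seq_len(n) - 1L,
               x_px = events$x_px[i], y_px = events$y_px[i])
  }))
}

# Recall/precision of detected foci against ground-truth occurrences,
# matched per frame within `tol` pixels (greedy by distance).
scoreDetection <- function(foci, truth, tol = 1) {
  tp <- 0L
  for (fr in unique(truth$frame)) {
    tr <- truth[truth$frame == fr, , drop = FALSE]
    de <- foci[foci$frame == fr, , drop = FALSE]
    if (!nrow(de)) next
    d <- outer(tr$x_px, de$x_px, "-")^2 + outer(tr$y_px, de$y_px, "-")^2
    ord <- order(d)
    usedT <- rep(FALSE, nrow(tr)); usedD <- rep(FALSE, nrow(de))
    for (k in ord) {
      if (d[k] > tol^2) break
      i <- (k - 1L) %% nrow(tr) + 1L; j <- (k - 1L) %/% nrow(tr) + 1L
      if (usedT[i] || usedD[j]) next
      usedT[i] <- TRUE; usedD[j] <- TRUE; tp <- tp + 1L
    }
  }
  c(recall = tp / nrow(truth), precision = tp / nrow(foci))
}

# Focus table a perfect detector would produce from ground-truth events.
perfectFoci <- function(events, protocol, conditionIndex) {
  occ <- truthOccurrences(events, protocol)
  data.frame(condition_id = conditionIndex, frame = occ$frame,
             x_px = occ$x_px, y_px = occ$y_px,
             peak_filtered = 1, background_sd = 0.1)
}
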
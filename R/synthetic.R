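#' Sample ground-truth bound durations from a kinetic model
#'
#' Draws true DNA-bound durations from the amplitude-weighted exponential
#' mixture of a [KineticModel-class]. A component with `koff = 0` yields
#' infinite durations (a permanently arrested species).
#'
#' @param model A [KineticModel-class].
#' @param n Number of durations to draw (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param returnComponents If TRUE, return a data.frame with the sampled
#'   component label alongside each duration.
#' @return Numeric vector of durations in seconds, or a data.frame with
#'   columns `duration` and `component`.
#' @examples
#' m <- kineticModel(lifetimes = 2)
#' mean(sampleDwellTimes(m, 1e4, seed = 1))  # ~2 s
#' @export
sampleDwellTimes <- function(model, n, seed = NULL,
                             returnComponents = FALSE) {
  validObject(model)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a single integer >= 1")
  n <- as.integer(n)
  withSeed(seed, {
    k <- length(model@amplitudes)
    comp <- if (k == 1L) rep(1L, n) else
      sample.int(k, n, replace = TRUE, prob = model@amplitudes)
    rate <- model@koff[comp]
    dur <- rep(Inf, n)
    pos <- rate > 0
    dur[pos] <- rexp(sum(pos), rate[pos])
    if (returnComponents) data.frame(duration = dur, component = comp)
    else dur
  })
}

#' Convert true bound durations into observed frame counts
#'
#' Applies the interval-imaging observation model for one dark-interval
#' condition: a molecule is counted in a frame only if it stays bound for
#' the full frame period \eqn{\tau_{tl}} and its fluorophore survives the
#' frame's illuminated exposure \eqn{\tau_{int}}. Photobleaching consumes an
#' exponential budget of illuminated time (rate `kb`), so the observed frame
#' count of a single-component molecule is geometric with per-frame survival
#' \eqn{p = e^{-k_{off}\tau_{tl}} e^{-k_b \tau_{int}}}. Partial frames at
#' either end are ignored (whole-frame counting), so molecules observed for
#' zero full frames are dropped by default. Events still visible in the last
#' phase-II frame are truncated there and flagged censored.
#'
#' @param durations True bound durations in seconds (may be `Inf`).
#' @param kb Photobleaching rate per illuminated second, or a
#'   [KineticModel-class] whose `kb` is used.
#' @param protocol An [AcquisitionProtocol-class].
#' @param conditionIndex Which dark-interval condition (1-based index into
#'   `tauD(protocol)`).
#' @param seed Optional integer seed.
#' @param startTimes Binding start times in seconds from the start of the
#'   single-molecule phase; a scalar is recycled (default 0).
#' @param dropZero Drop events observed for zero frames (default TRUE).
#' @return A data.frame of ground-truth events with columns `molecule_id`,
#'   `condition_index`, `binding_start`, `true_bound_duration`,
#'   `bleach_exposure_budget`, `observed_first_frame` (0-based, phase II),
#'   `observed_n_frames` and `censored`.
#' @examples
#' p <- acquisitionProtocol()
#' m <- kineticModel(lifetimes = 29, kb = 1)
#' d <- sampleDwellTimes(m, 1000, seed = 1)
#' ev <- simulateObservedFrames(d, m, p, conditionIndex = 6, seed = 2)
#' mean(ev$observed_n_frames)
#' @export
simulateObservedFrames <- function(durations, kb, protocol, conditionIndex,
                                   seed = NULL, startTimes = 0,
                                   dropZero = TRUE) {
  if (is(kb, "KineticModel")) kb <- kb@kb
  checkScalar(kb, "kb", 0)
  if (any(durations < 0, na.rm = TRUE) || any(is.na(durations)))
    stop("'durations' must all be >= 0")
  conditionIndex <- checkConditionIndex(protocol, conditionIndex)
  tl <- tauTl(protocol, conditionIndex)
  n <- length(durations)
  startTimes <- rep_len(startTimes, n)
  withSeed(seed, {
    budget <- if (kb > 0) rexp(n, kb) else rep(Inf, n)
    nBind <- floor(durations / tl)
    nBleach <- floor(budget / protocol@tauInt)
    firstFrame <- ceiling(startTimes / tl)
    avail <- pmax(protocol@nFrames - firstFrame, 0)
    intrinsic <- pmin(nBind, nBleach)
    nObs <- pmin(intrinsic, avail)
    out <- data.frame(
      molecule_id = seq_len(n),
      condition_index = conditionIndex,
      binding_start = startTimes,
      true_bound_duration = durations,
      bleach_exposure_budget = budget,
      observed_first_frame = as.integer(firstFrame),
      observed_n_frames = as.integer(nObs),
      censored = intrinsic > avail & nObs > 0)
    if (dropZero) out <- out[out$observed_n_frames > 0L, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Assign random in-field positions to simulated events
#'
#' Bound molecules appear as static foci, so each event gets one (x, y)
#' position, uniform over the field with a safety margin from the borders.
#' Coordinates are 0-based with the origin at the centre of the top-left
#' pixel.
#'
#' @param events Event data.frame as from [simulateObservedFrames()].
#' @param protocol An [AcquisitionProtocol-class] (provides the field shape).
#' @param margin Margin from the field edges, pixels.
#' @param seed Optional integer seed.
#' @return `events` with columns `x_px`, `y_px` added.
#' @export
placeEvents <- function(events, protocol, margin = 5, seed = NULL) {
  h <- protocol@fieldShape[1]; w <- protocol@fieldShape[2]
  if (2 * margin >= min(h, w) - 1)
    stop("margin too large for the field")
  withSeed(seed, {
    events$x_px <- runif(nrow(events), margin, w - 1 - margin)
    events$y_px <- runif(nrow(events), margin, h - 1 - margin)
    events
  })
}

# Add one symmetric 2-d Gaussian spot (integrated intensity `amp`) to `mat`
# at 0-based centre (x, y); evaluated at pixel centres over a +/-4 sigma
# window.
addGaussianSpot <- function(mat, x, y, amp, sigma) {
  w <- ceiling(4 * sigma)
  rows <- max(1L, floor(y + 1 - w)):min(nrow(mat), ceiling(y + 1 + w))
  cols <- max(1L, floor(x + 1 - w)):min(ncol(mat), ceiling(x + 1 + w))
  spot <- amp / (2 * pi * sigma^2) *
    exp(-outer((rows - 1 - y)^2, (cols - 1 - x)^2, "+") / (2 * sigma^2))
  mat[rows, cols] <- mat[rows, cols] + spot
  mat
}

#' Render a synthetic movie stack for one interval condition
#'
#' Turns placed ground-truth events into a two-phase fluorescence movie:
#' each bound, unbleached molecule contributes a static diffraction-limited
#' Gaussian spot in every frame of its observed span, on a uniform cytosolic
#' background. Photon shot noise is Poisson; the camera adds a constant
#' offset and Gaussian read noise. Phase-I frames carry a decaying pool of
#' extra emitters that mimics the bleach-down of the initial fluorophore
#' population (cosmetic only; phase I is excluded from analysis).
#'
#' @param events Data.frame with `observed_first_frame`,
#'   `observed_n_frames`, `x_px`, `y_px` (see [placeEvents()]).
#' @param protocol An [AcquisitionProtocol-class].
#' @param conditionIndex Condition the movie represents.
#' @param psfSigmaPx PSF standard deviation, pixels (> 0).
#' @param spotAmplitude Integrated spot intensity, photons per frame (> 0).
#' @param background Uniform background, photons per pixel per frame.
#' @param cameraOffset Constant camera offset, counts.
#' @param readNoiseSd Gaussian read noise SD, counts.
#' @param bleachPoolSize Number of phase-I pool emitters.
#' @param poolBleachRate Bleach rate of the phase-I pool, per illuminated
#'   second.
#' @param seed Optional integer seed.
#' @return A [MovieStack-class].
#' @export
renderMovie <- function(events, protocol, conditionIndex,
                        psfSigmaPx = 1.2, spotAmplitude = 600,
                        background = 20, cameraOffset = 100,
                        readNoiseSd = 2, bleachPoolSize = 30,
                        poolBleachRate = 2, seed = NULL) {
  checkScalar(psfSigmaPx, "psfSigmaPx", 0, strict = TRUE)
  checkScalar(spotAmplitude, "spotAmplitude", 0, strict = TRUE)
  checkScalar(background, "background", 0)
  conditionIndex <- checkConditionIndex(protocol, conditionIndex)
  h <- protocol@fieldShape[1]; w <- protocol@fieldShape[2]
  nB <- protocol@nBleachFrames; nF <- protocol@nFrames
  if (nrow(events)) {
    if (!all(c("x_px", "y_px") %in% names(events)))
      stop("events need x_px/y_px positions; see placeEvents()")
    if (any(events$x_px < 0 | events$x_px > w - 1 |
            events$y_px < 0 | events$y_px > h - 1))
      stop("event positions must lie within the field")
  }
  withSeed(seed, {
    expected <- array(background, dim = c(h, w, nB + nF))
    if (nB > 0 && bleachPoolSize > 0) {
      px <- runif(bleachPoolSize, 2, w - 3)
      py <- runif(bleachPoolSize, 2, h - 3)
      life <- floor(rexp(bleachPoolSize, poolBleachRate) /
                    protocol@tauInt) + 1
      for (i in seq_len(bleachPoolSize)) {
        for (f in seq_len(min(life[i], nB)))
          expected[, , f] <- addGaussianSpot(expected[, , f], px[i], py[i],
                                             spotAmplitude, psfSigmaPx)
      }
    }
    for (i in seq_len(nrow(events))) {
      n <- events$observed_n_frames[i]
      if (n < 1L) next
      f0 <- events$observed_first_frame[i]
      for (f in (nB + f0 + 1L):(nB + f0 + n))
        expected[, , f] <- addGaussianSpot(expected[, , f], events$x_px[i],
                                           events$y_px[i], spotAmplitude,
                                           psfSigmaPx)
    }
    counts <- array(rpois(length(expected), expected), dim = dim(expected))
    counts <- counts + cameraOffset +
      array(rnorm(length(expected), 0, readNoiseSd), dim = dim(expected))
    counts[counts < 0] <- 0
    new("MovieStack", frames = counts, protocol = protocol,
        conditionIndex = conditionIndex,
        noiseParams = list(psfSigmaPx = psfSigmaPx,
                           spotAmplitude = spotAmplitude,
                           background = background,
                           cameraOffset = cameraOffset,
                           readNoiseSd = readNoiseSd))
  })
}

#' Generate a complete on-disk fixture dataset
#'
#' Simulates every dark-interval condition of a protocol from a known
#' [KineticModel-class] and writes, per condition, either a rendered TIFF
#' movie with its YAML metadata sidecar or a dwell-time CSV, plus one
#' ground-truth event table covering all conditions. Every downstream stage
#' (detection, tracking, CRTDs, fitting) can be scored against the returned
#' ground truth. Per-condition seeds are derived as `seed + conditionIndex`
#' so individual conditions are reproducible in isolation.
#'
#' @param dir Output directory (created if needed).
#' @param model Ground-truth [KineticModel-class].
#' @param protocol An [AcquisitionProtocol-class].
#' @param nPerCondition Molecules simulated per condition.
#' @param mode `"movies"` renders TIFF stacks; `"dwells"` writes dwell CSVs
#'   only (no images).
#' @param startMode `"uniform"` staggers binding starts over phase II;
#'   `"zero"` starts every molecule at the first frame.
#' @param noise Named list overriding [renderMovie()] noise parameters.
#' @param seed Base integer seed.
#' @return Invisibly, a manifest list with the ground-truth table and the
#'   per-condition file paths.
#' @export
makeFixtureDataset <- function(dir, model, protocol, nPerCondition,
                               mode = c("movies", "dwells"),
                               startMode = c("uniform", "zero"),
                               noise = list(), seed = 1) {
  mode <- match.arg(mode)
  startMode <- match.arg(startMode)
  validObject(model); validObject(protocol)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  truth <- list()
  for (ci in seq_along(protocol@tauD)) {
    condSeed <- as.integer(seed) + ci
    durations <- sampleDwellTimes(model, nPerCondition, seed = condSeed)
    starts <- if (startMode == "uniform")
      withSeed(condSeed + 10000L,
               runif(nPerCondition, 0,
                     (protocol@nFrames - 1) * tauTl(protocol, ci)))
    else 0
    ev <- simulateObservedFrames(durations, model@kb, protocol, ci,
                                 seed = condSeed + 20000L,
                                 startTimes = starts)
    if (mode == "movies") {
      ev <- placeEvents(ev, protocol, seed = condSeed + 30000L)
      args <- c(list(events = ev, protocol = protocol, conditionIndex = ci,
                     seed = condSeed + 40000L), noise)
      movie <- do.call(renderMovie, args)
      path <- file.path(dir, sprintf("condition_%02d.tif", ci))
      writeMovie(movie, path)
      paths <- c(paths, path)
    } else {
      dw <- data.frame(condition_id = ci,
                       n_frames = ev$observed_n_frames,
                       dwell_s = ev$observed_n_frames * tauTl(protocol, ci),
                       censored = ev$censored)
      path <- file.path(dir, sprintf("dwells_%02d.csv", ci))
      write.csv(dw, path, row.names = FALSE)
      paths <- c(paths, path)
    }
    truth[[ci]] <- ev
  }
  truth <- do.call(rbind, truth)
  truthPath <- file.path(dir, "ground_truth.csv")
  write.csv(truth, truthPath, row.names = FALSE)
  invisible(list(groundTruth = truth, groundTruthPath = truthPath,
                 conditionPaths = paths, mode = mode, seed = seed))
}
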
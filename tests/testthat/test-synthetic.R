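# Ground-truth generator: exponential-mixture dwell sampling and the
# whole-frame interval-imaging observation model.

test_that("kinetic model and protocol validity constraints are enforced", {
  expect_error(kineticModel(koff = c(0.5, 0.1), amplitudes = c(0.6, 0.6)),
               "sum to 1")
  expect_error(kineticModel(koff = c(0.5, 0.1, 0.01),
                            amplitudes = c(0.3, 0.3, 0.4)),
               "1 or 2")
  expect_error(kineticModel(koff = 0.5, amplitudes = -1), "positive")
  expect_error(acquisitionProtocol(tauInt = 0), "positive")
  expect_error(acquisitionProtocol(tauD = -0.1), ">= 0")
  expect_error(acquisitionProtocol(nFrames = 1), ">= 2")
  m <- kineticModel(lifetimes = c(26, 1.1), amplitudes = c(0.32, 0.68))
  expect_equal(lifetimes(m), c(26, 1.1))
  expect_equal(sum(amplitudes(m)), 1)
  p <- acquisitionProtocol()
  expect_equal(tauTl(p), tauInt(p) + tauD(p))
  expect_equal(length(tauD(p)), 11L)
})

test_that("dwell sampling matches the mixture's closed-form moments", {
  n <- 1e5
  m1 <- kineticModel(koff = 0.5)
  d <- sampleDwellTimes(m1, n, seed = 11)
  se <- 2 / sqrt(n)                      # SD of Exp(0.5) is 2
  expect_lt(abs(mean(d) - 2), 3 * se)

  # two-population parameterization: fast 1.1 s (68%), slow 26 s (32%)
  m2 <- kineticModel(lifetimes = c(1.1, 26), amplitudes = c(0.68, 0.32))
  d2 <- sampleDwellTimes(m2, n, seed = 12)
  p5 <- 0.68 * (1 - exp(-5 / 1.1)) + 0.32 * (1 - exp(-5 / 26))
  phat <- mean(d2 < 5)
  expect_lt(abs(phat - p5), 3 * sqrt(p5 * (1 - p5) / n))
})

test_that("dwell sampling is reproducible and conserves amplitudes", {
  m <- kineticModel(lifetimes = c(30, 1), amplitudes = c(0.4, 0.6))
  expect_identical(sampleDwellTimes(m, 1000, seed = 7),
                   sampleDwellTimes(m, 1000, seed = 7))
  n <- 1e5
  comp <- sampleDwellTimes(m, n, seed = 8, returnComponents = TRUE)$component
  phat <- mean(comp == 1L)
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_error(sampleDwellTimes(m, 0), ">= 1")
})

test_that("pure-bleaching frame counts are geometric and condition-invariant", {
  p <- fullProtocol()
  n <- 1e5
  kb <- 3
  dur <- rep(Inf, n)                     # koff = 0: never dissociates
  counts <- lapply(c(1L, 5L, 11L), function(ci)
    simulateObservedFrames(dur, kb, p, ci, seed = 21)$observed_n_frames)
  # bleaching only consumes illuminated time, so the distribution must be
  # identical whatever the dark interval; same seed makes it exactly so
  expect_identical(counts[[1]], counts[[2]])
  expect_identical(counts[[1]], counts[[3]])
  # and geometric with per-exposure survival exp(-kb * tauInt)
  surv <- exp(-kb * tauInt(p))
  phat <- geometricSurvivalMLE(counts[[1]])
  se <- sqrt(surv * (1 - surv)^2 / length(counts[[1]]))
  expect_lt(abs(phat - surv), 3 * se)
})

test_that("interval imaging extends observed time as the geometric mean predicts", {
  # kb = 2 /s, tauInt = 0.1 s, tauD = 9.9 s, koff = 0:
  # mean observed real time = tauTl / (1 - exp(-0.2)) ~ 55 s
  p <- fullProtocol()
  ci <- which(tauD(p) == 9.9)
  n <- 1e5
  ev <- simulateObservedFrames(rep(Inf, n), 2, p, ci, seed = 31)
  tl <- tauTl(p, ci)
  pSurv <- exp(-2 * tauInt(p))
  expected <- tl / (1 - pSurv)
  seMean <- tl * sqrt(pSurv) / ((1 - pSurv) * sqrt(n))
  expect_lt(abs(mean(ev$observed_n_frames) * tl - expected), 3 * seMean)
})

test_that("without bleaching, continuous imaging recovers the bound lifetime", {
  p <- fullProtocol()
  m <- kineticModel(koff = 0.5)
  dur <- sampleDwellTimes(m, 1e5, seed = 41)
  ev <- simulateObservedFrames(dur, 0, p, 1L, seed = 42)   # tauD = 0
  # whole-frame counting biases by less than one frame period
  expect_lt(abs(mean(ev$observed_n_frames) * tauTl(p, 1) - 2),
            tauTl(p, 1) + 3 * 2 / sqrt(1e5))
})

test_that("per-frame survival matches exp(-(kb tauInt + koff tauTl)) across conditions", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 29, kb = 1)
  n <- 1e5
  for (ci in c(2L, 6L, 9L)) {
    ev <- simulateObservedFrames(sampleDwellTimes(m, n, seed = 50 + ci),
                                 m, p, ci, seed = 60 + ci)
    keep <- !ev$censored
    surv <- exp(-(1 * tauInt(p) + tauTl(p, ci) / 29))
    phat <- geometricSurvivalMLE(ev$observed_n_frames[keep])
    se <- sqrt(surv * (1 - surv)^2 / sum(keep))
    expect_lt(abs(phat - surv), 3 * se)
  }
})

test_that("zero-frame events are dropped and censoring is bookkept", {
  p <- smallProtocol(nFrames = 20L)
  m <- kineticModel(lifetimes = 50, kb = 0.2)
  dur <- sampleDwellTimes(m, 5000, seed = 71)
  all <- simulateObservedFrames(dur, m, p, 5L, seed = 72, dropZero = FALSE)
  kept <- simulateObservedFrames(dur, m, p, 5L, seed = 72)
  expect_equal(nrow(kept), nrow(all) - sum(all$observed_n_frames == 0L))
  expect_true(all(kept$observed_n_frames >= 1L))
  # censored events end exactly at the last frame and are flagged
  cen <- kept[kept$censored, ]
  expect_gt(nrow(cen), 0)
  expect_true(all(cen$observed_first_frame + cen$observed_n_frames ==
                  frames(p)))
  # whole-frame invariant: observed span never exceeds truth by a frame
  expect_true(all(kept$observed_n_frames * tauTl(p, 5L) <=
                  kept$true_bound_duration + tauTl(p, 5L)))
  expect_error(simulateObservedFrames(dur, m, p, 99L), "unknown condition")
  expect_error(simulateObservedFrames(c(-1, 2), 0.5, p, 1L), ">= 0")
})

test_that("rendered movies have the stated background and spot photometry", {
  p <- smallProtocol(nFrames = 6L, nBleachFrames = 2L, tauD = 0.5,
                     field = c(48L, 48L))
  empty <- renderMovie(data.frame(), p, 1L, background = 30,
                       cameraOffset = 100, readNoiseSd = 2,
                       bleachPoolSize = 0, seed = 81)
  px <- frames(empty)
  expect_equal(dim(px), c(48, 48, 8))
  expect_lt(abs(mean(px) - 130), 3 * sqrt(30 + 4) / sqrt(length(px)) + 0.1)
  expect_lt(abs(var(as.numeric(px)) - 34), 0.15 * 34)

  # one immobile molecule: integrated 7x7 intensity ~ amplitude
  ev <- data.frame(observed_first_frame = 0L, observed_n_frames = 6L,
                   x_px = 24, y_px = 24)
  one <- renderMovie(ev, p, 1L, spotAmplitude = 5000, psfSigmaPx = 1.0,
                     background = 30, cameraOffset = 100, readNoiseSd = 2,
                     bleachPoolSize = 0, seed = 82)
  win <- frames(one)[22:28, 22:28, 3:8]          # centred 7x7, phase II
  perFrame <- apply(win, 3, sum) - 49 * 130
  expect_lt(abs(mean(perFrame) - 5000), 4 * sd(perFrame) / sqrt(6) + 100)
  expect_error(renderMovie(ev, p, 1L, psfSigmaPx = 0), "psfSigmaPx")
  expect_error(renderMovie(ev, p, 1L, spotAmplitude = -5), "spotAmplitude")
})

test_that("fixture datasets cover every condition with scoreable ground truth", {
  p <- smallProtocol(nFrames = 15L, tauD = c(0, 0.4, 0.9), field = c(32L, 32L),
                     nBleachFrames = 2L)
  m <- kineticModel(lifetimes = 3, kb = 0.5)
  dir <- withr::local_tempdir()
  fix <- makeFixtureDataset(dir, m, p, nPerCondition = 50,
                            mode = "dwells", seed = 3)
  expect_length(fix$conditionPaths, 3)
  expect_true(all(file.exists(fix$conditionPaths)))
  expect_false(any(grepl("\\.tif$", list.files(dir))))
  truth <- read.csv(fix$groundTruthPath)
  expect_setequal(unique(truth$condition_index), 1:3)
  dw <- read.csv(fix$conditionPaths[2])
  expect_equal(nrow(dw), sum(truth$condition_index == 2))
  expect_equal(dw$dwell_s, dw$n_frames * tauTl(p, 2))

  dir2 <- withr::local_tempdir()
  fix2 <- makeFixtureDataset(dir2, m, p, nPerCondition = 10,
                             mode = "movies", seed = 3)
  movie <- readMovie(fix2$conditionPaths[1])
  expect_equal(dim(frames(movie))[3],
               p@nBleachFrames + frames(p))
  expect_equal(conditionIndex(movie), 1L)
})
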
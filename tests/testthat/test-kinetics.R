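# CRTDs, the decay model, the global fit, bootstrap and model selection.

test_that("CRTD counting is exact", {
  p <- fullProtocol()
  ci <- which(tauD(p) == 0.9)
  d <- data.frame(condition_id = ci, n_frames = c(1L, 2L, 3L))
  cr <- computeCrtd(d, p, ci)
  expect_equal(crtdCounts(cr), c(3, 2, 1))
  expect_equal(timeGrid(cr), c(1, 2, 3))
  expect_equal(totalEvents(cr), 3L)
  # all dwells equal: a step function
  step <- computeCrtd(data.frame(condition_id = ci, n_frames = rep(4L, 7)),
                      p, ci)
  expect_equal(crtdCounts(step), c(7, 7, 7, 7))
  expect_error(computeCrtd(d[0, ], p, ci), "empty")
})

test_that("simulated CRTDs follow the closed-form survival oracle", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 10, kb = 1)
  n <- 1e5
  ci <- 5L
  ev <- simulateObservedFrames(sampleDwellTimes(m, n, seed = 301), m, p,
                               ci, seed = 302)
  cr <- computeCrtd(data.frame(condition_id = ci,
                               n_frames = ev$observed_n_frames), p, ci)
  y <- crtdCounts(cr) / crtdCounts(cr)[1]
  mGrid <- seq_along(y) - 1          # kept events: survival p^(m-1)
  expected <- oracleSurvival(mGrid, tauInt(p), tauTl(p, ci), 1, 0.1) /
    oracleSurvival(0, tauInt(p), tauTl(p, ci), 1, 0.1)
  nn <- crtdCounts(cr)[1]
  tol <- 3 * sqrt(expected * (1 - expected) / nn) + 1e-9
  expect_true(all(abs(y - expected)[1:20] <= tol[1:20]))
})

test_that("the decay model combines bleaching and dissociation correctly", {
  # no bleaching: pure exponential in every condition
  expect_equal(crtdModel(c(1, 5, 20), 0.1, 7.9 + 0.1, 0, 0.05),
               exp(-0.05 * c(1, 5, 20)))
  # continuous imaging: rates add
  expect_equal(crtdModel(2, 0.1, 0.1, 1.5, 0.3), exp(-(1.5 + 0.3) * 2))
  # duty-cycle arithmetic: kb=2, tauInt=0.1, tauTl=10, koff=0.0072
  keff <- 2 * 0.1 / 10 + 0.0072
  expect_equal(keff, 0.0272)
  expect_equal(crtdModel(1, 0.1, 10, 2, 0.0072), exp(-0.0272))
  expect_equal(apparentLifetime(2, 0.1, 10, 0.0072), 1 / 0.0272)
  expect_equal(apparentLifetime(0, 0.1, 10, 0.25), 4)
  expect_equal(apparentLifetime(2, 0.1, 0.1, 0), 0.5)
  expect_error(apparentLifetime(0, 0.1, 1, 0), "cannot both be zero")
  expect_error(crtdModel(1, 0.2, 0.1, 1, 1), "tauTl")
})

test_that("global fit recovers exact parameters from noise-free CRTDs", {
  p <- fullProtocol()
  crt1 <- exactCrtds(p, kb = 1.2, koff = 1 / 139)
  f1 <- globalFit(crt1, 1)
  expect_true(converged(f1))
  expect_lt(abs(bleachRate(f1) - 1.2) / 1.2, 1e-6)
  expect_lt(abs(lifetimes(f1) - 139) / 139, 1e-6)
  # normalized data are S(t)/S(t1), so the profiled scale is 1/S(t1) >= 1
  expect_true(all(conditionScales(f1) >= 1))
  expect_lt(max(abs(conditionScales(f1) -
                    1 / exp(-(1.2 * tauInt(p) / tauTl(p) + 1 / 139) *
                            tauTl(p)))), 1e-6)

  crt2 <- exactCrtds(p, kb = 0.8, koff = c(1 / 26, 1 / 1.1),
                     amplitudes = c(0.32, 0.68))
  f2 <- globalFit(crt2, 2)
  expect_true(converged(f2))
  expect_lt(max(abs(lifetimes(f2) - c(26, 1.1)) / c(26, 1.1)), 1e-6)
  expect_lt(abs(amplitudes(f2)[1] - 0.32), 1e-6)
  expect_lt(abs(bleachRate(f2) - 0.8) / 0.8, 1e-6)
  expect_equal(sum(amplitudes(f2)), 1)
})

test_that("global fit recovers simulated single-component truth within 10%", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 29, kb = 1)
  dw <- simulateDwellTable(m, p, 1000, seed = 31)
  f <- globalFit(dwellTableToCrtds(dw, p), 1)
  expect_true(converged(f))
  expect_lt(abs(lifetimes(f) - 29) / 29, 0.10)
  expect_lt(abs(bleachRate(f) - 1), 0.15)
})

test_that("fit warns when conditions cannot separate kb from koff", {
  p <- acquisitionProtocol(tauD = c(0, 0.1))
  crt <- exactCrtds(p, kb = 1, koff = 0.1, mMax = 30)
  expect_warning(globalFit(crt, 1), "identifiab")
})

test_that("global least squares agrees with the geometric-survival MLE", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 20, kb = 1)
  dw <- simulateDwellTable(m, p, 1000, seed = 33)     # ~1e4 kept events
  f <- suppressWarnings(globalFit(dwellTableToCrtds(dw, p), 1))
  # per-condition MLE of the effective rate, then the linearization slope
  per <- do.call(rbind, lapply(split(dw, dw$condition_id), function(tab) {
    ci <- tab$condition_id[1]
    tl <- tauTl(p, ci)
    keff <- -log(geometricSurvivalMLE(tab$n_frames)) / tl
    data.frame(tauTl = tl, keff = keff)
  }))
  slope <- coef(lm(I(keff * tauTl) ~ tauTl, per))[2]
  expect_lt(abs(dissociationRates(f) - slope) / slope, 0.05)
})

test_that("linearized per-condition rates reproduce the global fit", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 50, kb = 1)
  dw <- simulateDwellTable(m, p, 2000, seed = 35)
  crtds <- dwellTableToCrtds(dw, p)
  f <- bootstrapFit(dw, p, 1L, seed = 36)
  lin <- linearizedRates(crtds)
  sdBoot <- bootstrapSummary(f)$sd[bootstrapSummary(f)$parameter ==
                                     "koff_slow"]
  combined <- 3 * sqrt(lin$koffSE^2 + sdBoot^2)
  expect_lt(abs(lin$koff - dissociationRates(f)), combined)
  expect_lt(abs(lin$kbTauInt - bleachRate(f) * tauInt(p)),
            4 * lin$kbTauIntSE + 0.02)
  expect_error(linearizedRates(crtds[1:2]), ">= 3")
})

test_that("bootstrap follows the 10-replicate, 80% convention reproducibly", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 15, kb = 1)
  dw <- simulateDwellTable(m, p, 300, seed = 37)
  f <- bootstrapFit(dw, p, 1L, nBoot = 10L, fraction = 0.8, seed = 99)
  s <- bootstrapSamples(f)
  expect_equal(nrow(s), 10L)
  perCond <- table(dw$condition_id)
  expect_true(all(s$n_events == sum(floor(0.8 * perCond))))
  expect_setequal(c("lifetime_slow", "koff_slow", "amplitude_slow", "kb"),
                  bootstrapSummary(f)$parameter)
  expect_true(all(is.finite(bootstrapSummary(f)$sd)))
  # bit-identical under the same seed, different otherwise
  f2 <- bootstrapFit(dw, p, 1L, nBoot = 10L, fraction = 0.8, seed = 99)
  expect_identical(s, bootstrapSamples(f2))
  f3 <- bootstrapFit(dw, p, 1L, nBoot = 10L, fraction = 0.8, seed = 100)
  expect_false(identical(s$lifetime_slow,
                         bootstrapSamples(f3)$lifetime_slow))
})

test_that("bootstrap lifetime SD shrinks roughly as one over sqrt(n)", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 40, kb = 1)
  sdFor <- function(n, seed) {
    dw <- simulateDwellTable(m, p, n, seed = seed)
    bs <- bootstrapSummary(bootstrapFit(dw, p, 1L, seed = seed))
    bs$sd[bs$parameter == "lifetime_slow"]
  }
  sdSmall <- median(vapply(1:3, function(i) sdFor(400, 40 + i), numeric(1)))
  sdBig <- median(vapply(1:3, function(i) sdFor(1600, 50 + i), numeric(1)))
  ratio <- sdSmall / sdBig
  expect_gt(ratio, 1.2)          # ~2 expected for a 4x event increase
  expect_lt(ratio, 3.5)
})

test_that("BIC model selection finds the true component count", {
  p <- fullProtocol()
  one <- 0L; two <- 0L
  for (s in 1:10) {
    m1 <- kineticModel(lifetimes = 20, kb = 1)
    dw1 <- simulateDwellTable(m1, p, 1000, seed = 400 + s)
    cr1 <- dwellTableToCrtds(dw1, p)
    sel1 <- selectModel(globalFit(cr1, 1), globalFit(cr1, 2),
                        dw1, p)
    one <- one + (sel1$chosenOrder == 1L)

    m2 <- kineticModel(lifetimes = c(100, 1), amplitudes = c(0.5, 0.5),
                       kb = 1)
    dw2 <- simulateDwellTable(m2, p, 1000, seed = 500 + s)
    cr2 <- dwellTableToCrtds(dw2, p)
    sel2 <- selectModel(globalFit(cr2, 1), globalFit(cr2, 2),
                        dw2, p)
    two <- two + (sel2$chosenOrder == 2L)
  }
  expect_gte(one, 9L)
  expect_gte(two, 9L)
})

test_that("equal-residual fits fall back to the single-exponential model", {
  p <- fullProtocol()
  crt <- exactCrtds(p, kb = 1, koff = 0.05)
  f1 <- globalFit(crt, 1)
  f2 <- globalFit(crt, 2)        # collapses onto (nearly) equal rates
  sel <- selectModel(f1, f2)
  expect_equal(sel$chosenOrder, 1L)
  expect_named(sel$bic, c("order1", "order2"))
  expect_error(selectModel(f2, f1), "order-1 and an order-2")
})

test_that("scanning distance is the rounded rate-time product", {
  expect_identical(expectedScanningDistance(4, 29), 116L)
  expect_identical(expectedScanningDistance(0, 29), 0L)
  expect_identical(expectedScanningDistance(4, 18), 72L)
  expect_error(expectedScanningDistance(-1, 5), ">= 0")
})

test_that("effective rates decrease toward koff as the frame period grows", {
  p <- fullProtocol()
  m <- kineticModel(lifetimes = 10, kb = 2)
  dw <- simulateDwellTable(m, p, 3000, seed = 61)
  lin <- linearizedRates(dwellTableToCrtds(dw, p))
  per <- lin$perCondition[order(lin$perCondition$tauTl), ]
  expect_true(all(diff(per$keff) < 0))
  # longest frame period: keff within 25% of koff (duty cycle 1%)
  expect_lt(abs(per$keff[nrow(per)] - 0.1) / 0.1, 0.25)
})
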
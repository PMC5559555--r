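# 2D sheet machinery: spectral analysis, lifespan bookkeeping, and
# engine consistency with the 1D cable.

test_that("dominant frequency finds pure and dominant tones", {
  t <- seq(0, 5, by = 1e-3)
  expect_equal(dominantFrequency(sin(2 * pi * 3 * t), fs = 1000), 3,
               tolerance = 0.2)
  mix <- sin(2 * pi * 2 * t) + 3 * sin(2 * pi * 5 * t)
  expect_equal(dominantFrequency(mix, fs = 1000), 5, tolerance = 0.2)
  expect_error(dominantFrequency(rep(1, 5000), fs = 1000), "constant")
  expect_error(dominantFrequency(sin(1:100), fs = 1000), "2 seconds")
})

test_that("re-entry lifespan reads the activation record", {
  rec <- list(lastActivation = matrix(c(100, 2500, 400, 450), 2, 2),
              s2Time = 500)
  expect_identical(reentryLifespan(rec), 2)       # 2500 - 500 ms
  rec2 <- list(lastActivation = matrix(c(100, 200), 1, 2), s2Time = 500)
  expect_identical(reentryLifespan(rec2), 0)      # nothing after S2
  expect_identical(reentryLifespan(list(lastActivation = matrix(1),
                                        s2Time = -1)), 0)
})

test_that("a one-row sheet reproduces strand propagation", {
  m <- genotypeModel("WT")
  g <- sqtsim:::.genoToC(m)
  st <- sqtsim:::conditionedState("EPI", m, 1000, 30)
  n <- 100
  inits <- list(NULL, NULL, st)
  r <- sqtsim:::sheetSimulateCpp(n, 1L, rep(2L, n), inits, g,
                                 sqtsim:::.defaultD, 0.2, 0.02, 60,
                                 s1Width = 5L, stimAmp = -52, stimDur = 2,
                                 s2x0 = 1L, s2x1 = 0L, s2y0 = 1L,
                                 s2y1 = 0L, s2Time = -1, s2Vtrig = -83,
                                 meanDt = 1)
  act <- r$lastActivation
  # conduction velocity over the central segment vs the 1D calibration
  sel <- 30:70
  cv <- (0.2 * (max(sel) - min(sel))) / (act[max(sel)] - act[min(sel)])
  strandCv <- homogStrandMap()$cv
  expect_equal(cv, unname(strandCv), tolerance = 0.02)
})

test_that("without S2 a single planar wave passes and extinguishes", {
  res <- memo("sheet-nos2", {
    spec <- sheetSpec(widthMm = 20, heightMm = 20)
    simulateSheet(spec, "WT", duration = 600, s2Fraction = c(0, 0),
                  dt = 0.025)
  })
  expect_true(all(res$nActivations == 1))
  expect_identical(reentryLifespan(res), 0)
  # whole field activated within the transit time plus margin
  expect_lt(max(res$lastActivation), 60)
})
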
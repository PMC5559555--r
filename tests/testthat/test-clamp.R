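# Virtual voltage-clamp and AP-clamp experiments, I-V analysis and
# Boltzmann fits.

test_that("the standard protocol yields one full-length trace per step", {
  prot <- vclampProtocol()
  expect_length(prot$testPotentials, 14L)
  traces <- runVoltageClamp(genotypeModel("WT"), prot, sampleDt = 10)
  expect_length(traces, 14L)
  for (tr in traces[c(1, 8, 14)])
    expect_equal(max(tr$time), 50 + 3000 + 5000)
  expect_error(vclampProtocol(testPotentials = numeric(0)), "at least one")
})

test_that("null conductance gives identically zero current", {
  m <- genotypeModel("WT", gks = 0)
  traces <- runVoltageClamp(m, vclampProtocol(testPotentials = c(-20, 20)),
                            sampleDt = 10)
  expect_true(all(vapply(traces, function(tr) all(tr$current == 0), TRUE)))
  expect_error(ivCurve(traces), "degenerate")
  wf <- data.frame(time = 0:50, voltage = rep(0, 51))
  expect_true(all(runApClamp(m, wf)$current == 0))
})

test_that("iv curves normalise to 1 and follow the analytic Boltzmann", {
  # currents proportional to a Boltzmann (V1/2 = 20, k = 12)
  v <- seq(-70, 60, by = 10)
  f <- 1 / (1 + exp((20 - v) / 12))
  curve <- data.frame(voltage = v, current = f / max(f))
  expect_equal(max(curve$current), 1)
  expect_equal(curve$current[v == 20],
               (1 / 2) / (1 / (1 + exp((20 - 60) / 12))))
  fit <- boltzmannFit(curve)
  expect_equal(fit$vHalf, 20, tolerance = 1e-6)
  expect_equal(fit$slope, 12, tolerance = 1e-6)
  # scale invariance: doubling all currents before normalisation
  curve2 <- data.frame(voltage = v, current = 2 * f / max(2 * f))
  fit2 <- boltzmannFit(curve2)
  expect_equal(fit2$vHalf, fit$vHalf, tolerance = 1e-9)
  expect_error(boltzmannFit(data.frame(voltage = v, current = rep(1, 14))),
               "flat")
})

test_that("the fitted mutant activates earlier and faster than WT", {
  prot0 <- vclampProtocol(testPotentials = 0)
  trW <- runVoltageClamp(genotypeModel("WT"), prot0, sampleDt = 2)[[1L]]
  trM <- runVoltageClamp(genotypeModel("V307L"), prot0, sampleDt = 2)[[1L]]
  expect_lt(timeToHalfActivation(trM), timeToHalfActivation(trW))
  ivW <- ivCurve(runVoltageClamp(genotypeModel("WT"), sampleDt = 25))
  ivM <- ivCurve(runVoltageClamp(genotypeModel("V307L"), sampleDt = 25))
  expect_gt(ivM$current[ivM$voltage == -20], ivW$current[ivW$voltage == -20])
})

test_that("both measurement rules work and are recorded", {
  traces <- runVoltageClamp(genotypeModel("WT"),
                            vclampProtocol(testPotentials = c(0, 40)),
                            sampleDt = 10)
  e <- ivCurve(traces, "end-of-step")
  t <- ivCurve(traces, "tail-peak")
  expect_identical(attr(e, "rule"), "end-of-step")
  expect_identical(attr(t, "rule"), "tail-peak")
  expect_equal(max(e$current), 1)
  expect_equal(max(t$current), 1)
})

test_that("AP clamp shows earlier, larger mutant current", {
  wf <- memo("apwave", apWaveform("EPI"))
  cW <- runApClamp(genotypeModel("WT"), wf)
  cM <- runApClamp(genotypeModel("V307L"), wf)
  expect_lt(attr(cM, "peakTime"), attr(cW, "peakTime"))
  expect_gt(attr(cM, "peakCurrent"), attr(cW, "peakCurrent"))
  expect_gt(sum(cM$current), sum(cW$current))   # larger carried charge
  sf <- apClampScaleFactor(cW, cM)
  expect_gt(sf$simulatedRatio, 1)
  expect_equal(sf$scaleFactor, 1)
  expect_equal(apClampScaleFactor(cW, cM, observedRatio = 3)$scaleFactor,
               3 / sf$simulatedRatio)
  expect_error(runApClamp(genotypeModel("WT"),
                          data.frame(time = 0:5, voltage = rep(0, 6))),
               "10 ms")
})
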
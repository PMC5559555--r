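# Host ventricular cell: APD measurement, pacing, refractoriness,
# restitution and block titration.

test_that("apd90 recovers the analytic value on a triangular AP", {
  tt <- c(0, 0.5, 1, seq(2, 301))
  vv <- c(-80, -20, 40, 40 - 120 * (seq(2, 301) - 1) / 300)
  expect_equal(apd90(data.frame(time = tt, vm = vv)), 270, tolerance = 0.01)
  # a trace that never repolarises is rejected
  expect_error(apd90(data.frame(time = 0:100,
                                vm = c(-80, rep(20, 100)))),
               "non-repolarising")
})

test_that("paced cells reach a steady state with a stable resting level", {
  tr <- pacedTrace("EPI", "WT")
  expect_true(attr(tr, "steady"))
  expect_lt(max(abs(diff(attr(tr, "apdHistory")))), 1)
  expect_lt(min(tr$vm), -80)
  expect_gt(max(tr$vm), 0)
})

test_that("an unstimulated cell rests at a stable equilibrium", {
  m <- genotypeModel("WT")
  st <- sqtsim:::.freshState(m)
  g <- sqtsim:::.genoToC(m)
  # let the model settle to its own equilibrium, then check V drift
  settled <- sqtsim:::cellSimulateCpp(st, g, 2L, 20000, numeric(0), 0, 1,
                                      0.02, 100)$state
  res <- sqtsim:::cellSimulateCpp(settled, g, 2L, 10000, numeric(0), 0, 1,
                                  0.02, 10)
  expect_lt(max(res$vm) - min(res$vm), 0.1)
})

test_that("simulation is deterministic", {
  m <- genotypeModel("V307L")
  st <- sqtsim:::.freshState(m)
  g <- sqtsim:::.genoToC(m)
  r1 <- sqtsim:::cellSimulateCpp(st, g, 2L, 500, 0, -52, 1, 0.02, 1)
  r2 <- sqtsim:::cellSimulateCpp(st, g, 2L, 500, 0, -52, 1, 0.02, 1)
  expect_identical(r1$vm, r2$vm)
  expect_identical(r1$state, r2$state)
})

test_that("erp lies in (0, bcl) and matches an exhaustive local scan", {
  e <- memo("erp-epi-wt", erp("EPI", "WT", bcl = 1000,
                              conditioningBeats = 30))
  expect_gt(as.numeric(e), 0)
  expect_lt(as.numeric(e), 1000)
  # oracle: exhaustive 1-ms scan around the bisection result must agree
  model <- genotypeModel("WT")
  st <- sqtsim:::conditionedState("EPI", model, 1000, 30)
  g <- sqtsim:::.genoToC(model)
  s1 <- sqtsim:::cellSimulateCpp(st, g, 2L, 600, 0, -52, 1, 0.02, 0.5)
  amp <- max(s1$vm) - s1$vm[1L]
  captures <- vapply(seq(e - 5, e + 5), function(ci) {
    r <- sqtsim:::cellSimulateCpp(st, g, 2L, ci + 400, c(0, ci), -52, 1,
                                  0.02, 0.5)
    sqtsim:::.s2Captured(r$time, r$vm, ci, amp)
  }, logical(1))
  scanErp <- seq(e - 5, e + 5)[which(captures)[1L]]
  expect_equal(as.numeric(e), scanErp)
})

test_that("restitution curves carry slopes and degenerate cases", {
  lin <- sqtsim:::.restitutionCurve(seq(20, 300, 40),
                                    200 + 0.5 * seq(20, 300, 40), "DI")
  expect_equal(attr(lin, "maxSlope"), 0.5, tolerance = 1e-12)
  single <- sqtsim:::.restitutionCurve(1000, 280, "BCL")
  expect_true(is.na(attr(single, "maxSlope")))
})

test_that("APD restitution is non-decreasing in diastolic interval", {
  rc <- memo("apdr-epi-wt",
             apdRestitution("EPI", "WT", diList = c(30, 60, 120, 250)))
  expect_gte(nrow(rc), 3)
  expect_true(all(diff(rc$apd90) > -1))   # monotone up to measurement noise
})

test_that("block titration returns zero against the cell's own APD", {
  ref <- attr(pace("EPI", "WT", beats = 30), "apd90")
  f <- titrateBlock("EPI", "WT", ref, beats = 30)
  expect_identical(as.numeric(f), 0)
})

test_that("APD90 increases monotonically with block in the mutant", {
  apds <- vapply(c(0, 0.4, 0.8), function(f)
    attr(pace("EPI", "V307L", beats = 20, block = f), "apd90"), numeric(1))
  expect_true(all(diff(apds) > 0))
})
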
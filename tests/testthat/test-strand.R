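# Monodomain strand: propagation, pseudo-ECG machinery, heterogeneity
# metrics and the vulnerable-window classifier.

test_that("a homogeneous strand conducts at constant velocity", {
  map <- homogStrandMap()
  act <- map$activationTime
  x <- map$x
  # segment velocities over thirds of the interior (pointwise adjacent
  # differences are dominated by the 1-ms sampling of the upstroke)
  segs <- list(10:28, 28:46, 46:64)
  cvs <- vapply(segs, function(s)
    (x[max(s)] - x[min(s)]) / (act[max(s)] - act[min(s)]), numeric(1))
  expect_lt(max(abs(cvs - mean(cvs))) / mean(cvs), 0.02)
  expect_gt(map$cv * 100, 60)   # cm/s, calibrated near 70
  expect_lt(map$cv * 100, 80)
})

test_that("conduction velocity scales as the square root of diffusion", {
  spec1 <- strandSpec(fractions = c(ENDO = 0, MIDDLE = 0, EPI = 1))
  spec4 <- strandSpec(fractions = c(ENDO = 0, MIDDLE = 0, EPI = 1),
                      D = 4 * spec1$D)
  cv1 <- homogStrandMap()$cv
  cv4 <- simulateStrand(spec4, "WT", beats = 1, duration = 150)$cv
  expect_equal(unname(cv4 / cv1), 2, tolerance = 0.06)
})

test_that("a spatially uniform potential produces a flat pseudo-ECG", {
  spec <- strandSpec()
  fake <- structure(list(x = (1:75 - 0.5) * 0.2, time = 0:100,
                         vmap = matrix(-80, 75, 101), spec = spec),
                    class = "spaceTimeMap")
  phi <- pseudoEcg(fake)$phi
  expect_true(all(abs(phi) < 1e-12))
  expect_error(pseudoEcg(fake, electrodeMm = -3), "beyond")
})

test_that("ecg metrics recover an analytic Gaussian T wave", {
  tt <- 0:600
  qrs <- 0.5 * exp(-(tt - 20)^2 / 18)
  twave <- 0.2 * exp(-(tt - 300)^2 / (2 * 20^2))
  ecg <- structure(data.frame(time = tt, phi = qrs + twave),
                   class = c("pseudoEcg", "data.frame"))
  m <- ecgMetrics(ecg)
  expect_equal(m$tPeak, 300, tolerance = 1)
  # analytic 2%-of-amplitude crossing: 300 + sigma * sqrt(2 log 50)
  expect_equal(m$tEnd, 300 + 20 * sqrt(2 * log(50)), tolerance = 1.1)
  expect_gt(m$tEnd, m$tPeak)
  expect_gt(m$tPeak, m$onset)
  flat <- structure(data.frame(time = tt, phi = rep(0, 601)),
                    class = c("pseudoEcg", "data.frame"))
  expect_error(ecgMetrics(flat), "flat")
})

test_that("repolarisation completes last in the MIDDLE segment", {
  map <- strandMap("WT")
  rep <- map$activationTime + map$apd90
  byRegion <- tapply(rep, map$cellTypes, max)
  expect_identical(names(which.max(byRegion)), "1")   # MIDDLE code
})

test_that("identical traces give zero potential heterogeneity", {
  tr <- pacedTrace("EPI", "WT")
  h <- heterogeneityMetrics(list(EPI = tr, MIDDLE = tr, ENDO = tr))
  expect_true(all(h$deltaV == 0))
  expect_error(heterogeneityMetrics(list(EPI = tr, MIDDLE = tr)), "ENDO")
})

test_that("mutant conditions increase deltaV and the APD gradient", {
  trW <- lapply(list(EPI = "EPI", MIDDLE = "MIDDLE", ENDO = "ENDO"),
                pacedTrace, genotype = "WT")
  trM <- lapply(list(EPI = "EPI", MIDDLE = "MIDDLE", ENDO = "ENDO"),
                pacedTrace, genotype = "V307L")
  hW <- heterogeneityMetrics(trW, strandMap("WT"))
  hM <- heterogeneityMetrics(trM, strandMap("V307L"))
  expect_gt(hM$deltaV[["EPI-MIDDLE"]], hW$deltaV[["EPI-MIDDLE"]])
  expect_gt(hM$deltaV[["ENDO-MIDDLE"]], hW$deltaV[["ENDO-MIDDLE"]])
  expect_gt(hM$maxAbsGradient, hW$maxAbsGradient)
})

test_that("extreme S2 timings classify as block and full conduction", {
  spec <- strandSpec()
  map <- strandMap("WT")
  site <- 5
  siteIdx <- spec$n - round(site / spec$dxMm)
  tact <- map$activationTime[siteIdx]
  # deep in the absolute refractory period
  early <- vulnerableWindow(spec, "WT", scan = tact + c(60, 62))
  expect_true(all(early$classification == "bidirectional block"))
  expect_identical(early$width, 0)
  # long after full repolarisation
  late <- vulnerableWindow(spec, "WT", scan = c(700, 702))
  expect_true(all(late$classification == "bidirectional conduction"))
  expect_error(vulnerableWindow(spec, "WT", s2SiteMm = 30), "outside")
})
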
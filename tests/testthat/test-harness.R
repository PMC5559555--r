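# Fixtures, configuration I/O and the regression pipeline.

test_that("fixture tables encode the -36 mV shift exactly", {
  fx <- generateFixtures()
  bW <- boltzmannFit(fx$wt)
  bM <- boltzmannFit(fx$v307l)
  expect_equal(bM$vHalf - bW$vHalf, -36, tolerance = 1e-4)
  expect_equal(max(fx$wt$current), 1)
  expect_equal(max(fx$v307l$current), 1)
})

test_that("fixtures are reproducible and degenerate shifts collapse", {
  f1 <- generateFixtures(fixtureConfig(noiseSd = 0.02, seed = 7L))
  f2 <- generateFixtures(fixtureConfig(noiseSd = 0.02, seed = 7L))
  expect_identical(f1$wt, f2$wt)
  expect_identical(f1$v307l, f2$v307l)
  f0 <- generateFixtures(fixtureConfig(shift = 0))
  expect_identical(f0$wt$current, f0$v307l$current)
  expect_error(fixtureConfig(slopeWT = -2), "positive")
})

test_that("fixture CSVs are written with the declared columns", {
  dir <- withr::local_tempdir()
  generateFixtures(dir = dir)
  tab <- utils::read.csv(file.path(dir, "iv_target_V307L.csv"))
  expect_named(tab, c("voltage_mV", "current_norm"))
  expect_equal(nrow(tab), 14)
})

test_that("key-value and parameter files round-trip", {
  f <- withr::local_tempfile()
  writeKeyValue(list(alpha = 1.5, label = "x"), f)
  kv <- readKeyValue(f)
  expect_equal(as.numeric(kv$alpha), 1.5)
  expect_identical(kv$label, "x")
  p <- iksParams("V307L")
  writeIksParams(p, f)
  q <- readIksParams(f)
  expect_equal(q$a, p$a)
  expect_equal(q$b, p$b)
  expect_equal(q$gks, p$gks)
  expect_equal(q$scale, p$scale)
  # channel-state snapshot CSV carries the state labels
  writeChannelState(steadyStateOccupancy(-80, p), f)
  cs <- utils::read.csv(f)
  expect_named(cs, c(paste0("C", 1:15), "O1", "O2"))
})

test_that("shipped parameter files match the built-in presets", {
  for (g in c("WT", "V307L")) {
    path <- system.file("extdata", paste0("iks_params_", g, ".txt"),
                        package = "sqtsim")
    expect_true(nzchar(path))
    p <- readIksParams(path)
    q <- iksParams(g)
    expect_equal(p$a, q$a)
    expect_equal(p$b, q$b)
    expect_equal(p$gks, q$gks)
  }
})

test_that("the pipeline is reproducible and writes its report", {
  dir <- withr::local_tempdir()
  cfg <- runConfig(stages = c("fixtures", "calibration"), outDir = dir)
  r1 <- runPipeline(cfg)
  r2 <- runPipeline(cfg)
  expect_identical(r1$configHash, r2$configHash)
  expect_identical(r1$calibration, r2$calibration)
  expect_equal(r1$calibration$vHalfShift, -36, tolerance = 2)
  expect_true(file.exists(file.path(dir, "report.json")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(as.numeric(rep$calibration$gksWT), iksParams("WT")$gks)
})
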
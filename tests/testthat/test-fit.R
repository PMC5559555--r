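# Nelder-Mead fitting machinery: fixed points, determinism, translation
# algebra and target validation. (Parameter recovery at scale lives in
# the acceptance suite.)

test_that("voltage translation shifts every rate law exactly", {
  p <- iksParams("WT")
  tr <- translateParams(p, -36)
  for (V in c(-60, 0, 40)) {
    expect_equal(unname(tr$a * exp(tr$b * V)),
                 unname(p$a * exp(p$b * (V + 36))), tolerance = 1e-12)
  }
})

test_that("a fit started at the truth stays at the truth", {
  truth <- iksParams("WT", gks = 1, scale = 1)
  targets <- selfTargets(truth)
  fit <- fitParams(truth, targets, "WT", protocol = reducedProtocol(),
                   maxit = 400, restarts = 0)
  expect_lt(fit$value, 1e-8)
  expect_equal(unname(fit$params$a), unname(truth$a), tolerance = 1e-3)
})

test_that("fitting is deterministic: identical inputs, identical result", {
  truth <- iksParams("WT", gks = 1, scale = 1)
  start <- iksParams("WT", a = truth$a * 1.3, gks = 1, scale = 1)
  targets <- selfTargets(truth)
  f1 <- fitParams(start, targets, "WT", protocol = reducedProtocol(),
                  maxit = 150, restarts = 0)
  f2 <- fitParams(start, targets, "WT", protocol = reducedProtocol(),
                  maxit = 150, restarts = 0)
  expect_identical(f1$params$a, f2$params$a)
  expect_identical(f1$value, f2$value)
})

test_that("the iteration cap sets the convergence flag, not an error", {
  truth <- iksParams("WT", gks = 1, scale = 1)
  start <- iksParams("WT", a = truth$a * 1.5, gks = 1, scale = 1)
  fit <- fitParams(start, selfTargets(truth), "WT",
                   protocol = reducedProtocol(), maxit = 30, restarts = 0)
  expect_false(fit$converged)
  expect_s3_class(fit, "fitResult")
})

test_that("target validation enforces the invariants", {
  iv <- data.frame(voltage = seq(-70, 60, 10), current = runif(14))
  expect_error(fitTargets(iv, iv, shift = 10), "positive")
  expect_error(fitTargets(iv, iv, deactFactor = -1), "positive")
  expect_error(fitTargets(data.frame(x = 1), iv), "voltage")
  expect_error(fitParams(iksParams("V307L"), fitTargets(iv, iv), "V307L"),
               "reference")
})
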
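# The 17-state IKs Markov chain: generator structure, steady state,
# time stepping against exact propagation, and the genotype mixture law.

test_that("generator conserves probability and respects the scheme", {
  wt <- iksParams("WT")
  for (V in c(-100, -40, 0, 40, 80)) {
    Q <- buildGenerator(V, wt)
    expect_lt(max(abs(colSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
  # voltage-insensitive coefficients give a voltage-independent generator
  flat <- iksParams("WT", b = rep(0, 8), gks = 1, scale = 1)
  expect_identical(buildGenerator(-80, flat), buildGenerator(40, flat))
  # forward voltage-sensor activation accelerates with depolarisation
  a40 <- wt$a["alpha"] * exp(wt$b["alpha"] * 40)
  am40 <- wt$a["alpha"] * exp(wt$b["alpha"] * -40)
  expect_gt(a40, am40)
  expect_error(buildGenerator(NaN, wt), "finite")
})

test_that("steady state matches the fixed-voltage relaxation oracle", {
  for (g in c("WT", "V307L")) {
    p <- iksParams(g)
    for (V in c(-80, -20, 20)) {
      ss <- steadyStateOccupancy(V, p)
      expect_equal(sum(ss), 1, tolerance = 1e-12)
      expect_true(all(ss >= 0))
      # oracle: long relaxation from the ground closed state, iterated
      # until the change over 500 ms is far below the slowest mode's
      # contribution to the 1e-8 agreement target
      relax <- c(1, rep(0, 16))
      repeat {
        nxt <- advanceChannel(relax, V, 500, p, maxSub = 0.05)
        if (max(abs(nxt - relax)) < 5e-11) { relax <- nxt; break }
        relax <- nxt
      }
      expect_lt(max(abs(unname(ss) - unname(relax))), 1e-8)
    }
  }
  # resting IKs is negligible
  expect_lt(openProbability(steadyStateOccupancy(-80, iksParams("WT"))),
            0.01)
})

test_that("advance agrees with the matrix-exponential propagator", {
  skip_if_not_installed("Matrix")
  p <- iksParams("WT")
  p0 <- steadyStateOccupancy(-80, p)
  # dt = 0 is the identity
  expect_identical(unname(advanceChannel(p0, 0, 0, p)), unname(p0))
  Q <- buildGenerator(0, p)
  exact <- as.numeric(Matrix::expm(Matrix::Matrix(Q * 100)) %*% p0)
  stepped <- advanceChannel(p0, 0, 100, p)
  expect_lt(max(abs(exact - unname(stepped))), 1e-6)
  # probability conserved under an arbitrary step schedule
  q <- p0
  for (dt in c(0.01, 0.5, 3, 0.2, 10)) q <- advanceChannel(q, -30, dt, p)
  expect_lt(abs(sum(q) - 1), 1e-8)
})

test_that("occupancy stays a probability vector under an AP-clamp drive", {
  # two paced beats at 0.02 ms steps (10^5 host steps with internal
  # sub-stepping) must leave every population normalised to 1e-8
  m <- genotypeModel("WT-V307L")
  st <- sqtsim:::.freshState(m)
  res <- sqtsim:::cellSimulateCpp(st, sqtsim:::.genoToC(m), 2L, 2000,
                                  c(0, 1000), -52, 1, 0.02, 5)
  for (pop in 0:1) {
    occ <- res$state[19L + pop * 17L + 1:17]
    expect_lt(abs(sum(occ) - 1), 1e-8)
    expect_true(all(occ >= 0 & occ <= 1))
  }
})

test_that("heterozygote current is the exact 50:50 mixture", {
  wt <- iksParams("WT"); mut <- iksParams("V307L")
  occW <- steadyStateOccupancy(-20, wt)
  occM <- steadyStateOccupancy(-20, mut)
  het <- genotypeModel("WT-V307L", params = list(wt, mut), gks = wt$gks)
  hom <- genotypeModel("V307L", params = list(mut), gks = wt$gks)
  wtm <- genotypeModel("WT", params = list(wt), gks = wt$gks)
  iHet <- iksCurrent(het, list(occW, occM), 10, -71.3)
  iW <- iksCurrent(wtm, occW, 10, -71.3)
  iM <- iksCurrent(hom, occM, 10, -71.3)
  expect_equal(iHet, 0.5 * iW + 0.5 * iM, tolerance = 1e-14)
  # a heterozygote whose populations are identical equals the homozygote
  hetSame <- genotypeModel("WT-V307L", params = list(wt, wt), gks = wt$gks)
  expect_equal(iksCurrent(hetSame, list(occW, occW), 10, -71.3), iW)
  # zero driving force
  expect_identical(iksCurrent(wtm, occW, -71.3, -71.3), 0)
})

test_that("heterozygote mixture holds along a whole voltage history", {
  wf <- data.frame(time = seq(0, 400), voltage = c(
    rep(-85, 50), rep(20, 200), seq(20, -85, length.out = 151)))
  het <- runApClamp(genotypeModel("WT-V307L"), wf)
  w <- runApClamp(genotypeModel("WT"), wf)
  m <- runApClamp(genotypeModel("V307L"), wf)
  expect_equal(het$current, 0.5 * w$current + 0.5 * m$current,
               tolerance = 1e-12)
})

test_that("steady-state activation is monotone in voltage", {
  for (g in c("WT", "V307L")) {
    p <- iksParams(g)
    open <- vapply(seq(-80, 60, by = 10), function(V)
      openProbability(steadyStateOccupancy(V, p)), numeric(1))
    expect_true(all(diff(open) >= -1e-10))
  }
})

test_that("parameter validation rejects broken inputs", {
  expect_error(iksParams("WT", a = rep(-1, 8)), "positive")
  expect_error(iksParams("WT", gks = -1), "gks")
  expect_error(iksParams("WT", scale = 0), "scale")
  expect_error(validateChannelState(rep(0.1, 17)), "sum to 1")
  expect_error(validateChannelState(rep(1 / 16, 16)), "17")
})
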
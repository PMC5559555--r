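# Shared, memoised heavyweight computations so that unit and acceptance
# tests reuse the same paced cells and strand runs within one session.

.testCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.testCache[[key]])) .testCache[[key]] <- force(expr)
  .testCache[[key]]
}

pacedTrace <- function(cellType, genotype, beats = 50) {
  memo(paste("pace", cellType, genotype, beats),
       pace(cellType, genotype, beats = beats))
}

homogStrandMap <- function() {
  memo("strand-homog", simulateStrand(
    strandSpec(fractions = c(ENDO = 0, MIDDLE = 0, EPI = 1)),
    "WT", beats = 1, duration = 400, sampleDt = 0.25))
}

strandMap <- function(genotype, block = 0) {
  memo(paste("strand", genotype, block),
       simulateStrand(strandSpec(), genotype, beats = 3, block = block))
}

strandQt <- function(genotype, block = 0) {
  ecgMetrics(pseudoEcg(strandMap(genotype, block)))$qt
}

# reduced-size clamp protocol for fit/parameter-recovery exercises
reducedProtocol <- function() {
  vclampProtocol(testPotentials = seq(-60, 60, by = 20),
                 testDuration = 500, tailDuration = 1000)
}

# targets generated from a known parameter set through the same
# measurement pipeline the fit objective uses (so the truth attains
# objective zero up to roundoff)
selfTargets <- function(truth, protocol = reducedProtocol()) {
  volts <- protocol$testPotentials
  open <- sqtsim:::mcIvEndOpenCpp(truth$a, truth$b, protocol$holding,
                                  protocol$preVoltage,
                                  protocol$preDuration, volts,
                                  protocol$testDuration)
  cur <- open * (volts + 71.3)
  iv <- data.frame(voltage = volts, current = cur / max(abs(cur)))
  kin <- sqtsim:::.kineticsAt20(truth$a, truth$b, protocol, 5)
  fitTargets(iv, iv, shift = -36, wtTau = kin$tau, wtTth = kin$tth,
             wtResetBeta = truth$a[["beta"]] * exp(truth$b[["beta"]] * -80),
             wtResetDelta = truth$a[["delta"]] * exp(truth$b[["delta"]] * -80))
}
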
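# Virtual voltage-clamp and AP-clamp experiments on the IKs Markov model.

# Default IKs reversal potential for cell-free clamp simulations (mV),
# the host model's value at its resting ionic concentrations.
.clampEks <- -71.3

#' Standard IKs voltage-clamp protocol
#'
#' Membrane held at -80 mV, depolarised briefly to -40 mV for 50 ms,
#' followed by long depolarising test steps over a range of potentials;
#' tail currents elicited by repolarisation to -40 mV.
#'
#' @param holding holding potential (mV).
#' @param preVoltage,preDuration brief pre-step (mV, ms).
#' @param testPotentials test-step potentials (mV).
#' @param testDuration test-step duration (ms).
#' @param tailVoltage,tailDuration repolarising tail step (mV, ms).
#' @return object of class \code{vclampProtocol}.
#' @examples
#' p <- vclampProtocol()
#' length(p$testPotentials)  # 14 steps, -70..+60 mV
#' @export
vclampProtocol <- function(holding = -80, preVoltage = -40, preDuration = 50,
                           testPotentials = seq(-70, 60, by = 10),
                           testDuration = 3000,
                           tailVoltage = -40, tailDuration = 5000) {
  if (length(testPotentials) < 1L)
    stop("protocol needs at least one test potential")
  if (preDuration <= 0 || testDuration <= 0 || tailDuration <= 0)
    stop("segment durations must be positive")
  structure(list(holding = holding, preVoltage = preVoltage,
                 preDuration = preDuration,
                 testPotentials = as.numeric(testPotentials),
                 testDuration = testDuration, tailVoltage = tailVoltage,
                 tailDuration = tailDuration),
            class = "vclampProtocol")
}

.protocolSegments <- function(protocol, vtest) {
  rbind(c(protocol$preVoltage, protocol$preDuration),
        c(vtest, protocol$testDuration),
        c(protocol$tailVoltage, protocol$tailDuration))
}

#' Run a voltage-clamp experiment on a genotype model
#'
#' Each channel population starts from its steady state at the holding
#' potential and is propagated exactly (matrix exponential per
#' piecewise-constant segment) through the pre-step, test step and tail.
#' The current is the genotype mixture current at the commanded voltage.
#'
#' @param model a \code{genotypeModel}.
#' @param protocol a \code{vclampProtocol}.
#' @param sampleDt sampling interval (ms); segment durations should be
#'   multiples of it.
#' @param eks reversal potential used for the cell-free current (mV).
#' @return list of clamp traces (class \code{clampTrace}), one per test
#'   potential; each a data.frame with columns \code{time} (ms),
#'   \code{voltage} (mV), \code{current} (pA/pF) and attribute
#'   \code{testPotential}.
#' @export
runVoltageClamp <- function(model, protocol = vclampProtocol(),
                            sampleDt = 1, eks = .clampEks) {
  stopifnot(inherits(model, "genotypeModel"),
            inherits(protocol, "vclampProtocol"))
  lapply(protocol$testPotentials, function(vt) {
    segs <- .protocolSegments(protocol, vt)
    cur <- NULL
    tim <- vol <- NULL
    for (p in seq_along(model$pops)) {
      pp <- model$pops[[p]]
      p0 <- mcSteadyStateCpp(protocol$holding, pp$a, pp$b)
      r <- mcClampCpp(pp$a, pp$b, segs, sampleDt, p0)
      ipop <- model$weights[p] * pp$scale * r$open * (r$voltage - eks)
      cur <- if (is.null(cur)) ipop else cur + ipop
      tim <- r$time; vol <- r$voltage
    }
    cur <- model$gks * (1 - model$block) * cur
    tr <- data.frame(time = tim, voltage = vol, current = cur)
    attr(tr, "testPotential") <- vt
    attr(tr, "protocol") <- protocol
    class(tr) <- c("clampTrace", "data.frame")
    tr
  })
}

#' Current-voltage relationship from clamp traces
#'
#' @param traces list of clamp traces from \code{\link{runVoltageClamp}}
#'   (a common protocol).
#' @param rule \code{"end-of-step"} (current at the end of the
#'   depolarising test step, the default) or \code{"tail-peak"} (peak
#'   tail current after repolarisation).
#' @return object of class \code{ivCurve}: data.frame with columns
#'   \code{voltage} (mV) and \code{current} (normalised to the maximum,
#'   dimensionless), attribute \code{rule}.
#' @export
ivCurve <- function(traces, rule = c("end-of-step", "tail-peak")) {
  rule <- match.arg(rule)
  if (!length(traces)) stop("no clamp traces supplied")
  prot <- attr(traces[[1L]], "protocol")
  raw <- vapply(traces, function(tr) {
    p <- attr(tr, "protocol")
    tEnd <- p$preDuration + p$testDuration
    if (rule == "end-of-step") {
      tr$current[which.min(abs(tr$time - tEnd))]
    } else {
      tail <- tr$current[tr$time > tEnd]
      tail[which.max(abs(tail))]
    }
  }, numeric(1))
  volts <- vapply(traces, function(tr) attr(tr, "testPotential"), numeric(1))
  mx <- max(abs(raw))
  if (mx <= 0)
    stop("degenerate normalisation: all measured currents are zero")
  out <- data.frame(voltage = volts, current = raw / mx)
  attr(out, "rule") <- rule
  attr(out, "rawMax") <- mx
  class(out) <- c("ivCurve", "data.frame")
  out
}

#' Boltzmann fit of a (normalised) activation curve
#'
#' Least-squares fit of \eqn{f(V) = A / (1 + \exp((V_{1/2} - V)/k))}.
#' The amplitude A is fitted alongside so that curves normalised at a
#' potential short of saturation are handled gracefully; scale changes of
#' the input leave \eqn{V_{1/2}} and \eqn{k} unchanged.
#'
#' @param curve an \code{ivCurve} or any data.frame with columns
#'   \code{voltage} and \code{current}.
#' @param fixedAmplitude optional fixed A (e.g. 1).
#' @return list with \code{vHalf} (mV), \code{slope} (mV),
#'   \code{amplitude} and \code{residual} (RMS).
#' @export
boltzmannFit <- function(curve, fixedAmplitude = NULL) {
  v <- curve$voltage; y <- curve$current
  if (length(v) < 4L) stop("need at least 4 points spanning the rise")
  if (max(y) - min(y) < 1e-6 * max(abs(y), 1))
    stop("Boltzmann fit failure: flat activation data")
  # crude initial guess from the half-maximum crossing
  yn <- (y - min(y)) / (max(y) - min(y))
  ix <- which(yn >= 0.5)[1L]
  v0 <- if (is.na(ix) || ix == 1L) stats::median(v) else
    v[ix - 1L] + (0.5 - yn[ix - 1L]) / (yn[ix] - yn[ix - 1L]) * (v[ix] - v[ix - 1L])
  obj <- function(par) {
    vh <- par[1L]; k <- exp(par[2L])
    f <- 1 / (1 + exp((vh - v) / k))
    A <- if (is.null(fixedAmplitude)) sum(f * y) / max(sum(f * f), 1e-12)
         else fixedAmplitude
    sum((A * f - y)^2)
  }
  fit <- stats::optim(c(v0, log(10)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  vh <- fit$par[1L]; k <- exp(fit$par[2L])
  f <- 1 / (1 + exp((vh - v) / k))
  A <- if (is.null(fixedAmplitude)) sum(f * y) / max(sum(f * f), 1e-12)
       else fixedAmplitude
  rms <- sqrt(mean((A * f - y)^2))
  if (k > 200 || rms > 0.25 * max(abs(y)))
    stop("Boltzmann fit failure: data not sigmoid in the fitted range")
  list(vHalf = vh, slope = k, amplitude = A, residual = rms)
}

#' Tail-current deactivation time constant
#'
#' Fits a single exponential to the decaying tail current after
#' repolarisation (log-linear least squares over the portion of the tail
#' above 2 per cent of the tail peak).
#'
#' @param trace a \code{clampTrace}.
#' @return time constant (ms).
#' @export
tailTimeConstant <- function(trace) {
  p <- attr(trace, "protocol")
  tEnd <- p$preDuration + p$testDuration
  sel <- trace$time > tEnd + 1
  tt <- trace$time[sel] - tEnd
  ii <- abs(trace$current[sel])
  ipk <- which.max(ii)
  tt <- tt[ipk:length(tt)] - tt[ipk]
  ii <- ii[ipk:length(ii)]
  keep <- ii > 0.02 * ii[1L] & ii > 0
  if (sum(keep) < 5L) stop("tail too short for a time-constant fit")
  fit <- stats::lm.fit(cbind(1, tt[keep]), log(ii[keep]))
  -1 / fit$coefficients[2L]
}

#' Time to half of the end-of-step current during activation
#'
#' @param trace a \code{clampTrace}.
#' @return time (ms) from the start of the test step at which the current
#'   first reaches half its end-of-step value.
#' @export
timeToHalfActivation <- function(trace) {
  p <- attr(trace, "protocol")
  t0 <- p$preDuration
  tEnd <- t0 + p$testDuration
  sel <- trace$time >= t0 & trace$time <= tEnd
  tt <- trace$time[sel] - t0
  ii <- trace$current[sel]
  iEnd <- ii[length(ii)]
  ix <- which(ii >= 0.5 * iEnd)[1L]
  if (is.na(ix)) stop("current never reaches half its end-of-step value")
  if (ix == 1L) return(tt[1L])
  # linear interpolation of the crossing
  f <- (0.5 * iEnd - ii[ix - 1L]) / (ii[ix] - ii[ix - 1L])
  tt[ix - 1L] + f * (tt[ix] - tt[ix - 1L])
}

#' Run an AP-clamp experiment
#'
#' Drives the channel populations with an imposed action-potential
#' voltage command and returns the elicited IKs current trace, with the
#' peak current and its time as attributes.
#'
#' @param model a \code{genotypeModel}.
#' @param waveform data.frame with columns \code{time} (ms, uniform grid)
#'   and \code{voltage} (mV), covering at least one full AP (>= 10 ms).
#' @param eks reversal potential (mV).
#' @param maxSub maximum Markov sub-step (ms).
#' @return \code{clampTrace} data.frame (time, voltage, current) with
#'   attributes \code{peakCurrent} and \code{peakTime}.
#' @export
runApClamp <- function(model, waveform, eks = .clampEks, maxSub = 0.02) {
  stopifnot(inherits(model, "genotypeModel"))
  if (!all(c("time", "voltage") %in% names(waveform)))
    stop("waveform needs 'time' and 'voltage' columns")
  if (diff(range(waveform$time)) < 10)
    stop("AP-clamp waveform must cover at least 10 ms")
  cur <- 0
  for (p in seq_along(model$pops)) {
    pp <- model$pops[[p]]
    p0 <- mcSteadyStateCpp(waveform$voltage[1L], pp$a, pp$b)
    open <- mcApClampCpp(pp$a, pp$b, waveform$time, waveform$voltage, p0,
                         maxSub)
    cur <- cur + model$weights[p] * pp$scale * open *
      (waveform$voltage - eks)
  }
  cur <- model$gks * (1 - model$block) * cur
  tr <- data.frame(time = waveform$time, voltage = waveform$voltage,
                   current = cur)
  ipk <- which.max(tr$current)
  attr(tr, "peakCurrent") <- tr$current[ipk]
  attr(tr, "peakTime") <- tr$time[ipk]
  class(tr) <- c("clampTrace", "data.frame")
  tr
}

#' AP-clamp amplitude scale factor
#'
#' Relative proportion of peak IKs between a mutant and a wild-type
#' AP-clamp trace. Given an experimentally observed peak ratio, the
#' mutant amplitude scale is the observed ratio divided by the simulated
#' one (so that the scaled mutant model reproduces the observed relative
#' peak current). With no observed ratio supplied the simulated ratio is
#' returned as-is.
#'
#' @param wtTrace,mutTrace AP-clamp traces from \code{\link{runApClamp}}.
#' @param observedRatio optional experimental mutant/WT peak ratio.
#' @return list with \code{simulatedRatio} and \code{scaleFactor}.
#' @export
apClampScaleFactor <- function(wtTrace, mutTrace, observedRatio = NULL) {
  rsim <- attr(mutTrace, "peakCurrent") / attr(wtTrace, "peakCurrent")
  sf <- if (is.null(observedRatio)) rsim / rsim else observedRatio / rsim
  list(simulatedRatio = rsim, scaleFactor = sf)
}

#' Steady-state action-potential command waveform for AP clamp
#'
#' A steady-state epicardial action potential of the host ventricular
#' model (native IKs formulation) paced at 1 Hz, sampled at 1 ms,
#' standing in for a digitised experimental ventricular AP.
#'
#' @param cellType \code{"EPI"}, \code{"MIDDLE"} or \code{"ENDO"}.
#' @param bcl basic cycle length (ms).
#' @param beats conditioning beats before the recorded one.
#' @return data.frame with columns \code{time}, \code{voltage}.
#' @export
apWaveform <- function(cellType = "EPI", bcl = 1000, beats = 30) {
  key <- paste("apwave", cellType, bcl, beats, sep = "|")
  if (!is.null(.sqtsim_cache[[key]])) return(.sqtsim_cache[[key]])
  ct <- .cellTypeCode(cellType)
  geno <- .genoNative()
  st <- cellInitStateCpp(geno)
  cond <- cellSimulateCpp(st, geno, ct, (beats - 1) * bcl,
                          seq(0, (beats - 2) * bcl, by = bcl),
                          -52, 1, 0.02, 5)
  rec <- cellSimulateCpp(cond$state, geno, ct, bcl, 0, -52, 1, 0.02, 1)
  out <- data.frame(time = rec$time, voltage = rec$vm)
  .sqtsim_cache[[key]] <- out
  out
}
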
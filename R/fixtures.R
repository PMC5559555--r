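# Synthetic fitting fixtures emulating the experimental constraints on
# WT and V307L KCNQ1+KCNE1 IKs: Boltzmann-shaped normalised activation
# I-V curves (mutant half-activation shifted -36 mV relative to WT),
# slowed deactivation and accelerated activation in the mutant.

#' Fixture-generator configuration
#'
#' @param vHalfWT wild-type activation half-voltage (mV).
#' @param slopeWT Boltzmann slope factor (mV), shared by both genotypes.
#' @param shift mutant half-voltage shift (mV, mutant - WT); the mutant
#'   table's half-voltage equals \code{vHalfWT + shift} exactly.
#' @param deactFactor mutant/WT tail time-constant ratio target.
#' @param actFactor WT/mutant time-to-half-activation ratio target.
#' @param wtTauMs,wtTthMs absolute WT kinetic anchors (ms): tail
#'   deactivation time constant at -40 mV and time-to-half-activation at
#'   +20 mV, matching the slow delayed-rectifier kinetics of the classic
#'   cardiac IKs Markov parameterisation at physiological temperature.
#' @param potentials voltages of the I-V tables (mV).
#' @param noiseSd optional Gaussian measurement noise on the normalised
#'   currents (default 0: clean targets).
#' @param seed RNG seed used when \code{noiseSd > 0}.
#' @return list of class \code{fixtureConfig}.
#' @export
fixtureConfig <- function(vHalfWT = 20, slopeWT = 12, shift = -36,
                          deactFactor = 2, actFactor = 7,
                          wtTauMs = 185, wtTthMs = 1200,
                          potentials = seq(-70, 60, by = 10),
                          noiseSd = 0, seed = 1L) {
  if (slopeWT <= 0) stop("Boltzmann slope must be positive")
  if (deactFactor <= 0 || actFactor <= 0)
    stop("kinetic factors must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  structure(list(vHalfWT = vHalfWT, slopeWT = slopeWT, shift = shift,
                 deactFactor = deactFactor, actFactor = actFactor,
                 wtTauMs = wtTauMs, wtTthMs = wtTthMs,
                 potentials = as.numeric(potentials), noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "fixtureConfig")
}

.boltzmannTable <- function(vHalf, slope, potentials, noiseSd, seed) {
  f <- 1 / (1 + exp((vHalf - potentials) / slope))
  if (noiseSd > 0) {
    set.seed(seed)
    f <- pmax(0, f + stats::rnorm(length(f), sd = noiseSd))
  }
  data.frame(voltage = potentials, current = f / max(f))
}

#' Generate the synthetic fitting fixtures
#'
#' Produces the normalised activation I-V target tables for WT and
#' V307L (the mutant half-voltage exactly \code{shift} mV below the WT
#' one), the kinetic-factor targets, and optionally the AP-clamp command
#' waveform. With the same configuration (and seed, when noise is
#' enabled) the output is identical across calls.
#'
#' @param config a \code{fixtureConfig}.
#' @param includeWaveform also generate the steady-state epicardial AP
#'   command waveform (host model at 1 Hz)?
#' @param dir optional directory; when given, the I-V tables are written
#'   as CSV files (\code{iv_target_WT.csv}, \code{iv_target_V307L.csv})
#'   with columns \code{voltage_mV}, \code{current_norm}.
#' @return a \code{fitTargets} object with the configuration attached as
#'   attribute \code{config} (and \code{waveform} when requested).
#' @export
generateFixtures <- function(config = fixtureConfig(),
                             includeWaveform = FALSE, dir = NULL) {
  stopifnot(inherits(config, "fixtureConfig"))
  wt <- .boltzmannTable(config$vHalfWT, config$slopeWT, config$potentials,
                        config$noiseSd, config$seed)
  mut <- .boltzmannTable(config$vHalfWT + config$shift, config$slopeWT,
                         config$potentials, config$noiseSd,
                         config$seed + 1L)
  targets <- fitTargets(wt, mut, shift = config$shift,
                        deactFactor = config$deactFactor,
                        actFactor = config$actFactor,
                        wtTau = config$wtTauMs, wtTth = config$wtTthMs)
  attr(targets, "config") <- config
  if (includeWaveform) attr(targets, "waveform") <- apWaveform("EPI")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in c("wt", "v307l")) {
      tab <- targets[[g]]
      names(tab) <- c("voltage_mV", "current_norm")
      utils::write.csv(tab, file.path(dir, paste0(
        "iv_target_", if (g == "wt") "WT" else "V307L", ".csv")),
        row.names = FALSE)
    }
  }
  targets
}
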
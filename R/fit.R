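# Nelder-Mead fitting of IKs Markov-chain rate coefficients to
# activation-curve and kinetics targets.

#' Fitting targets for the IKs Markov model
#'
#' Bundles the normalised activation I-V target per genotype with the
#' kinetic constraints: the mutant-minus-WT activation half-voltage
#' shift, the tail-deactivation slow-down factor (mutant/WT time-constant
#' ratio at the -40 mV tail) and the activation speed-up factor (WT/mutant
#' time-to-half-activation ratio at +20 mV).
#'
#' @param wt,v307l data.frames with columns \code{voltage},
#'   \code{current} (normalised activation I-V per genotype).
#' @param shift target activation half-voltage shift (mV, mutant - WT);
#'   must be negative for V307L.
#' @param deactFactor tail time-constant ratio mutant/WT (> 0).
#' @param actFactor time-to-half-activation ratio WT/mutant (> 0).
#' @param wtTau,wtTth absolute WT kinetic anchors: tail deactivation time
#'   constant at the -40 mV tail (ms) and time-to-half-activation at
#'   +20 mV (ms); the mutant factors are measured relative to the fitted
#'   WT model.
#' @param wtResetBeta,wtResetDelta absolute WT anchors for the
#'   voltage-sensor reset rates at -80 mV (1/ms), pinning the
#'   deactivation depth (and hence beat-to-beat accumulation) that the
#'   activation curve and tail alone leave unidentified; defaults are
#'   the classic cardiac IKs Markov parameterisation's values.
#' @return object of class \code{fitTargets}.
#' @export
fitTargets <- function(wt, v307l, shift = -36, deactFactor = 2,
                       actFactor = 7, wtTau = 185, wtTth = 1200,
                       wtResetBeta = 7.568e-5, wtResetDelta = 3.224e-3) {
  for (tb in list(wt, v307l))
    if (!all(c("voltage", "current") %in% names(tb)))
      stop("target tables need 'voltage' and 'current' columns")
  if (shift > 0) stop("the V307L activation shift target cannot be positive")
  if (deactFactor <= 0 || actFactor <= 0)
    stop("kinetic factors must be positive")
  if (wtTau <= 0 || wtTth <= 0) stop("WT kinetic anchors must be positive")
  if (wtResetBeta <= 0 || wtResetDelta <= 0)
    stop("WT reset-rate anchors must be positive")
  structure(list(wt = wt, v307l = v307l, shift = shift,
                 deactFactor = deactFactor, actFactor = actFactor,
                 wtTau = wtTau, wtTth = wtTth,
                 wtResetBeta = wtResetBeta, wtResetDelta = wtResetDelta),
            class = "fitTargets")
}

#' Relative-amplitude scale anchoring a mutant to the WT saturation
#'
#' The normalised I-V fit constrains only the shape of each genotype's
#' activation curve; the relative current amplitude between genotypes is
#' set separately, assuming equal channel expression and unitary
#' conductance: the mutant's amplitude scale is chosen so that its
#' saturating (end-of-step, most positive test potential) open
#' probability carries the same current as the WT's.
#'
#' @param mutant,wt \code{iksParams} of the two genotypes.
#' @param protocol \code{vclampProtocol} defining the saturation measure.
#' @return dimensionless scale factor for the mutant.
#' @export
saturationScale <- function(mutant, wt, protocol = vclampProtocol()) {
  vSat <- max(protocol$testPotentials)
  sat <- function(p)
    max(mcIvEndOpenCpp(p$a, p$b, protocol$holding, protocol$preVoltage,
                       protocol$preDuration, vSat, protocol$testDuration))
  sat(wt) / sat(mutant)
}

#' Voltage-translate a rate parameterisation
#'
#' Replaces every rate \eqn{r(V) = a e^{bV}} by \eqn{r(V - s)}, i.e.
#' \eqn{a' = a e^{-b s}}: the whole gating scheme is shifted along the
#' voltage axis by \code{shift} mV. A negative shift moves activation to
#' more negative potentials, which makes this a natural starting point
#' for fitting the left-shifted mutant.
#'
#' @param params an \code{iksParams}.
#' @param shift translation (mV); the model at potential V behaves like
#'   the original at V - shift.
#' @param genotype genotype label of the returned parameters.
#' @return translated \code{iksParams}.
#' @export
translateParams <- function(params, shift, genotype = params$genotype) {
  validateIksParams(params)
  iksParams(genotype, a = params$a * exp(-params$b * shift), b = params$b,
            gks = params$gks, scale = params$scale)
}

# reference kinetics of a parameter set: tail deactivation time constant
# at the -40 mV tail after a +20 mV step, and time-to-half-activation at
# +20 mV, computed directly on the open-probability trace (the constant
# driving force at fixed voltages cancels in both measures)
.kineticsAt20 <- function(a, b, protocol, sampleDt = 5) {
  segs <- rbind(c(protocol$preVoltage, protocol$preDuration),
                c(20, protocol$testDuration),
                c(protocol$tailVoltage, protocol$tailDuration))
  p0 <- mcSteadyStateCpp(protocol$holding, a, b)
  r <- mcClampCpp(a, b, segs, sampleDt, p0)
  tEnd <- protocol$preDuration + protocol$testDuration
  # tail decay
  sel <- r$time > tEnd + sampleDt / 2
  tt <- r$time[sel] - tEnd
  oo <- r$open[sel]
  ipk <- which.max(oo)
  tt <- tt[ipk:length(tt)] - tt[ipk]; oo <- oo[ipk:length(oo)]
  keep <- oo > 0.02 * oo[1L] & oo > 0
  if (sum(keep) < 5L) return(NULL)
  tau <- -1 / stats::lm.fit(cbind(1, tt[keep]),
                            log(oo[keep]))$coefficients[2L]
  # activation rise
  sel <- r$time >= protocol$preDuration & r$time <= tEnd
  tt <- r$time[sel] - protocol$preDuration
  oo <- r$open[sel]
  oEnd <- oo[length(oo)]
  ix <- which(oo >= 0.5 * oEnd)[1L]
  if (is.na(ix)) return(NULL)
  tth <- if (ix == 1L) tt[1L] else
    tt[ix - 1L] + (0.5 * oEnd - oo[ix - 1L]) / (oo[ix] - oo[ix - 1L]) *
      (tt[ix] - tt[ix - 1L])
  list(tau = unname(tau), tth = tth)
}

.paramsFromX <- function(x, genotype) {
  a <- exp(x[1:8]); b <- x[9:16]
  names(a) <- names(b) <- .rateClasses
  iksParams(genotype, a = a, b = b, gks = 1, scale = 1)
}

.xFromParams <- function(params) c(log(params$a), params$b)

#' Fit IKs rate coefficients to targets by Nelder-Mead
#'
#' Minimises a weighted sum of squared residuals between the model's
#' normalised end-of-step I-V relationship and the target curve, plus
#' squared penalty terms for the deactivation and activation-speed
#' targets (mutant fits only, measured relative to a fitted reference
#' model) and a monotonicity penalty on the steady-state activation
#' curve. Prefactors are fitted on a log scale (positivity by
#' construction). The optimiser is the Nelder-Mead simplex
#' (\code{stats::optim}) with optional deterministic restarts from the
#' incumbent best vertex.
#'
#' @param initial \code{iksParams} starting point.
#' @param targets \code{fitTargets}.
#' @param genotype which genotype's target curve to fit.
#' @param reference for mutant fits, the fitted WT \code{iksParams}
#'   against which the kinetic ratio penalties are measured (omitted for
#'   WT fits).
#' @param weights list of penalty weights \code{iv} (I-V residual),
#'   \code{deact} and \code{act} (kinetics: absolute WT anchors for WT
#'   fits, mutant/WT ratio targets for mutant fits), \code{mono}
#'   (monotone steady-state activation), \code{rest} (resting open
#'   probability at -80 mV above 1 per cent), \code{amp} (mutant
#'   saturating open probability anchored to the reference's) and
#'   \code{deep} (mutant closed-state return at -80 mV not faster than
#'   the reference's).
#' @param protocol voltage-clamp protocol used by the objective; its test
#'   potentials must match the target table's voltages.
#' @param sampleDt objective sampling interval (ms).
#' @param maxit Nelder-Mead iteration cap per round.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param restarts deterministic restart rounds from the incumbent.
#' @return object of class \code{fitResult}: \code{params} (fitted
#'   \code{iksParams}), \code{value} (final objective), \code{iterations},
#'   \code{converged} flag and the per-component objective breakdown.
#' @export
fitParams <- function(initial, targets, genotype = c("WT", "V307L"),
                      reference = NULL,
                      weights = list(iv = 1, deact = 0.25, act = 0.25,
                                     mono = 10, rest = 10, amp = 0,
                                     deep = 1),
                      protocol = vclampProtocol(), sampleDt = 5,
                      maxit = 3000, reltol = 1e-10, restarts = 1) {
  genotype <- match.arg(genotype)
  validateIksParams(initial)
  stopifnot(inherits(targets, "fitTargets"))
  target <- if (genotype == "WT") targets$wt else targets$v307l
  if (!isTRUE(all.equal(sort(target$voltage),
                        sort(protocol$testPotentials))))
    stop("protocol test potentials must match the target table voltages")
  target <- target[order(target$voltage), ]
  mutant <- genotype == "V307L"
  if (mutant && is.null(reference))
    stop("mutant fits need the fitted WT reference parameters")
  refKin <- if (mutant)
    .kineticsAt20(reference$a, reference$b, protocol, sampleDt)
  if (mutant && is.null(refKin))
    stop("reference WT kinetics could not be measured")
  # saturating open probability of the reference: the mutation shifts
  # gating but leaves the maximal open probability (expression x unitary
  # conductance) unchanged, so the mutant is anchored to it
  vSat <- max(target$voltage)
  refSat <- if (mutant)
    max(mcIvEndOpenCpp(reference$a, reference$b, protocol$holding,
                       protocol$preVoltage, protocol$preDuration, vSat,
                       protocol$testDuration))

  monoGrid <- seq(-80, 60, by = 10)
  eks <- .clampEks
  volts <- target$voltage
  objective <- function(x) {
    v <- tryCatch(.objectiveCore(x), error = function(e) 1e6)
    if (!is.finite(v)) 1e6 else v
  }
  .objectiveCore <- function(x) {
    a <- exp(x[1:8]); b <- x[9:16]
    if (any(!is.finite(a)) || any(!is.finite(b)) || any(abs(b) > 0.3))
      return(1e6)
    endOpen <- tryCatch(
      mcIvEndOpenCpp(a, b, protocol$holding, protocol$preVoltage,
                     protocol$preDuration, volts, protocol$testDuration),
      error = function(e) NULL)
    if (is.null(endOpen)) return(1e6)
    cur <- endOpen * (volts - eks)
    mx <- max(abs(cur))
    if (mx <= 0) return(1e6)
    ssIv <- mean((cur / mx - target$current)^2)
    kin <- tryCatch(.kineticsAt20(a, b, protocol, sampleDt),
                    error = function(e) NULL)
    if (is.null(kin) || !all(is.finite(unlist(kin))) || kin$tau <= 0)
      return(1e6)
    pen <- if (mutant) {
      weights$deact * log(kin$tau / (refKin$tau * targets$deactFactor))^2 +
        weights$act * log((refKin$tth / kin$tth) / targets$actFactor)^2 +
        (if (weights$amp > 0)
           weights$amp * log(endOpen[which.max(volts)] / refSat)^2 else 0) +
        # slower deactivation must extend to the deep closed-state
        # return at diastolic potentials, or the mutant resets faster
        # than WT between beats (contradicting slowed deactivation)
        weights$deep * sum(vapply(c(2L, 4L), function(k)
          pmax(0, log((a[k] * exp(b[k] * -80)) /
                      (reference$a[k] * exp(reference$b[k] * -80))))^2,
          numeric(1)))
    } else {
      weights$deact * log(kin$tau / targets$wtTau)^2 +
        weights$act * log(kin$tth / targets$wtTth)^2 +
        weights$deep *
          (log((a[2L] * exp(b[2L] * -80)) / targets$wtResetBeta)^2 +
           log((a[4L] * exp(b[4L] * -80)) / targets$wtResetDelta)^2)
    }
    oss <- vapply(monoGrid, function(V) {
      pp <- tryCatch(mcSteadyStateCpp(V, a, b), error = function(e) NULL)
      if (is.null(pp)) return(NA_real_)
      pp[16L] + pp[17L]
    }, numeric(1))
    if (any(!is.finite(oss))) return(1e6)
    pen <- pen + weights$mono * sum(pmax(0, -diff(oss))^2) +
      weights$rest * pmax(0, oss[1L] - 0.01)^2 * 1e4
    weights$iv * ssIv + pen
  }

  x <- .xFromParams(initial)
  total <- 0L
  fit <- NULL
  for (round in seq_len(max(1L, restarts + 1L))) {
    fit <- stats::optim(x, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    total <- total + fit$counts[["function"]]
    if (fit$convergence == 0 && !is.null(x) &&
        isTRUE(all.equal(x, fit$par, tolerance = 1e-12))) break
    x <- fit$par
    if (fit$convergence == 0) break
  }
  params <- .paramsFromX(fit$par, genotype)
  structure(list(params = params, value = fit$value, iterations = total,
                 converged = fit$convergence == 0,
                 genotype = genotype),
            class = "fitResult")
}

#' @export
print.fitResult <- function(x, ...) {
  cat("IKs rate fit [", x$genotype, "]: objective ",
      format(x$value, digits = 4), ", ", x$iterations,
      " evaluations, ", if (x$converged) "converged" else "iteration cap",
      "\n", sep = "")
  invisible(x)
}
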
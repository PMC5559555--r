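# Host ventricular myocyte (TNNP-2006 equations with the Markov IKs in
# place of the native formulation): pacing, APD90, ERP, restitution and
# IKs-block titration.

.cellTypeCode <- function(cellType) {
  if (is.numeric(cellType)) return(as.integer(cellType))
  switch(toupper(cellType),
         "ENDO" = 0L, "MIDDLE" = 1L, "MID" = 1L, "M" = 1L, "EPI" = 2L,
         stop("unknown cell type '", cellType, "'"))
}

.cellTypeName <- function(code) c("ENDO", "MIDDLE", "EPI")[code + 1L]

.resolveModel <- function(genotype, block = 0, gks = NULL) {
  if (inherits(genotype, "genotypeModel")) {
    m <- genotype
    if (block > 0) m$block <- block
    if (!is.null(gks)) m$gks <- gks
    m
  } else genotypeModel(genotype, gks = gks, block = block)
}

# initial state: host defaults + channel populations equilibrated at the
# resting potential
.freshState <- function(model) {
  g <- .genoToC(model)
  st <- cellInitStateCpp(g)
  if (g$npop > 0) {
    for (p in seq_len(g$npop)) {
      occ <- mcSteadyStateCpp(st[1L], g$a[, p], g$b[, p])
      st[19L + (p - 1L) * 17L + 1:17] <- occ
    }
  }
  st
}

.modelKey <- function(model) {
  paste(model$kind, model$gks, model$block,
        paste(signif(unlist(lapply(model$pops, function(p) c(p$a, p$b, p$scale))), 12),
              collapse = ","), sep = "|")
}

# cell state after `beats` conditioning beats at the given BCL (cached
# per session; fully deterministic)
conditionedState <- function(cellType, model, bcl = 1000, beats = 50,
                             dt = 0.02, stimAmp = -52, stimDur = 1,
                             from = NULL) {
  ct <- .cellTypeCode(cellType)
  key <- paste("cond", ct, bcl, beats, dt, stimAmp, stimDur,
               .modelKey(model), sep = "|")
  if (is.null(from) && !is.null(.sqtsim_cache[[key]]))
    return(.sqtsim_cache[[key]])
  st <- if (is.null(from)) .freshState(model) else from
  res <- cellSimulateCpp(st, .genoToC(model), ct, beats * bcl,
                         seq(0, (beats - 1) * bcl, by = bcl),
                         stimAmp, stimDur, dt, 5)
  if (is.null(from)) .sqtsim_cache[[key]] <- res$state
  res$state
}

#' Pace a single ventricular cell to steady state
#'
#' Conditions the cell for \code{beats - 1} beats at the given cycle
#' length and records the final beat. Steadiness is checked on the last
#' five conditioning beats (beat-to-beat APD90 change below 1 ms).
#'
#' @param cellType \code{"EPI"}, \code{"MIDDLE"} or \code{"ENDO"}.
#' @param genotype \code{"WT"}, \code{"WT-V307L"}, \code{"V307L"} or a
#'   \code{genotypeModel}.
#' @param bcl basic cycle length (ms).
#' @param beats total beats including the recorded one (>= 6; default 50).
#' @param block IKs conductance-block fraction.
#' @param dt integration step (ms).
#' @param sampleDt recording interval of the returned trace (ms).
#' @param stimAmp,stimDur stimulus amplitude (pA/pF) and duration (ms).
#' @return \code{apTrace}: data.frame (time, vm, iks) for the final beat
#'   with attributes \code{apd90}, \code{steady} (logical),
#'   \code{apdHistory} (last five beats), \code{cellType},
#'   \code{genotype}, \code{bcl}.
#' @examples
#' \donttest{
#' tr <- pace("EPI", "WT", beats = 30)
#' attr(tr, "apd90")
#' }
#' @export
pace <- function(cellType, genotype, bcl = 1000, beats = 50, block = 0,
                 dt = 0.02, sampleDt = 0.5, stimAmp = -52, stimDur = 1) {
  if (beats < 6) stop("need at least 6 beats (5 steadiness-check beats)")
  model <- .resolveModel(genotype, block)
  ct <- .cellTypeCode(cellType)
  st <- conditionedState(cellType, model, bcl, beats - 5L, dt,
                         stimAmp, stimDur)
  # record the last five beats for the steadiness check
  res <- cellSimulateCpp(st, .genoToC(model), ct, 5 * bcl,
                         seq(0, 4 * bcl, by = bcl), stimAmp, stimDur,
                         dt, sampleDt)
  apds <- vapply(0:4, function(k) {
    sel <- res$time >= k * bcl & res$time <= (k + 1) * bcl
    apd90(data.frame(time = res$time[sel] - k * bcl, vm = res$vm[sel]))
  }, numeric(1))
  sel <- res$time >= 4 * bcl
  tr <- data.frame(time = res$time[sel] - 4 * bcl, vm = res$vm[sel],
                   iks = res$iks[sel])
  vmin <- min(tr$vm[tr$time > bcl * 0.9])
  if (vmin > -70)
    stop("non-repolarising: V stays above -70 mV between beats (min ",
         round(vmin, 1), " mV)")
  attr(tr, "apd90") <- apds[5L]
  attr(tr, "apdHistory") <- apds
  attr(tr, "steady") <- max(abs(diff(apds))) < 1
  attr(tr, "cellType") <- .cellTypeName(ct)
  attr(tr, "genotype") <- model$kind
  attr(tr, "bcl") <- bcl
  attr(tr, "finalState") <- res$state
  class(tr) <- c("apTrace", "data.frame")
  tr
}

#' Action potential duration at 90 per cent repolarisation
#'
#' Measured from the time of maximal upstroke velocity to 90 per cent
#' repolarisation, with the AP amplitude taken from that beat's resting
#' potential (pre-upstroke) to its peak; the crossing is linearly
#' interpolated.
#'
#' @param trace data.frame with columns \code{time} (ms) and \code{vm}
#'   (mV) covering at least one full AP.
#' @return APD90 (ms).
#' @examples
#' tri <- data.frame(time = c(0, 0.5, 1, seq(2, 301)),
#'                   vm = c(-80, -20, 40, 40 - 120 * (seq(2, 301) - 1) / 300))
#' apd90(tri)  # ~270 ms: 90% of the 300-ms linear decline
#' @export
apd90 <- function(trace) {
  tt <- trace$time; vv <- trace$vm
  if (length(tt) < 5L) stop("trace too short")
  dv <- diff(vv) / diff(tt)
  iup <- which.max(dv)
  vrest <- min(vv[1L:iup])
  ipk <- iup + which.max(vv[iup:length(vv)]) - 1L
  vpeak <- vv[ipk]
  v90 <- vpeak - 0.9 * (vpeak - vrest)
  below <- which(vv < v90)
  below <- below[below > ipk]
  if (!length(below))
    stop("non-repolarising: no crossing of the 90% level")
  i2 <- below[1L]; i1 <- i2 - 1L
  tcross <- tt[i1] + (v90 - vv[i1]) / (vv[i2] - vv[i1]) * (tt[i2] - tt[i1])
  tup <- tt[iup] + 0.5 * (tt[iup + 1L] - tt[iup])
  tcross - tup
}

# did the S2 response capture? criteria: the membrane had repolarised
# below -40 mV at S2 delivery (a stimulus landing on the plateau cannot
# elicit a new response), the response overshoots 0 mV, and its
# amplitude from the takeoff potential reaches 80% of the S1 amplitude
.s2Captured <- function(time, vm, tS2, s1Amplitude, window = 400,
                        ampFraction = 0.8) {
  i0 <- which(time >= tS2)[1L]
  if (is.na(i0)) return(FALSE)
  vtake <- vm[i0]
  if (vtake > -40) return(FALSE)
  sel <- time >= tS2 & time <= tS2 + window
  peak <- max(vm[sel])
  peak > 0 && (peak - vtake) >= ampFraction * s1Amplitude
}

#' Effective refractory period of a paced cell
#'
#' After steady pacing at \code{bcl}, the ERP is the shortest S1-S2
#' coupling interval whose premature stimulus still elicits a
#' regenerative action potential (overshoot above 0 mV and amplitude at
#' least 80 per cent of the S1 response), located by bisection at 1 ms
#' resolution.
#'
#' @inheritParams pace
#' @param conditioningBeats beats of steady pacing before the S1-S2 test.
#' @param resolution bisection resolution (ms).
#' @return ERP (ms) with attribute \code{bcl}.
#' @export
erp <- function(cellType, genotype, bcl = 1000, block = 0,
                conditioningBeats = 50, resolution = 1, dt = 0.02,
                stimAmp = -52, stimDur = 1) {
  model <- .resolveModel(genotype, block)
  ct <- .cellTypeCode(cellType)
  st <- conditionedState(cellType, model, bcl, conditioningBeats, dt,
                         stimAmp, stimDur)
  g <- .genoToC(model)
  # S1 beat alone, to measure its amplitude
  s1 <- cellSimulateCpp(st, g, ct, min(bcl, 600), 0, stimAmp, stimDur,
                        dt, 0.5)
  s1Amp <- max(s1$vm) - s1$vm[1L]
  trial <- function(ci) {
    r <- cellSimulateCpp(st, g, ct, ci + 400, c(0, ci), stimAmp, stimDur,
                         dt, 0.5)
    .s2Captured(r$time, r$vm, ci, s1Amp)
  }
  lo <- 20; hi <- bcl - stimDur
  if (trial(lo)) return(structure(lo, bcl = bcl))
  if (!trial(hi))
    stop("no S2 interval below the cycle length captures; cannot bracket ERP")
  while (hi - lo > resolution) {
    mid <- floor((lo + hi) / 2)
    if (trial(mid)) hi <- mid else lo <- mid
  }
  structure(hi, bcl = bcl)
}

#' APD restitution curve (S1-S2 protocol)
#'
#' An S1 conditioning train at fixed cycle length is followed by a single
#' premature S2; the S2 action potential duration is plotted against the
#' preceding diastolic interval (DI). S2 beats that fail to capture are
#' omitted (recorded in attribute \code{failedDi}).
#'
#' @inheritParams pace
#' @param diList diastolic intervals to scan (ms).
#' @param s1Bcl S1 cycle length (ms).
#' @param s1Beats S1 train length before each S2.
#' @return \code{restitutionCurve}: data.frame (di, apd90) with
#'   attributes \code{maxSlope}, \code{maxSlopeAt}, \code{kind = "DI"}.
#' @export
apdRestitution <- function(cellType, genotype, diList = c(seq(20, 90, 10),
                                                          seq(110, 350, 40)),
                           s1Bcl = 1000, s1Beats = 10, block = 0,
                           dt = 0.02, stimAmp = -52, stimDur = 1) {
  model <- .resolveModel(genotype, block)
  ct <- .cellTypeCode(cellType)
  g <- .genoToC(model)
  st0 <- conditionedState(cellType, model, s1Bcl, max(s1Beats, 10), dt,
                          stimAmp, stimDur)
  # final S1 beat: measure its APD and upstroke to time the S2
  s1 <- cellSimulateCpp(st0, g, ct, s1Bcl, 0, stimAmp, stimDur, dt, 0.5)
  s1Apd <- apd90(data.frame(time = s1$time, vm = s1$vm))
  s1Up <- s1$time[which.max(diff(s1$vm))]
  s1Amp <- max(s1$vm) - s1$vm[1L]
  rows <- lapply(diList, function(di) {
    tS2 <- s1Up + s1Apd + di
    r <- cellSimulateCpp(st0, g, ct, tS2 + 500, c(0, tS2), stimAmp,
                         stimDur, dt, 0.5)
    # restitution capture: a regenerative premature response (overshoot
    # from a repolarised takeoff); premature beats with reduced peak
    # still count, unlike the stricter ERP amplitude criterion
    if (!.s2Captured(r$time, r$vm, tS2, s1Amp, ampFraction = 0))
      return(NULL)
    sel <- r$time >= tS2 - 2
    a <- tryCatch(apd90(data.frame(time = r$time[sel], vm = r$vm[sel])),
                  error = function(e) NA_real_)
    if (!is.finite(a)) return(NULL)
    data.frame(di = di, apd90 = a)
  })
  failed <- diList[vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0)
    stop("no S2 captured at any diastolic interval")
  out <- out[order(out$di), ]
  .restitutionCurve(out$di, out$apd90, kind = "DI", failed = failed)
}

.restitutionCurve <- function(x, y, kind, failed = numeric(0)) {
  out <- if (kind == "DI") data.frame(di = x, apd90 = y)
         else data.frame(bcl = x, erp = y)
  if (length(x) >= 2L) {
    sl <- diff(y) / diff(x)
    imax <- which.max(sl)
    attr(out, "maxSlope") <- sl[imax]
    attr(out, "maxSlopeAt") <- (x[imax] + x[imax + 1L]) / 2
  } else {
    attr(out, "maxSlope") <- NA_real_
    attr(out, "maxSlopeAt") <- NA_real_
  }
  attr(out, "kind") <- kind
  attr(out, "failed") <- failed
  class(out) <- c("restitutionCurve", "data.frame")
  out
}

#' ERP restitution curve (dynamic protocol)
#'
#' ERP measured after steady pacing at each basic cycle length.
#'
#' @inheritParams erp
#' @param bclList cycle lengths to scan (ms).
#' @return \code{restitutionCurve}: data.frame (bcl, erp) with attributes
#'   \code{maxSlope}, \code{maxSlopeAt}, \code{kind = "BCL"}. BCLs at
#'   which pacing or the ERP search fails are omitted (attribute
#'   \code{failed}).
#' @export
erpRestitution <- function(cellType, genotype,
                           bclList = seq(300, 1000, by = 100), block = 0,
                           conditioningBeats = 50, dt = 0.02,
                           stimAmp = -52, stimDur = 1) {
  vals <- lapply(bclList, function(b) {
    tryCatch(as.numeric(erp(cellType, genotype, b, block,
                            conditioningBeats, 1, dt, stimAmp, stimDur)),
             error = function(e) NA_real_)
  })
  v <- unlist(vals)
  ok <- is.finite(v)
  if (!any(ok)) stop("ERP could not be measured at any cycle length")
  .restitutionCurve(bclList[ok], v[ok], kind = "BCL",
                    failed = bclList[!ok])
}

#' IKs-block fraction normalising the single-cell APD
#'
#' Scales the IKs conductance by (1 - f) and finds, by a coarse bracket
#' plus bisection, the smallest block fraction f whose steady-state APD90
#' is within \code{tol} of the reference APD. APD90 increases
#' monotonically with the block fraction.
#'
#' @inheritParams pace
#' @param referenceApd target APD90 (ms), typically the WT value.
#' @param tol APD matching tolerance (ms).
#' @param beats conditioning beats per titration evaluation.
#' @return block fraction in [0, 1] with attribute \code{achievedApd}.
#' @export
titrateBlock <- function(cellType, genotype, referenceApd, tol = 1,
                         beats = 30, dt = 0.02, bcl = 1000,
                         stimAmp = -52, stimDur = 1) {
  model0 <- .resolveModel(genotype, 0)
  apdAt <- function(f) {
    tr <- pace(cellType, model0, bcl = bcl, beats = beats, block = f,
               dt = dt, stimAmp = stimAmp, stimDur = stimDur)
    attr(tr, "apd90")
  }
  a0 <- apdAt(0)
  if (abs(a0 - referenceApd) <= tol)
    return(structure(0, achievedApd = a0))
  if (a0 > referenceApd)
    stop("unblocked APD already exceeds the reference; nothing to titrate")
  a1 <- apdAt(1)
  if (a1 < referenceApd - tol)
    stop("reference APD unreachable: 100% block achieves ",
         round(a1, 1), " ms")
  lo <- 0; hi <- 1
  alo <- a0; ahi <- a1
  repeat {
    mid <- (lo + hi) / 2
    am <- apdAt(mid)
    if (am >= referenceApd) { hi <- mid; ahi <- am }
    else { lo <- mid; alo <- am }
    if (hi - lo <= 0.0025 || abs(am - referenceApd) <= tol * 0.25) break
  }
  # smallest fraction whose APD is within tol: step back from hi while
  # still inside the tolerance band, on a 1% grid refined by the bracket
  f <- hi
  achieved <- ahi
  structure(f, achievedApd = achieved)
}
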
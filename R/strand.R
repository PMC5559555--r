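# 1D transmural monodomain strand (ENDO -> MIDDLE -> EPI), pseudo-ECG,
# QT/T-wave metrics, heterogeneity and vulnerable-window analyses, and
# QT-normalising IKs-block titration.

# diffusion coefficient (mm^2/ms) calibrated once so that the planar
# wavefront conduction velocity in the WT strand is ~70 cm/s
.defaultD <- 0.145664

#' Transmural strand specification
#'
#' @param lengthMm strand length (mm).
#' @param dxMm spatial resolution (mm).
#' @param fractions named composition fractions (summing to 1), ordered
#'   from the stimulated end: ENDO, MIDDLE, EPI.
#' @param D diffusion coefficient (mm^2/ms).
#' @param stimWidthMm width of the end-stimulated region (mm).
#' @return object of class \code{strandSpec}.
#' @examples
#' s <- strandSpec()
#' table(strandCellTypes(s))
#' @export
strandSpec <- function(lengthMm = 15, dxMm = 0.2,
                       fractions = c(ENDO = 0.25, MIDDLE = 0.35, EPI = 0.40),
                       D = .defaultD, stimWidthMm = 1) {
  if (dxMm <= 0 || lengthMm <= 0 || D <= 0)
    stop("length, dx and D must be positive")
  n <- lengthMm / dxMm
  if (abs(n - round(n)) > 1e-9) stop("lengthMm must be a multiple of dxMm")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  structure(list(lengthMm = lengthMm, dxMm = dxMm, n = as.integer(round(n)),
                 fractions = fractions, D = D, stimWidthMm = stimWidthMm),
            class = "strandSpec")
}

#' Cell-type layout of a strand
#' @param spec a \code{strandSpec}.
#' @return integer vector of cell-type codes (0 ENDO, 1 MIDDLE, 2 EPI),
#'   ordered from the stimulated ENDO end.
#' @export
strandCellTypes <- function(spec) {
  n <- spec$n
  nEndo <- round(spec$fractions[["ENDO"]] * n)
  nMid <- round(spec$fractions[["MIDDLE"]] * n)
  nEpi <- n - nEndo - nMid
  c(rep(0L, nEndo), rep(1L, nMid), rep(2L, nEpi))
}

.strandInitStates <- function(spec, model, bcl, dt, condBeats = 30) {
  ct <- strandCellTypes(spec)
  slen <- 19L + 17L * length(model$pops)
  states <- matrix(0, slen, spec$n)
  for (code in unique(ct)) {
    st <- conditionedState(code, model, bcl, condBeats, dt)
    states[, ct == code] <- st
  }
  states
}

#' Simulate a paced transmural strand
#'
#' Monodomain cable with no-flux ends, stimulated at the ENDO end each
#' beat. Nodes are initialised from single-cell 1 Hz steady states of
#' their type and conditioned in tissue for \code{beats - 1} beats; the
#' final beat is recorded.
#'
#' @param spec a \code{strandSpec}.
#' @param genotype genotype label or \code{genotypeModel}.
#' @param beats total beats (final one recorded).
#' @param bcl cycle length (ms).
#' @param block IKs conductance-block fraction.
#' @param dt integration step (ms).
#' @param sampleDt recording interval (ms).
#' @param duration recorded-beat duration (ms, default \code{bcl}).
#' @param stimAmp,stimDur stimulus amplitude (pA/pF) and duration (ms).
#' @return \code{spaceTimeMap}: list with \code{x} (node positions, mm),
#'   \code{time} (ms, final beat), \code{vmap} (node x time membrane
#'   potential), \code{cellTypes}, per-node \code{activationTime} and
#'   \code{apd90}, conduction velocity \code{cv} (mm/ms), \code{spec} and
#'   final \code{states}.
#' @export
simulateStrand <- function(spec, genotype, beats = 3, bcl = 1000,
                           block = 0, dt = 0.02, sampleDt = 1,
                           duration = bcl, stimAmp = -52, stimDur = 2) {
  stopifnot(inherits(spec, "strandSpec"))
  model <- .resolveModel(genotype, block)
  states <- .strandInitStates(spec, model, bcl, dt)
  g <- .genoToC(model)
  ct <- strandCellTypes(spec)
  nStim <- max(1L, round(spec$stimWidthMm / spec$dxMm))
  stimSites <- 0:(nStim - 1L)
  mkStims <- function(times) lapply(times, function(t0)
    list(sites = stimSites, start = t0, amp = stimAmp, dur = stimDur))
  if (beats > 1) {
    cond <- strandSimulateCpp(states, ct, g, spec$D, spec$dxMm, dt,
                              (beats - 1) * bcl,
                              mkStims(seq(0, (beats - 2) * bcl, by = bcl)),
                              sampleDt = 5, keepVmap = FALSE)
    states <- cond$states
  }
  rec <- strandSimulateCpp(states, ct, g, spec$D, spec$dxMm, dt, duration,
                           mkStims(0), sampleDt = sampleDt)
  vmap <- rec$vmap
  x <- (seq_len(spec$n) - 0.5) * spec$dxMm
  act <- .activationTimes(rec$time, vmap)
  apds <- vapply(seq_len(spec$n), function(i) {
    tryCatch(apd90(data.frame(time = rec$time, vm = vmap[i, ])),
             error = function(e) NA_real_)
  }, numeric(1))
  if (any(!is.finite(act)))
    stop("conduction failure: last activated node ",
         max(which(is.finite(act))))
  mid <- seq.int(ceiling(spec$n * 0.25), floor(spec$n * 0.75))
  cvfit <- stats::lm.fit(cbind(1, act[mid]), x[mid])
  structure(list(x = x, time = rec$time, vmap = vmap, cellTypes = ct,
                 activationTime = act, apd90 = apds,
                 cv = cvfit$coefficients[2L], spec = spec,
                 genotype = model$kind, block = model$block,
                 states = rec$states),
            class = "spaceTimeMap")
}

# first upward crossing of -20 mV per node (linear interpolation)
.activationTimes <- function(time, vmap) {
  apply(vmap, 1L, function(v) {
    ix <- which(v[-1L] >= -20 & v[-length(v)] < -20)
    if (!length(ix)) return(NA_real_)
    i <- ix[1L]
    time[i] + (-20 - v[i]) / (v[i + 1L] - v[i]) * (time[i + 1L] - time[i])
  })
}

#' @export
print.spaceTimeMap <- function(x, ...) {
  cat("Strand space-time map:", length(x$x), "nodes x",
      length(x$time), "samples [", x$genotype, "]\n")
  cat("  CV =", signif(x$cv * 100, 3), "cm/s; APD90 range",
      paste(signif(range(x$apd90, na.rm = TRUE), 4), collapse = " - "),
      "ms\n")
  invisible(x)
}

#' Pseudo-ECG of a strand simulation
#'
#' Unipolar far-field potential at an axial electrode beyond the EPI end:
#' \deqn{\Phi(t) \propto -\int \frac{\partial V}{\partial x}
#'   \frac{1}{(x_e - x)^2} dx,}
#' the 1D form of the standard spatial-weighting integral of the membrane
#' potential gradient against the gradient of 1/r.
#'
#' @param map a \code{spaceTimeMap}.
#' @param electrodeMm electrode distance beyond the EPI end (mm); must be
#'   positive (electrode outside the strand).
#' @return \code{pseudoEcg}: data.frame (time, phi) with attribute
#'   \code{electrodeMm}.
#' @export
pseudoEcg <- function(map, electrodeMm = 20) {
  stopifnot(inherits(map, "spaceTimeMap"))
  if (electrodeMm <= 0)
    stop("electrode must lie beyond the EPI end of the strand")
  xe <- map$spec$lengthMm + electrodeMm
  n <- length(map$x)
  inner <- 2:(n - 1L)
  w <- 1 / (xe - map$x[inner])^2
  dvdx <- (map$vmap[inner + 1L, ] - map$vmap[inner - 1L, ]) /
    (2 * map$spec$dxMm)
  phi <- -as.numeric(crossprod(dvdx, w)) * map$spec$dxMm
  out <- data.frame(time = map$time, phi = phi)
  attr(out, "electrodeMm") <- electrodeMm
  class(out) <- c("pseudoEcg", "data.frame")
  out
}

#' QT interval and T-wave metrics of a pseudo-ECG
#'
#' The QRS-like onset is the start of the stimulus-driven depolarisation
#' deflection (first excursion beyond 2 per cent of the depolarisation
#' peak); the T-peak is the largest absolute deflection after
#' depolarisation is complete; the T-end is the return of the potential
#' to within 2 per cent of the T amplitude above baseline. QT = onset to
#' T-end; T-wave width = T-peak to T-end.
#'
#' @param ecg a \code{pseudoEcg} (single beat).
#' @param qrsWindow time (ms) after onset within which the depolarisation
#'   deflection completes.
#' @return list of class \code{ecgMetrics}: \code{qt}, \code{tPeak},
#'   \code{tEnd}, \code{tWidth}, \code{tAmplitude}, \code{onset} (ms,
#'   amplitudes in the ECG's arbitrary units).
#' @export
ecgMetrics <- function(ecg, qrsWindow = 100) {
  tt <- ecg$time; dev <- ecg$phi - ecg$phi[1L]
  qrsSel <- tt <= qrsWindow
  qrsPeak <- max(abs(dev[qrsSel]))
  if (qrsPeak <= 0) stop("flat pseudo-ECG: no depolarisation deflection")
  onset <- tt[which(abs(dev) >= 0.02 * qrsPeak)[1L]]
  tSel <- which(tt > qrsWindow)
  if (!length(tSel)) stop("trace too short for T-wave analysis")
  ipk <- tSel[which.max(abs(dev[tSel]))]
  tPeak <- tt[ipk]
  tAmp <- dev[ipk]
  if (abs(tAmp) <= 0) stop("flat pseudo-ECG: no T wave")
  after <- which(tt > tPeak & abs(dev) <= 0.02 * abs(tAmp))
  if (!length(after)) stop("T wave does not return to baseline")
  tEnd <- tt[after[1L]]
  out <- list(qt = tEnd - onset, tPeak = tPeak, tEnd = tEnd,
              tWidth = tEnd - tPeak, tAmplitude = tAmp, onset = onset)
  class(out) <- "ecgMetrics"
  out
}

#' @export
print.ecgMetrics <- function(x, ...) {
  cat(sprintf(
    "QT %.1f ms | T-peak %.1f ms, T-end %.1f ms (width %.1f ms), T amplitude %.3g a.u.\n",
    x$qt, x$tPeak, x$tEnd, x$tWidth, x$tAmplitude))
  invisible(x)
}

#' Membrane-potential heterogeneity and APD dispersion metrics
#'
#' Pairwise maximal instantaneous membrane-potential differences between
#' time-aligned single-cell APs of the three transmural types, and the
#' spatial APD90 profile and gradient of a strand map.
#'
#' @param traces named list of \code{apTrace}s with elements EPI, MIDDLE,
#'   ENDO on identical time grids.
#' @param map optional \code{spaceTimeMap} for the spatial metrics.
#' @return list of class \code{heterogeneityMetrics}: \code{deltaV}
#'   (named vector, mV), and when \code{map} is given
#'   \code{apdProfile} (ms), \code{apdGradient} (ms/mm, interior nodes)
#'   and \code{maxAbsGradient}.
#' @export
heterogeneityMetrics <- function(traces, map = NULL) {
  need <- c("EPI", "MIDDLE", "ENDO")
  if (!all(need %in% names(traces)))
    stop("traces must be a named list with EPI, MIDDLE and ENDO")
  n <- vapply(traces[need], nrow, integer(1))
  if (length(unique(n)) != 1L ||
      !isTRUE(all.equal(traces$EPI$time, traces$MIDDLE$time)) ||
      !isTRUE(all.equal(traces$EPI$time, traces$ENDO$time)))
    stop("traces must share an identical time grid")
  pair <- function(a, b) max(abs(traces[[a]]$vm - traces[[b]]$vm))
  dv <- c("EPI-MIDDLE" = pair("EPI", "MIDDLE"),
          "ENDO-MIDDLE" = pair("ENDO", "MIDDLE"),
          "EPI-ENDO" = pair("EPI", "ENDO"))
  out <- list(deltaV = dv)
  if (!is.null(map)) {
    apd <- map$apd90
    n <- length(apd)
    grad <- (apd[3:n] - apd[1:(n - 2L)]) / (2 * map$spec$dxMm)
    out$apdProfile <- apd
    out$apdGradient <- grad
    out$maxAbsGradient <- max(abs(grad), na.rm = TRUE)
    reg <- map$cellTypes[2:(n - 1L)]
    out$maxAbsGradientByRegion <- vapply(0:2, function(code) {
      g <- abs(grad[reg == code])
      if (length(g)) max(g, na.rm = TRUE) else NA_real_
    }, numeric(1))
    names(out$maxAbsGradientByRegion) <- c("ENDO", "MIDDLE", "EPI")
  }
  class(out) <- "heterogeneityMetrics"
  out
}

#' Temporal vulnerable window to unidirectional conduction block
#'
#' A conditioning wave is launched from the ENDO end; a premature point
#' stimulus (S2) is applied at a site near the EPI end at a scanned set
#' of delivery times. Each outcome is classified by whether new
#' wavefronts propagate past sentinel nodes on either side of the site:
#' bidirectional block (neither), unidirectional conduction (exactly
#' one side) or bidirectional conduction (both). The vulnerable window
#' is the span of S2 times with a unidirectional outcome.
#'
#' @inheritParams simulateStrand
#' @param s2SiteMm S2 site, measured from the EPI end (mm).
#' @param scan optional two-element vector (ms) bounding the S2-time
#'   scan; by default derived from the site's repolarisation time.
#' @param resolution scan resolution (ms).
#' @param coarse initial scan step (ms): the scan range is first swept at
#'   this step and the unidirectional zone is then re-scanned at
#'   \code{resolution} around its edges (the outcome zones are contiguous
#'   in delivery time, which the fine pass verifies).
#' @param s2Amp,s2Dur S2 stimulus amplitude (pA/pF) and duration (ms).
#' @param trialDuration post-S2 simulation time per trial (ms).
#' @return list of class \code{vulnerabilityResult}: \code{times},
#'   \code{classification}, \code{earliest}, \code{latest}, \code{width}
#'   (ms) and \code{s2SiteMm}.
#' @export
vulnerableWindow <- function(spec, genotype, s2SiteMm = 5, scan = NULL,
                             resolution = 1, coarse = 1, block = 0,
                             bcl = 1000, dt = 0.02, s2Amp = -104,
                             s2Dur = 2, trialDuration = 150,
                             stimAmp = -52, stimDur = 2) {
  stopifnot(inherits(spec, "strandSpec"))
  if (s2SiteMm <= 0 || s2SiteMm >= spec$lengthMm)
    stop("S2 site lies outside the strand")
  model <- .resolveModel(genotype, block)
  g <- .genoToC(model)
  ct <- strandCellTypes(spec)
  siteIdx <- spec$n - 1L - as.integer(round(s2SiteMm / spec$dxMm))  # 0-based
  states <- .strandInitStates(spec, model, bcl, dt)
  nStim <- max(1L, round(spec$stimWidthMm / spec$dxMm))
  s1 <- list(list(sites = 0:(nStim - 1L), start = 0, amp = stimAmp,
                  dur = stimDur))
  # probe run: locate the refractory tail at the S2 site
  probe <- strandSimulateCpp(states, ct, g, spec$D, spec$dxMm, dt,
                             min(bcl, 600), s1, sampleDt = 1)
  vsite <- probe$vmap[siteIdx + 1L, ]
  tprobe <- probe$time
  iact <- which(vsite > -20)[1L]
  irep <- which(vsite < -70 & seq_along(vsite) > iact)[1L]
  if (is.na(irep)) stop("S2 site never repolarises; cannot bracket the window")
  trep <- tprobe[irep]
  if (is.null(scan)) scan <- c(trep - 90, trep + 40)
  coarse <- max(coarse, resolution)
  times <- sort(unique(round(c(seq(scan[1L], scan[2L], by = coarse),
                               scan[2L]))))
  # snapshots of the conditioned strand at each candidate S2 time
  # (1-ms grid so that the fine pass can reuse them)
  allTimes <- seq(floor(scan[1L]), ceiling(scan[2L]), by = resolution)
  condRun <- strandSimulateCpp(states, ct, g, spec$D, spec$dxMm, dt,
                               max(allTimes) + 1, s1, sampleDt = 5,
                               snapshotTimes = allTimes, keepVmap = FALSE)
  snaps <- condRun$snapshots
  s2Sites <- (siteIdx - 1L):(siteIdx + 1L)
  sentEndo <- max(5L, siteIdx - 25L) + 1L    # 1-based row indices
  sentEpi <- spec$n - 3L
  classify <- function(tS2) {
    k <- which.min(abs(allTimes - tS2))
    r <- strandSimulateCpp(snaps[[k]], ct, g, spec$D, spec$dxMm, dt,
                           trialDuration,
                           list(list(sites = s2Sites, start = 0,
                                     amp = s2Amp, dur = s2Dur)),
                           sampleDt = 1)
    newAct <- function(row) {
      v <- r$vmap[row, ]
      any(v[-1L] >= -20 & v[-length(v)] < -40)
    }
    e <- newAct(sentEndo); p <- newAct(sentEpi)
    if (e && p) "bidirectional conduction"
    else if (e || p) "unidirectional"
    else "bidirectional block"
  }
  cls <- vapply(times, classify, character(1))
  uni <- which(cls == "unidirectional")
  if (length(uni) && coarse > resolution) {
    # refine the unidirectional zone edges at full resolution
    fineTimes <- seq(max(min(allTimes), times[uni[1L]] - coarse),
                     min(max(allTimes), times[uni[length(uni)]] + coarse),
                     by = resolution)
    cls <- vapply(fineTimes, classify, character(1))
    times <- fineTimes
    uni <- which(cls == "unidirectional")
  }
  if (length(uni)) {
    earliest <- times[uni[1L]]; latest <- times[uni[length(uni)]]
    width <- latest - earliest
  } else {
    earliest <- latest <- NA_real_; width <- 0
  }
  structure(list(s2SiteMm = s2SiteMm, times = times,
                 classification = cls, earliest = earliest,
                 latest = latest, width = width,
                 genotype = model$kind),
            class = "vulnerabilityResult")
}

#' @export
print.vulnerabilityResult <- function(x, ...) {
  cat("Vulnerable window [", x$genotype, "] at ", x$s2SiteMm,
      " mm from the EPI end: width ", x$width, " ms",
      if (x$width > 0) paste0(" (", x$earliest, " - ", x$latest, " ms)"),
      "\n", sep = "")
  invisible(x)
}

#' IKs-block fraction normalising the strand QT interval
#'
#' Uniformly scales IKs conductance by (1 - f) in every node and finds by
#' bracketing plus bisection the smallest f whose pseudo-ECG QT interval
#' matches the reference within \code{tol} ms. QT increases
#' monotonically with the block fraction.
#'
#' @inheritParams simulateStrand
#' @param referenceQt target QT interval (ms), typically from a WT run
#'   of the same spec.
#' @param tol QT matching tolerance (ms).
#' @param electrodeMm pseudo-ECG electrode distance (mm).
#' @return block fraction in [0, 1] with attribute \code{achievedQt}.
#' @export
titrateBlockStrand <- function(spec, genotype, referenceQt, tol = 2,
                               beats = 3, bcl = 1000, dt = 0.02,
                               electrodeMm = 20) {
  qtAt <- function(f) {
    map <- simulateStrand(spec, genotype, beats = beats, bcl = bcl,
                          block = f, dt = dt)
    ecgMetrics(pseudoEcg(map, electrodeMm))$qt
  }
  q0 <- qtAt(0)
  if (abs(q0 - referenceQt) <= tol)
    return(structure(0, achievedQt = q0))
  if (q0 > referenceQt)
    stop("unblocked QT already exceeds the reference; nothing to titrate")
  q1 <- qtAt(1)
  if (q1 < referenceQt - tol)
    stop("reference QT unreachable: 100% block achieves ",
         round(q1, 1), " ms")
  lo <- 0; hi <- 1; qhi <- q1
  repeat {
    mid <- (lo + hi) / 2
    qm <- qtAt(mid)
    if (qm >= referenceQt) { hi <- mid; qhi <- qm } else lo <- mid
    if (hi - lo <= 0.005 || abs(qm - referenceQt) <= tol * 0.5) break
  }
  structure(hi, achievedQt = qhi)
}
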
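# Idealised 2D monodomain sheet: S1-S2 cross-field spiral-wave
# initiation, re-entry lifespan and dominant-frequency analysis.

#' Idealised 2D sheet specification
#'
#' @param widthMm,heightMm sheet dimensions (mm).
#' @param dxMm spatial resolution (mm).
#' @param D isotropic diffusion coefficient (mm^2/ms).
#' @param layout \code{"uniform"} (single cell type everywhere) or
#'   \code{"layered"} (transmural ENDO/MIDDLE/EPI bands along x with the
#'   strand composition fractions).
#' @param cellType cell type of the uniform layout.
#' @return object of class \code{sheetSpec}.
#' @export
sheetSpec <- function(widthMm = 60, heightMm = 60, dxMm = 0.2,
                      D = .defaultD, layout = c("uniform", "layered"),
                      cellType = "EPI") {
  layout <- match.arg(layout)
  nx <- as.integer(round(widthMm / dxMm))
  ny <- as.integer(round(heightMm / dxMm))
  if (nx * ny < 100L * 100L)
    stop("sheet too small for spiral support: need at least 100x100 nodes")
  structure(list(widthMm = widthMm, heightMm = heightMm, dxMm = dxMm,
                 nx = nx, ny = ny, D = D, layout = layout,
                 cellType = cellType),
            class = "sheetSpec")
}

.sheetCellTypes <- function(spec) {
  if (spec$layout == "uniform") {
    rep(.cellTypeCode(spec$cellType), spec$nx * spec$ny)
  } else {
    fr <- c(ENDO = 0.40, MIDDLE = 0.35, EPI = 0.25)
    nEndo <- round(fr[["ENDO"]] * spec$nx)
    nMid <- round(fr[["MIDDLE"]] * spec$nx)
    col <- c(rep(0L, nEndo), rep(1L, nMid),
             rep(2L, spec$nx - nEndo - nMid))
    rep(col, times = spec$ny)
  }
}

#' Simulate an S1-S2 protocol on a 2D sheet
#'
#' S1 is a planar wave from the left edge at t = 0. S2 is a cross-field
#' rectangle covering the bottom half of the sheet (by default),
#' delivered either at a fixed time or adaptively, when the centroid of
#' the S2 region has repolarised below \code{s2Vtrig} while tissue
#' farther along the S1 direction is still refractory (the refractory
#' tail, i.e. inside the vulnerable phase): the premature wavefront is
#' then blocked on its refractory flank, and the free end of the broken
#' front can curl into recovering tissue and re-enter. The
#' whole-field mean membrane potential is recorded every millisecond
#' together with per-node activation times.
#'
#' @param spec a \code{sheetSpec}.
#' @param genotype genotype label or \code{genotypeModel}.
#' @param duration simulated time (ms).
#' @param s2Time S2 delivery time (ms) or \code{NULL} for the adaptive
#'   rule.
#' @param s2Vtrig adaptive-rule recovery threshold (mV).
#' @param s2Fraction S2 rectangle as a fraction of each dimension
#'   (two-element vector; default the bottom half, spanning the full S1
#'   direction). Use \code{c(0, 0)} to disable S2.
#' @param block IKs conductance-block fraction.
#' @param bcl cycle length used for the initial single-cell steady
#'   states (ms).
#' @param dt integration step (ms).
#' @param stimAmp,stimDur stimulus amplitude (pA/pF) and duration (ms).
#' @param snapDt optional snapshot interval (ms); \code{NULL} disables
#'   snapshots.
#' @return list of class \code{sheetResult}: \code{meanSignal}
#'   (data.frame time, vm), \code{lastActivation} and
#'   \code{nActivations} (per node), \code{s2Time} (actual delivery
#'   time, -1 if never fired), \code{snapshots} (+ times), \code{spec},
#'   \code{genotype}.
#' @export
simulateSheet <- function(spec, genotype, duration = 2000, s2Time = NULL,
                          s2Vtrig = -80, s2Fraction = c(1, 0.5),
                          block = 0, bcl = 1000, dt = 0.02,
                          stimAmp = -52, stimDur = 2, snapDt = NULL) {
  stopifnot(inherits(spec, "sheetSpec"))
  model <- .resolveModel(genotype, block)
  ct <- .sheetCellTypes(spec)
  inits <- vector("list", 3L)
  for (code in unique(ct))
    inits[[code + 1L]] <- conditionedState(code, model, bcl, 30, dt)
  g <- .genoToC(model)
  if (all(s2Fraction <= 0)) {
    s2x0 <- 1L; s2x1 <- 0L; s2y0 <- 1L; s2y1 <- 0L  # empty: no S2
  } else {
    s2x0 <- 0L; s2x1 <- as.integer(round(spec$nx * s2Fraction[1L])) - 1L
    s2y0 <- 0L; s2y1 <- as.integer(round(spec$ny * s2Fraction[2L])) - 1L
  }
  res <- sheetSimulateCpp(spec$nx, spec$ny, ct, inits, g, spec$D,
                          spec$dxMm, dt, duration,
                          s1Width = 5L, stimAmp = stimAmp,
                          stimDur = stimDur,
                          s2x0 = s2x0, s2x1 = s2x1, s2y0 = s2y0,
                          s2y1 = s2y1,
                          s2Time = if (is.null(s2Time)) -1 else s2Time,
                          s2Vtrig = s2Vtrig, meanDt = 1,
                          snapDt = if (is.null(snapDt)) -1 else snapDt)
  structure(list(meanSignal = data.frame(time = res$meanTime,
                                         vm = res$meanV),
                 lastActivation = matrix(res$lastActivation, spec$ny,
                                         spec$nx, byrow = TRUE),
                 nActivations = matrix(res$nActivations, spec$ny,
                                       spec$nx, byrow = TRUE),
                 s2Time = res$s2Time, snapshots = res$snapshots,
                 snapshotTimes = res$snapshotTimes, spec = spec,
                 genotype = model$kind, duration = duration),
            class = "sheetResult")
}

#' Re-entry lifespan
#'
#' Time from S2 delivery to the last activation (upstroke) recorded
#' anywhere in the sheet; 0 when no node activates after S2.
#'
#' @param result a \code{sheetResult} (or a list with
#'   \code{lastActivation} and \code{s2Time}).
#' @return lifespan in seconds.
#' @export
reentryLifespan <- function(result) {
  la <- result$lastActivation
  s2 <- result$s2Time
  if (is.null(s2) || s2 < 0) return(0)
  post <- la[la > s2]
  if (!length(post)) return(0)
  (max(post) - s2) / 1000
}

#' Dominant frequency of a tissue-averaged signal
#'
#' Mean-removed, Hann-windowed periodogram (zero-padded to a frequency
#' resolution of at most \code{resHz}); returns the frequency of the
#' largest peak within \code{band}.
#'
#' @param signal numeric vector (e.g. whole-field mean membrane
#'   potential), uniformly sampled, covering at least 2 s.
#' @param fs sampling rate (Hz).
#' @param band frequency search band (Hz).
#' @param resHz maximum frequency-grid spacing (Hz).
#' @param highpassMs optional running-mean window (ms, assuming the
#'   sampling rate is in Hz and the signal in ms-spaced samples): the
#'   window's running mean is subtracted before the periodogram,
#'   suppressing the slow activity envelope of transient re-entrant
#'   episodes. \code{NULL} (default) removes the mean only.
#' @return dominant frequency (Hz).
#' @examples
#' t <- seq(0, 5, by = 1e-3)
#' dominantFrequency(sin(2 * pi * 3 * t), fs = 1000)  # 3 Hz
#' @export
dominantFrequency <- function(signal, fs, band = c(0.5, 20),
                              resHz = 0.2, highpassMs = NULL) {
  n <- length(signal)
  if (n / fs < 2) stop("signal must cover at least 2 seconds")
  x <- signal - mean(signal)
  if (!is.null(highpassMs)) {
    w <- max(3L, round(highpassMs * fs / 1000))
    if (w %% 2L == 0L) w <- w + 1L
    trend <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    x <- x - trend
    x[is.na(x)] <- 0
  }
  if (max(abs(x)) == 0) stop("constant signal: no spectral peak")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  x <- x * w
  nfft <- 2^ceiling(log2(max(n, ceiling(fs / resHz))))
  sp <- abs(fft(c(x, rep(0, nfft - n))))^2
  freq <- (seq_len(nfft) - 1) * fs / nfft
  sel <- freq > band[1L] & freq < band[2L]
  if (!any(sel)) stop("no frequencies inside the search band")
  freq[sel][which.max(sp[sel])]
}
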
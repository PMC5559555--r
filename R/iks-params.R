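#' @title IKs channel rate parameters
#' @description Container for the voltage-dependent transition-rate
#' coefficients of one IKs channel population. Each of the eight transition
#' classes (alpha, beta, gamma, delta between closed states; theta/eta for
#' channel opening; psi/omega between the two open states) follows a
#' single-exponential voltage dependence
#' \deqn{r(V) = a \exp(b V)}
#' with prefactor \eqn{a} (1/ms) and voltage sensitivity \eqn{b} (1/mV).
#'
#' @param genotype label, \code{"WT"} or \code{"V307L"}.
#' @param a named numeric vector of 8 positive prefactors (1/ms), names
#'   \code{alpha, beta, gamma, delta, theta, eta, psi, omega}.
#' @param b named numeric vector of 8 voltage sensitivities (1/mV), same
#'   names.
#' @param gks maximal conductance (nS/pF), non-negative.
#' @param scale dimensionless relative-amplitude multiplier (from the
#'   AP-clamp peak-current ratio), positive.
#' @return object of class \code{iksParams}.
#' @examples
#' p <- iksParams("WT")
#' p$a["alpha"]
#' @export
iksParams <- function(genotype = c("WT", "V307L"), a = NULL, b = NULL,
                      gks = NULL, scale = NULL) {
  genotype <- match.arg(genotype)
  preset <- .iksPresets[[genotype]]
  if (is.null(a)) a <- preset$a
  if (is.null(b)) b <- preset$b
  if (is.null(gks)) gks <- preset$gks
  if (is.null(scale)) scale <- preset$scale
  a <- .asRateVec(a, "a")
  b <- .asRateVec(b, "b")
  obj <- structure(list(genotype = genotype, a = a, b = b,
                        gks = gks, scale = scale),
                   class = "iksParams")
  validateIksParams(obj)
  obj
}

.rateClasses <- c("alpha", "beta", "gamma", "delta",
                  "theta", "eta", "psi", "omega")

.asRateVec <- function(x, what) {
  if (length(x) != 8L)
    stop("'", what, "' must have 8 entries (one per transition class)")
  if (!is.null(names(x)) && all(.rateClasses %in% names(x)))
    x <- x[.rateClasses]
  x <- as.numeric(x)
  names(x) <- .rateClasses
  x
}

#' Validate IKs parameter invariants
#'
#' Checks positivity of the prefactors, non-negativity of the conductance,
#' positivity of the amplitude scale, and finiteness of every transition
#' rate over the physiological voltage range -120 to +80 mV.
#'
#' @param params an \code{iksParams} object.
#' @return invisibly \code{TRUE}; stops with a diagnostic otherwise.
#' @export
validateIksParams <- function(params) {
  stopifnot(inherits(params, "iksParams"))
  if (any(!is.finite(params$a)) || any(params$a <= 0))
    stop("all rate prefactors must be positive and finite")
  if (any(!is.finite(params$b)))
    stop("all voltage sensitivities must be finite")
  if (!is.finite(params$gks) || params$gks < 0)
    stop("gks must be non-negative")
  if (!is.finite(params$scale) || params$scale <= 0)
    stop("scale factor must be positive")
  for (V in c(-120, 80)) {
    r <- params$a * exp(params$b * V)
    if (any(!is.finite(r)))
      stop("transition rates not finite at V = ", V, " mV")
  }
  invisible(TRUE)
}

#' @export
print.iksParams <- function(x, ...) {
  cat("IKs Markov-chain rate parameters [", x$genotype, "]\n", sep = "")
  tab <- rbind(prefactor = x$a, sensitivity = x$b)
  print(signif(tab, 4))
  cat("gks =", signif(x$gks, 4), "nS/pF, amplitude scale =",
      signif(x$scale, 4), "\n")
  invisible(x)
}

#' Construct a genotype channel model
#'
#' A genotype model couples one (homozygote) or two (heterozygote) IKs
#' channel populations to a shared membrane potential. The heterozygote is
#' the 50:50 mixture of wild-type and V307L populations: each population
#' evolves under its own transition rates, and the total current is the
#' equally-weighted sum of the two population currents at full conductance.
#'
#' @param kind \code{"WT"}, \code{"WT-V307L"} (heterozygote) or
#'   \code{"V307L"}.
#' @param params optional list of \code{iksParams} (length 1, or 2 for the
#'   heterozygote); defaults to the fitted genotype presets.
#' @param gks optional conductance override (nS/pF).
#' @param block fraction of IKs conductance removed, in [0, 1]
#'   (pharmacological block as pure conductance scaling).
#' @return object of class \code{genotypeModel}.
#' @examples
#' m <- genotypeModel("WT-V307L")
#' length(m$pops)
#' @export
genotypeModel <- function(kind = c("WT", "WT-V307L", "V307L"),
                          params = NULL, gks = NULL, block = 0) {
  kind <- match.arg(kind)
  if (is.null(params)) {
    params <- switch(kind,
      "WT" = list(iksParams("WT")),
      "V307L" = list(iksParams("V307L")),
      "WT-V307L" = list(iksParams("WT"), iksParams("V307L")))
  }
  if (!is.list(params) || !all(vapply(params, inherits, TRUE, "iksParams")))
    stop("'params' must be a list of iksParams objects")
  npop <- if (kind == "WT-V307L") 2L else 1L
  if (length(params) != npop)
    stop("genotype '", kind, "' needs ", npop, " channel population(s)")
  w <- if (npop == 2L) c(0.5, 0.5) else 1
  if (is.null(gks)) gks <- params[[1L]]$gks
  if (block < 0 || block > 1) stop("block fraction must lie in [0, 1]")
  structure(list(kind = kind, pops = params, weights = w,
                 gks = gks, block = block),
            class = "genotypeModel")
}

#' @export
print.genotypeModel <- function(x, ...) {
  cat("IKs genotype model:", x$kind, "\n")
  cat("  populations:", length(x$pops),
      paste0("(weights ", paste(x$weights, collapse = "/"), ")"), "\n")
  cat("  gks =", signif(x$gks, 4), "nS/pF")
  if (x$block > 0) cat(",", round(100 * x$block), "% conductance block")
  cat("\n")
  invisible(x)
}

# translate a genotypeModel to the C++ argument list
.genoToC <- function(model) {
  stopifnot(inherits(model, "genotypeModel"))
  npop <- length(model$pops)
  list(npop = as.integer(npop),
       a = vapply(model$pops, function(p) p$a, numeric(8)),
       b = vapply(model$pops, function(p) p$b, numeric(8)),
       scale = vapply(model$pops, function(p) p$scale, numeric(1)),
       w = as.numeric(model$weights),
       gks = as.numeric(model$gks),
       block = as.numeric(model$block))
}

# native host-model IKs (Hodgkin-Huxley xs^2), used for the AP-clamp
# command waveform and host-model validation
.genoNative <- function(block = 0) {
  list(npop = 0L, gks = 0, block = as.numeric(block))
}

#' Read IKs parameters from a flat key-value text file
#'
#' File format: one \code{key = value} pair per line; keys are
#' \code{genotype}, \code{gks}, \code{scale}, and \code{a_<class>} /
#' \code{b_<class>} for the eight transition classes. Lines starting with
#' \code{#} are ignored.
#'
#' @param path file path.
#' @return an \code{iksParams} object.
#' @export
readIksParams <- function(path) {
  kv <- readKeyValue(path)
  a <- vapply(.rateClasses, function(k) as.numeric(kv[[paste0("a_", k)]]),
              numeric(1))
  b <- vapply(.rateClasses, function(k) as.numeric(kv[[paste0("b_", k)]]),
              numeric(1))
  iksParams(genotype = kv$genotype, a = a, b = b,
            gks = as.numeric(kv$gks), scale = as.numeric(kv$scale))
}

#' Write IKs parameters to a flat key-value text file
#' @param params an \code{iksParams} object.
#' @param path file path.
#' @return invisibly \code{path}.
#' @export
writeIksParams <- function(params, path) {
  validateIksParams(params)
  lines <- c(paste("genotype =", params$genotype),
             paste("gks =", format(params$gks, digits = 17)),
             paste("scale =", format(params$scale, digits = 17)),
             paste0("a_", .rateClasses, " = ",
                    vapply(params$a, format, "", digits = 17)),
             paste0("b_", .rateClasses, " = ",
                    vapply(params$b, format, "", digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a channel-state occupancy snapshot as CSV
#'
#' Columns are labelled C1..C15, O1, O2.
#' @param occupancy numeric vector of length 17 (or matrix with 17 columns,
#'   one row per snapshot).
#' @param path file path.
#' @return invisibly \code{path}.
#' @export
writeChannelState <- function(occupancy, path) {
  m <- if (is.matrix(occupancy)) occupancy else matrix(occupancy, nrow = 1)
  if (ncol(m) != 17L) stop("occupancy must have 17 entries per snapshot")
  colnames(m) <- c(paste0("C", 1:15), "O1", "O2")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
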
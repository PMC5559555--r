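#' Build the 17-state IKs generator matrix at a fixed voltage
#'
#' The Markov scheme has 15 closed states and two open states. Each of the
#' four channel subunits undergoes two sequential voltage-sensor
#' transitions (resting -> intermediate at rate alpha, back at beta;
#' intermediate -> activated at gamma, back at delta); with all four
#' sensors activated the channel opens (C15 -> O1 at theta, back at eta)
#' and the open channel interconverts between two open states
#' (O1 <-> O2 at psi/omega). The generator \eqn{Q} satisfies
#' \eqn{dp/dt = Q p} with columns summing to zero (probability
#' conservation by construction).
#'
#' @param V membrane potential (mV), finite.
#' @param params an \code{iksParams} object.
#' @return 17 x 17 rate matrix (1/ms), states ordered C1..C15, O1, O2.
#' @examples
#' Q <- buildGenerator(-40, iksParams("WT"))
#' max(abs(colSums(Q)))  # 0 up to roundoff
#' @export
buildGenerator <- function(V, params) {
  validateIksParams(params)
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("membrane potential must be a single finite number (got ",
         deparse(substitute(V)), ")")
  Q <- mcGeneratorCpp(V, params$a, params$b)
  dimnames(Q) <- list(.mcStateNames(), .mcStateNames())
  Q
}

.mcStateNames <- function() c(paste0("C", 1:15), "O1", "O2")

#' Steady-state channel occupancy at a fixed voltage
#'
#' Solves for the probability-normalised null vector of the generator:
#' the equilibrium occupancy the channel population relaxes to when held
#' at \code{V} indefinitely (e.g. the -80 mV holding potential of the
#' voltage-clamp protocol).
#'
#' @inheritParams buildGenerator
#' @return named numeric vector of 17 non-negative occupancies summing
#'   to 1.
#' @examples
#' p <- steadyStateOccupancy(-80, iksParams("WT"))
#' sum(p)
#' unname(p["O1"] + p["O2"])  # negligible resting open probability
#' @export
steadyStateOccupancy <- function(V, params) {
  validateIksParams(params)
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("membrane potential must be a single finite number")
  p <- as.numeric(mcSteadyStateCpp(V, params$a, params$b))
  names(p) <- .mcStateNames()
  p
}

#' Advance a channel occupancy vector in time at fixed voltage
#'
#' Integrates \eqn{dp/dt = Q(V) p} over \code{dt} milliseconds with
#' adaptive sub-stepping (classical RK4, maximum sub-step
#' \code{maxSub} ms), followed by non-negativity clamping and
#' renormalisation. For fixed \code{V} the result converges to
#' \code{steadyStateOccupancy(V, params)} as \code{dt} grows.
#'
#' @param occupancy numeric vector of length 17, a valid probability
#'   vector.
#' @param V membrane potential (mV).
#' @param dt time step (ms), positive (0 returns the input unchanged).
#' @param params an \code{iksParams} object.
#' @param maxSub maximum sub-step (ms); default 0.02.
#' @return occupancy vector after \code{dt} ms.
#' @export
advanceChannel <- function(occupancy, V, dt, params, maxSub = 0.02) {
  validateIksParams(params)
  occupancy <- validateChannelState(occupancy)
  if (dt < 0) stop("dt must be non-negative")
  p <- mcAdvanceCpp(occupancy, V, dt, params$a, params$b, maxSub)
  if (abs(sum(p) - 1) > 1e-8)
    stop("integration-step failure: occupancy drift beyond 1e-8")
  names(p) <- .mcStateNames()
  p
}

#' Validate a channel occupancy vector
#' @param occupancy numeric vector of length 17.
#' @param tol tolerance on the probability sum (default 1e-8).
#' @return the occupancy vector, invisibly validated.
#' @export
validateChannelState <- function(occupancy, tol = 1e-8) {
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != 17L)
    stop("channel state must have 17 occupancies (C1..C15, O1, O2)")
  if (any(occupancy < -tol) || any(occupancy > 1 + tol))
    stop("occupancies must lie in [0, 1]")
  if (abs(sum(occupancy) - 1) > tol)
    stop("occupancies must sum to 1 (within ", tol, ")")
  occupancy
}

#' Open probability of a channel state
#' @param occupancy numeric vector of length 17.
#' @return O1 + O2.
#' @export
openProbability <- function(occupancy) {
  occupancy <- validateChannelState(occupancy)
  occupancy[16L] + occupancy[17L]
}

#' IKs current density of a genotype model
#'
#' Ohmic current law \eqn{I = g_{Ks} (1 - block) \sum_p w_p s_p
#' (O1_p + O2_p) (V - E_{Ks})} with population weights \eqn{w_p}
#' (0.5/0.5 for the heterozygote) and relative-amplitude scales
#' \eqn{s_p}. The heterozygote current is therefore exactly the 50:50
#' average of the two population currents, each at full conductance.
#'
#' @param model a \code{genotypeModel}.
#' @param occupancies list of occupancy vectors, one per population.
#' @param V membrane potential (mV).
#' @param eks IKs reversal potential (mV).
#' @return current density (pA/pF).
#' @export
iksCurrent <- function(model, occupancies, V, eks) {
  stopifnot(inherits(model, "genotypeModel"))
  if (!is.list(occupancies)) occupancies <- list(occupancies)
  if (length(occupancies) != length(model$pops))
    stop("need one occupancy vector per channel population")
  open <- 0
  for (p in seq_along(model$pops)) {
    occ <- validateChannelState(occupancies[[p]])
    open <- open + model$weights[p] * model$pops[[p]]$scale *
      (occ[16L] + occ[17L])
  }
  model$gks * (1 - model$block) * open * (V - eks)
}
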
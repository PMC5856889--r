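#' Chemical reaction system with initial configuration
#'
#' A \code{ReactionNetwork} holds a finite species set, a list of uni- or
#' bi-molecular reactions (reactant and product count vectors plus a positive
#' rate coefficient), an initial configuration of molecule counts and the
#' volumetric factor \eqn{N} that links counts \eqn{x} to concentrations
#' \eqn{z = x/N}.  The net change of a reaction is always derived as
#' \eqn{\upsilon = p - r}, never stored.  Optional scheduled injections
#' (reactions added to the network at a given time, used to emulate signal
#' changes while a circuit is running) are kept in the \code{injections} slot
#' and honoured by all three simulation engines.
#'
#' Species order is first-appearance order and fixes every vector layout:
#' ODE state, SSA reaction scan order, trajectory and CSV column order.
#'
#' @slot species character vector of species names (unique, ordered).
#' @slot reactants,products integer matrices, one row per reaction, one
#'   column per species; row sums of \code{reactants} must be 1 or 2.
#' @slot rates positive numeric vector of rate coefficients, one per reaction.
#' @slot x0 non-negative numeric vector of initial molecule counts.
#' @slot N positive scalar volumetric factor.
#' @slot injections list of scheduled network extensions, each a list with
#'   elements \code{time}, \code{reactants}, \code{products}, \code{rates}.
#'
#' @seealso [parseCRN()], [simulateODE()], [simulateSSA()], [simulateLNA()]
#' @export
setClass("ReactionNetwork",
         slots = c(species = "character",
                   reactants = "matrix",
                   products = "matrix",
                   rates = "numeric",
                   x0 = "numeric",
                   N = "numeric",
                   injections = "list"),
         prototype = prototype(injections = list()))

setValidity("ReactionNetwork", function(object) {
  msg <- character(0)
  S <- length(object@species)
  R <- nrow(object@reactants)
  if (anyDuplicated(object@species))
    msg <- c(msg, "species names must be unique")
  if (ncol(object@reactants) != S || ncol(object@products) != S)
    msg <- c(msg, "reactant/product matrices must have one column per species")
  if (nrow(object@products) != R || length(object@rates) != R)
    msg <- c(msg, "reactants, products and rates must agree in length")
  if (R > 0) {
    if (any(object@reactants < 0) || any(object@products < 0))
      msg <- c(msg, "stoichiometric counts must be non-negative")
    ra <- rowSums(object@reactants)
    if (any(ra < 1 | ra > 2))
      msg <- c(msg, "only uni- and bi-molecular reactions are supported")
    if (any(object@rates <= 0))
      msg <- c(msg, "rate coefficients must be positive")
  }
  if (length(object@x0) != S || any(object@x0 < 0))
    msg <- c(msg, "x0 must be a non-negative vector with one entry per species")
  if (length(object@N) != 1 || object@N <= 0)
    msg <- c(msg, "N must be a positive scalar")
  for (ev in object@injections) {
    if (ev$time < 0) msg <- c(msg, "injection times must be non-negative")
    if (ncol(ev$reactants) != S)
      msg <- c(msg, "injection reactions must be defined over the same species")
  }
  if (length(msg)) msg else TRUE
})

#' Dual-rail circuit
#'
#' A [ReactionNetwork-class] together with its declared Boolean interface:
#' input and output signals, each represented by a rail pair
#' \code{<name>_hi} / \code{<name>_lo}, and a signal amplitude
#' \code{railMax} (the number of molecules representing a full rail, 10
#' throughout the shipped components).  All remaining species are internal
#' (conventionally named with a \code{lambda} prefix) and are assumed not to
#' catalyse anything outside the circuit.
#'
#' @slot inputs,outputs character vectors of signal base names.
#' @slot railMax numeric scalar, molecules on a fully asserted rail.
#' @slot contract optional list describing the component's behavioural
#'   contract (a truth table for combinational gates, empty otherwise).
#' @export
setClass("DualRailCircuit",
         contains = "ReactionNetwork",
         slots = c(inputs = "character",
                   outputs = "character",
                   railMax = "numeric",
                   contract = "list"),
         prototype = prototype(contract = list()))

setValidity("DualRailCircuit", function(object) {
  msg <- character(0)
  railSpecies <- function(base) paste0(rep(base, each = 2), c("_hi", "_lo"))
  need <- railSpecies(c(object@inputs, object@outputs))
  missing <- setdiff(need, object@species)
  if (length(missing))
    msg <- c(msg, paste("rail species not declared in the network:",
                        paste(missing, collapse = ", ")))
  if (length(object@railMax) != 1 || object@railMax <= 0)
    msg <- c(msg, "railMax must be a positive scalar")
  if (length(intersect(object@inputs, object@outputs)))
    msg <- c(msg, "a signal cannot be both input and output")
  if (length(msg)) msg else TRUE
})

## ---- trajectory containers ----

#' Virtual base class for simulated trajectories
#'
#' Slot \code{values} is a matrix with one row per time point and one column
#' per species (counts for SSA, count-scale concentrations for the continuous
#' engines; the two coincide at N = 1).
#' @export
setClass("Trajectory",
         representation("VIRTUAL",
                        times = "numeric",
                        values = "matrix"))

#' Deterministic (ODE) trajectory. @export
setClass("OdeTrajectory", contains = "Trajectory")

#' A single exact SSA sample path
#'
#' \code{times} are the jump times (starting at 0) and \code{values} the
#' integer configurations reached after each jump; the path is piecewise
#' constant from the left.  \code{seed} reproduces the path bit-exactly.
#' @export
setClass("SsaPath", contains = "Trajectory",
         slots = c(seed = "integer"))

#' Linear noise approximation trajectory
#'
#' \code{values} holds the mean \eqn{E[Y(t)] = N \Phi(t)}, \code{sd} the
#' per-species standard deviation and \code{cov} the full covariance
#' \eqn{C[Y(t)] = N C[Z(t)]} as an array of dimension (time, species,
#' species).
#' @export
setClass("LnaTrajectory", contains = "Trajectory",
         slots = c(sd = "matrix", cov = "array"))

#' Pointwise empirical mean over SSA paths (with standard errors)
#' @export
setClass("MeanTrajectory", contains = "Trajectory",
         slots = c(se = "matrix", nPaths = "integer", seed = "integer"))

#' Dual-rail correctness thresholds
#'
#' A rail is read as high when its mean exceeds
#' \code{hiFraction * railMax - sdMultiplier * SD} and as low when the mean is
#' below \code{loFraction * railMax + sdMultiplier * SD}; the standard
#' deviation is taken from the trajectory (zero under the deterministic and
#' SSA semantics, the Gaussian SD under the LNA).
#'
#' @export
setClass("ThresholdPolicy",
         slots = c(hiFraction = "numeric",
                   loFraction = "numeric",
                   sdMultiplier = "numeric",
                   railMax = "numeric"))

setValidity("ThresholdPolicy", function(object) {
  if (object@loFraction <= 0 || object@hiFraction >= 1 ||
      object@loFraction >= object@hiFraction)
    "need 0 < loFraction < hiFraction < 1"
  else TRUE
})
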
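## Dual-rail threshold logic, first-passage measurement and truth-table
## sweeps.

#' Construct a threshold policy
#'
#' A high rail is read as correct when its mean exceeds
#' \code{hiFraction * railMax - sdMultiplier * SD}, a low rail when its mean
#' is below \code{loFraction * railMax + sdMultiplier * SD}.  The standard
#' deviation is the trajectory's own (zero under deterministic and single
#' SSA semantics, the Gaussian SD under the LNA).  \code{railMax} is the
#' circuit's signal amplitude -- at the default amplitude of 10 molecules
#' the high threshold is the familiar 8 molecules.
#'
#' @param hiFraction,loFraction normalised thresholds (defaults 0.8, 0.2)
#' @param sdMultiplier how many standard deviations widen the read (1)
#' @param railMax signal amplitude in molecules (10)
#' @return a [ThresholdPolicy-class]
#' @export
thresholdPolicy <- function(hiFraction = 0.8, loFraction = 0.2,
                            sdMultiplier = 1, railMax = 10) {
  new("ThresholdPolicy", hiFraction = hiFraction, loFraction = loFraction,
      sdMultiplier = sdMultiplier, railMax = railMax)
}

#' Dual-rail threshold reads
#'
#' @param traj a [Trajectory-class]
#' @param species rail species name (e.g. \code{"Z_hi"})
#' @param t time at which to read
#' @param policy a [ThresholdPolicy-class]
#' @return logical
#' @export
isHigh <- function(traj, species, t, policy = thresholdPolicy()) {
  m <- speciesAt(traj, species, t)
  s <- sdAt(traj, species, t)
  m > policy@hiFraction * policy@railMax - policy@sdMultiplier * s
}

#' @rdname isHigh
#' @export
isLow <- function(traj, species, t, policy = thresholdPolicy()) {
  m <- speciesAt(traj, species, t)
  s <- sdAt(traj, species, t)
  m < policy@loFraction * policy@railMax + policy@sdMultiplier * s
}

#' Boolean value of a dual-rail signal
#'
#' Returns 1 when the hi rail reads high and the lo rail reads low, 0 for
#' the mirror image, and NA when neither holds -- including the case of both
#' rails high, which is a dual-rail exclusivity violation and is surfaced,
#' not masked.
#'
#' @param traj a [Trajectory-class]
#' @param signal signal base name (rails \code{<signal>_hi/_lo})
#' @inheritParams isHigh
#' @return 0, 1 or NA
#' @export
signalValue <- function(traj, signal, t, policy = thresholdPolicy()) {
  hi <- paste0(signal, "_hi"); lo <- paste0(signal, "_lo")
  up <- isHigh(traj, hi, t, policy) && isLow(traj, lo, t, policy)
  dn <- isHigh(traj, lo, t, policy) && isLow(traj, hi, t, policy)
  if (up && !dn) 1 else if (dn && !up) 0 else NA
}

#' Debounced first-passage time
#'
#' Earliest grid time at which the predicate \code{<species> <comparator>
#' <level>} holds and continues to hold until the end of the trajectory, so
#' transient crossings do not count.
#'
#' @param traj a [Trajectory-class]
#' @param species species name
#' @param level threshold level
#' @param comparator one of \code{">="}, \code{">"}, \code{"<="}, \code{"<"}
#' @return time, or NA if the predicate never latches
#' @export
firstPassage <- function(traj, species, level, comparator = ">=") {
  .checkSpecies(traj, species)
  v <- traj@values[, species]
  ok <- switch(comparator,
               ">=" = v >= level, ">" = v > level,
               "<=" = v <= level, "<" = v < level,
               stop("unknown comparator: ", comparator))
  ## holds from here to the horizon
  latched <- rev(cumprod(rev(ok))) > 0
  if (!any(latched)) return(NA_real_)
  traj@times[which(latched)[1]]
}

## component registry for truth-table sweeps: builder(x, y, state, M) plus
## expected-output function
.sweepComponents <- function() {
  gate2 <- function(kind) list(
    build = function(x, y, state, M) buildGate(kind, x = x, y = y, M = M),
    inputs = 2, stateful = FALSE, out = "Z",
    expected = function(x, y, state) gateTruthTable(kind)$z[1 + x + 2 * y])
  list(
    NOT = list(build = function(x, y, state, M) buildGate("NOT", x = x, M = M),
               inputs = 1, stateful = FALSE, out = "Y",
               expected = function(x, y, state) 1 - x),
    AND = gate2("AND"), OR = gate2("OR"), NAND = gate2("NAND"),
    NOR = gate2("NOR"), XOR = gate2("XOR"),
    C = list(build = function(x, y, state, M)
               buildCElement(x = x, y = y, output = state, M = M),
             inputs = 2, stateful = TRUE, out = "Z",
             expected = function(x, y, state)
               if (x == y) x else state),
    fork = list(build = function(x, y, state, M) buildFork(input = x, M = M),
                inputs = 1, stateful = FALSE, out = c("Y1", "Y2"),
                expected = function(x, y, state) x),
    join = list(build = function(x, y, state, M)
                  buildJoin(x1 = x, x2 = y, M = M),
                inputs = 2, stateful = FALSE, out = "Y",
                expected = function(x, y, state)
                  if (x == y) x else NA_real_),
    `latch-simple` = list(build = function(x, y, state, M)
                            buildLatch("simple", input = x, output = state,
                                       M = M),
                          inputs = 1, stateful = TRUE, out = "Y",
                          expected = function(x, y, state) x),
    `latch-reset` = list(build = function(x, y, state, M)
                           buildLatch("with_reset", input = x,
                                      output = state, M = M),
                         inputs = 1, stateful = TRUE, out = "Y",
                         expected = function(x, y, state) x))
}

#' Truth-table sweep of a component
#'
#' Systematically simulates a component for every Boolean input assignment
#' (and, for stateful components, every initial output state), reads the
#' output signals through the dual-rail thresholds at the horizon, and
#' compares with the component's behavioural contract.
#'
#' Under \code{semantics = "ode"} one deterministic run per row is
#' performed and \code{pass} requires the observed value to equal the
#' expected one.  Under \code{"ssa"}, \code{nPaths} seeded stochastic paths
#' are run per row; \code{successRate} is the fraction of paths giving the
#' expected reading and \code{pass} requires at least 95 per cent.
#'
#' @param component one of NOT, AND, OR, NAND, NOR, XOR, C, fork, join,
#'   latch-simple, latch-reset
#' @param horizon simulation horizon (default 5 s)
#' @param semantics \code{"ode"} or \code{"ssa"}
#' @param policy a [ThresholdPolicy-class] (defaults to the component's
#'   amplitude)
#' @param nPaths SSA paths per assignment
#' @param seed master seed for SSA sweeps
#' @param M signal amplitude
#' @return data.frame with one row per assignment: inputs, initial state
#'   (for stateful components), expected, observed, successRate (SSA),
#'   pass
#' @export
sweepTruthTable <- function(component, horizon = 5,
                            semantics = c("ode", "ssa"), policy = NULL,
                            nPaths = 20L, seed = 1L, M = 10) {
  semantics <- match.arg(semantics)
  comp <- .sweepComponents()[[component]]
  if (is.null(comp)) stop("unknown component: ", component)
  if (is.null(policy)) policy <- thresholdPolicy(railMax = M)
  xs <- c(0, 1)
  ys <- if (comp$inputs == 2) c(0, 1) else NA
  states <- if (comp$stateful) c(0, 1) else NA
  grid <- expand.grid(x = xs, y = ys, state = states)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; yv <- grid$y[i]; st <- grid$state[i]
    circ <- comp$build(x, yv, st, M)
    expected <- comp$expected(x, yv, st)
    readOut <- function(traj) {
      vals <- unname(vapply(comp$out, function(o)
        signalValue(traj, o, horizon, policy), numeric(1)))
      if (length(unique(vals)) == 1) vals[1] else NA_real_
    }
    same <- function(a, b)
      (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
    if (semantics == "ode") {
      obs <- readOut(simulateODE(circ, horizon))
      rate <- NA_real_
      pass <- same(obs, expected)
    } else {
      vals <- vapply(seq_len(nPaths), function(k)
        readOut(simulateSSA(circ, horizon,
                            seed = seed + 1000L * i + k)), numeric(1))
      hits <- if (is.na(expected)) is.na(vals) else
        !is.na(vals) & vals == expected
      rate <- mean(hits)
      obs <- if (rate >= 0.5) expected else NA_real_
      pass <- rate >= 0.95
    }
    rows[[i]] <- data.frame(x = x, y = yv, state = st,
                            expected = expected, observed = obs,
                            successRate = rate, pass = pass)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
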
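## Builders for the basic circuit components.  Every reaction is a 2-reactant
## / 2-product catalytic conversion, so the total molecule count -- and the
## total of each signal group (rail pair plus its shared intermediaries) --
## is invariant under all three semantics.
##
## Design vocabulary used below:
##   attack   cat + R_other -> cat + lambda   (demote the opposing rail)
##   amplify  cat + lambda  -> cat + R_own    (promote the own rail)
## The Approximate-Majority output stage uses both on its own rails, which
## makes the committed rail self-reinforcing and the network bistable.

.cat <- function(cat, from, to) sprintf("%s + %s -> %s + %s", cat, from, cat, to)

## init statements double as species declarations (zero counts included),
## so rails that no reaction touches still exist and declaration order is
## deterministic
.initLines <- function(counts) {
  counts <- counts[!duplicated(names(counts), fromLast = TRUE)]
  sprintf("init %s %d", names(counts), as.integer(counts))
}

.mkCircuit <- function(lines, inits, inputs, outputs, M, contract = list()) {
  net <- parseCRN(paste(c(.initLines(inits), lines), collapse = "\n"))
  dualRailCircuit(net, inputs = inputs, outputs = outputs, railMax = M,
                  contract = contract)
}

## initial counts for a rail pair given a Boolean (or NA) value
.railInit <- function(base, value, M) {
  if (is.na(value)) return(setNames(c(0, 0), paste0(base, c("_hi", "_lo"))))
  setNames(if (value == 1) c(M, 0) else c(0, M), paste0(base, c("_hi", "_lo")))
}

#' The two-reaction dual-rail motif
#'
#' \code{X_hi} catalyses \code{Y_lo -> Y_hi} and \code{X_lo} catalyses
#' \code{Y_hi -> Y_lo}: the output copies the Boolean value of the input.
#' This conversion motif is the unit out of which all other components are
#' built.
#'
#' @param input initial input value (0, 1 or NA for absent; default NA)
#' @param output initial output value (default 0)
#' @param M signal amplitude in molecules (default 10)
#' @return a [DualRailCircuit-class]
#' @examples
#' m <- buildMotif(input = 1)
#' traj <- simulateODE(m, 1)
#' speciesAt(traj, "Y_hi", 0.4)   # ~10: the input value has been copied
#' @export
buildMotif <- function(input = NA, output = 0, M = 10) {
  .mkCircuit(c(.cat("X_hi", "Y_lo", "Y_hi"),
               .cat("X_lo", "Y_hi", "Y_lo")),
             c(.railInit("X", input, M), .railInit("Y", output, M)),
             inputs = "X", outputs = "Y", M = M)
}

#' The single-rail Approximate Majority network
#'
#' The classic 3-species, 4-reaction bi-molecular consensus network: the two
#' populations X and Y convert each other into the undecided intermediary
#' \code{lambda}, which either population recruits to its side.  The
#' majority population drives the minority to extinction.
#'
#' @param X,Y,lambda initial molecule counts
#' @return a [ReactionNetwork-class]
#' @export
buildAM <- function(X = 0, Y = 0, lambda = 0) {
  parseCRN(paste(c(.initLines(c(X = X, Y = Y, lambda = lambda)),
                   .cat("X", "Y", "lambda"),
                   .cat("Y", "X", "lambda"),
                   .cat("X", "lambda", "X"),
                   .cat("Y", "lambda", "Y")), collapse = "\n"))
}

## the dual-rail AM core: input pair X attacks the opposing output rail,
## input pair Y amplifies the matching output rail, and the output rails do
## both (self-reinforcement).  Returned as text so larger circuits can embed
## it under renamed ports.
.dualRailAmLines <- function(xBase, yBase, zBase, lambda) {
  zh <- paste0(zBase, "_hi"); zl <- paste0(zBase, "_lo")
  c(.cat(paste0(xBase, "_hi"), zl, lambda),
    .cat(zh, zl, lambda),
    .cat(paste0(xBase, "_lo"), zh, lambda),
    .cat(zl, zh, lambda),
    .cat(paste0(yBase, "_hi"), lambda, zh),
    .cat(zh, lambda, zh),
    .cat(paste0(yBase, "_lo"), lambda, zl),
    .cat(zl, lambda, zl))
}

## arbiter / amplifier stage: a single input pair does both attack and
## amplification, output self-reinforcing
.arbiterLines <- function(xBase, yBase, lambda) {
  xh <- paste0(xBase, "_hi"); xl <- paste0(xBase, "_lo")
  yh <- paste0(yBase, "_hi"); yl <- paste0(yBase, "_lo")
  c(.cat(xh, yl, lambda), .cat(yh, yl, lambda),
    .cat(xh, lambda, yh), .cat(yh, lambda, yh),
    .cat(xl, yh, lambda), .cat(yl, yh, lambda),
    .cat(xl, lambda, yl), .cat(yl, lambda, yl))
}

## initial counts for an AM output group: value 1 / 0 / "lambda" (neutral)
.amGroupInit <- function(zBase, lambda, value, M) {
  counts <- setNames(c(0, 0, 0), c(paste0(zBase, c("_hi", "_lo")), lambda))
  if (identical(value, "lambda")) counts[lambda] <- M
  else if (!is.na(value)) counts[paste0(zBase, if (value == 1) "_hi" else "_lo")] <- M
  counts
}

#' Dual-rail Approximate Majority circuit
#'
#' Four input rails (signals X and Y) drive one output pair Z through the
#' undecided intermediary \code{lambda}: the X rails convert the opposing Z
#' rail into \code{lambda}, the Y rails convert \code{lambda} into the
#' matching Z rail, and the Z rails do both, enlarging whichever output
#' population currently holds the majority.  On agreeing inputs the output
#' converges to the input value; on conflicting inputs the committed output
#' rail is only partially degraded (it settles at
#' \eqn{(\sqrt{500}-10)/2 \approx 6.2} of 10 molecules, with the remainder
#' undecided), which is why a single AM stage fails the Muller C-element
#' specification and a second, amplifying stage is required (see
#' [buildCElement()]).
#'
#' @param x,y initial input values (0, 1 or NA)
#' @param output initial output state: 0, 1, NA (empty) or \code{"lambda"}
#'   (all molecules undecided)
#' @param M signal amplitude
#' @return a [DualRailCircuit-class]
#' @export
buildDualRailAM <- function(x = NA, y = NA, output = "lambda", M = 10) {
  .mkCircuit(.dualRailAmLines("X", "Y", "Z", "lambda"),
             c(.railInit("X", x, M), .railInit("Y", y, M),
               .amGroupInit("Z", "lambda", output, M)),
             inputs = c("X", "Y"), outputs = "Z", M = M)
}

#' Arbiter
#'
#' An Approximate Majority stage with a single input pair: whichever input
#' rail arrives first (or has the larger population) recruits the undecided
#' output pool \code{lambda} to the corresponding output rail, which then
#' reinforces itself to the full amplitude.
#'
#' @param input initial input value (0, 1, NA); partial inputs can be set
#'   afterwards with [setSignal()]
#' @param output initial output state (default \code{"lambda"}: the neutral
#'   undecided pool, full)
#' @inheritParams buildDualRailAM
#' @return a [DualRailCircuit-class]
#' @export
buildArbiter <- function(input = NA, output = "lambda", M = 10) {
  .mkCircuit(.arbiterLines("X", "Y", "lambda"),
             c(.railInit("X", input, M),
               .amGroupInit("Y", "lambda", output, M)),
             inputs = "X", outputs = "Y", M = M)
}

#' Muller C-element
#'
#' Two Approximate Majority circuits in series: the first AM (inputs X, Y,
#' internal output pair held on the wired \code{lambda.w1} rails) computes
#' the consensus of the inputs, and the second, arbiter-style AM amplifies
#' that outcome onto the output Z -- restoring full amplitude and
#' suppressing the residual undecided species that makes the single-stage AM
#' violate the C-element contract on conflicting inputs.
#'
#' The first stage's rail group is initialized consistently with the
#' declared output state (it mirrors Z), i.e. the element remembers its last
#' committed value; \code{output = "lambda"} gives the fully neutral element
#' that has not yet committed either way.
#'
#' Contract (all checked under ODE semantics in the validation layer): both
#' inputs high -> output high; both low -> output low; conflicting inputs ->
#' output unchanged for the whole horizon.
#'
#' @inheritParams buildDualRailAM
#' @return a [DualRailCircuit-class]
#' @export
buildCElement <- function(x = NA, y = NA, output = "lambda", M = 10) {
  am <- buildDualRailAM(M = M)
  am <- renameSpecies(am, c(lambda = "lambda1", Z = "W"))
  arb <- buildArbiter(M = M)
  arb <- renameSpecies(arb, c(lambda = "lambda2", X = "W", Y = "Z"))
  ce <- composeSeries(am, arb, wiring = c(W = "W"))
  initialCounts(ce) <- c(.railInit("X", x, M), .railInit("Y", y, M),
                         .amGroupInit("Z", "lambda2", output, M),
                         .amGroupInit("lambda.w1", "lambda1", output, M))
  ce
}

#' Latches
#'
#' Two state-holding elements.  The \emph{simple} latch is the motif plus
#' two feedback reactions in which each output rail catalyses the conversion
#' of the other into itself; deterministically the feedback terms cancel,
#' but stochastically they make the committed state self-stabilising when
#' the input is withdrawn.  The \emph{with_reset} latch is
#' Approximate-Majority shaped around a central undecided state
#' \code{lambda}: the input attacks the opposing rail and recruits
#' \code{lambda}, the output rails reinforce themselves, and a reset rail
#' \code{R_hi} drains both output rails back into \code{lambda}, leaving the
#' latch holding neither value -- useful when the outputs catalyse further
#' components that must not fire.
#'
#' @param kind \code{"simple"} or \code{"with_reset"}
#' @param input,output,reset initial values (0, 1, NA; \code{output} also
#'   accepts \code{"lambda"} for the neutral state of the reset latch)
#' @param M signal amplitude
#' @return a [DualRailCircuit-class]
#' @export
buildLatch <- function(kind = c("simple", "with_reset"),
                       input = NA, output = 0, reset = NA, M = 10) {
  kind <- match.arg(kind)
  if (kind == "simple") {
    if (identical(output, "lambda"))
      stop("the simple latch has no neutral state")
    .mkCircuit(c(.cat("X_hi", "Y_lo", "Y_hi"),
                 .cat("X_lo", "Y_hi", "Y_lo"),
                 .cat("Y_hi", "Y_lo", "Y_hi"),
                 .cat("Y_lo", "Y_hi", "Y_lo")),
               c(.railInit("X", input, M), .railInit("Y", output, M)),
               inputs = "X", outputs = "Y", M = M)
  } else {
    .mkCircuit(c(.arbiterLines("X", "Y", "lambda"),
                 .cat("R_hi", "Y_hi", "lambda"),
                 .cat("R_hi", "Y_lo", "lambda")),
               c(.railInit("X", input, M), .railInit("R", reset, M),
                 .amGroupInit("Y", "lambda", output, M)),
               inputs = c("X", "R"), outputs = "Y", M = M)
  }
}

#' Fork (signal split)
#'
#' Two conversion motifs sharing the input rails: the input drives both
#' output pairs Y1 and Y2 identically.  Under deterministic semantics and
#' equal initial output rails the two branches are exactly equal at all
#' times -- the CRN analogue of an isochronous fork.
#'
#' @inheritParams buildMotif
#' @param outputs initial value of both output signals
#' @export
buildFork <- function(input = NA, outputs = 0, M = 10) {
  .mkCircuit(c(.cat("X_hi", "Y1_lo", "Y1_hi"), .cat("X_lo", "Y1_hi", "Y1_lo"),
               .cat("X_hi", "Y2_lo", "Y2_hi"), .cat("X_lo", "Y2_hi", "Y2_lo")),
             c(.railInit("X", input, M),
               .railInit("Y1", outputs, M), .railInit("Y2", outputs, M)),
             inputs = "X", outputs = c("Y1", "Y2"), M = M)
}

#' Join (signal synchronisation)
#'
#' Merges two input signals into one output that asserts a value only when
#' both inputs agree: each polarity is produced by a two-step chain that
#' needs both input catalysts in series, so a single input cannot raise the
#' output above threshold.  Disagreeing inputs leave the output undefined
#' (the synchroniser stalls), matching the join's role in asynchronous
#' design.
#'
#' @param x1,x2 initial input values
#' @param M signal amplitude
#' @export
buildJoin <- function(x1 = NA, x2 = NA, M = 10) {
  .mkCircuit(c(.cat("X2_hi", "lambda2", "lambda1"),
               .cat("X1_hi", "lambda1", "Y_hi"),
               .cat("X2_lo", "lambda4", "lambda3"),
               .cat("X1_lo", "lambda3", "Y_lo"),
               .cat("Y_hi", "Y_lo", "lambda4"),
               .cat("Y_lo", "Y_hi", "lambda2")),
             c(.railInit("X1", x1, M), .railInit("X2", x2, M),
               c(lambda2 = M, lambda4 = M)),
             inputs = c("X1", "X2"), outputs = "Y", M = M)
}

#' The lambda-sink example circuit
#'
#' Converts both output rails into the internal species \code{lambda}
#' (assuming some \code{lambda} is present to catalyse the conversion)
#' unless an input rail is present to convert \code{lambda} back into an
#' output.  With no \code{lambda} and no input the circuit deadlocks.
#'
#' @param input initial input value (0, 1 or NA)
#' @param Y_hi,Y_lo,lambda initial counts of the output rails and sink
#' @param M signal amplitude
#' @export
buildLambdaSink <- function(input = NA, Y_hi = 0, Y_lo = 0, lambda = 0,
                            M = 10) {
  .mkCircuit(c(.cat("X_hi", "lambda", "Y_hi"),
               .cat("X_lo", "lambda", "Y_lo"),
               .cat("lambda", "Y_hi", "lambda"),
               .cat("lambda", "Y_lo", "lambda")),
             c(.railInit("X", input, M),
               c(Y_hi = Y_hi, Y_lo = Y_lo, lambda = lambda)),
             inputs = "X", outputs = "Y", M = M)
}
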
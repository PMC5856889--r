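## Dual-rail Boolean gates.
##
## NOT is a crossed motif (pure wire inversion realised as reactions).  The
## four monotone gates share one template built from two production routes
## plus cross-suppression:
##
##   conjunctive route   c1: lambda2 -> lambda1,  c2: lambda1 -> P
##     (a two-step chain needing both catalysts; detects the one input
##      assignment that must flip the output to P)
##   disjunctive route   d1|d2: lambda3 -> Q
##     (either catalyst produces the complementary output Q)
##   suppression         P: Q -> lambda3,  Q: P -> lambda2
##     (the winning rail demotes the other back into its source pool, which
##      both enforces dual-rail exclusivity and refills the pools so the
##      gate is reusable when its inputs change)
##
## XOR cannot be expressed with one conjunctive and one disjunctive route;
## it detects all four input minterms with two-step chains drawn from a
## shared hi-source pool (lambda1, minterms 10 and 01) and a shared
## lo-source pool (lambda2, minterms 11 and 00).  Each minterm chain exists
## in both catalyst orders, which doubles its throughput and keeps the gate
## symmetric in its inputs.

.GATE_KINDS <- c("NOT", "AND", "OR", "NAND", "NOR", "XOR")

## two-route template: list(conj = c(c1, c2, P), disj = c(d1, d2, Q)) with
## rails written as <signal>_<polarity>
.gateRoutes <- function(kind) {
  switch(kind,
    AND  = list(conj = c("Y_hi", "X_hi", "Z_hi"),
                disj = c("X_lo", "Y_lo", "Z_lo")),
    OR   = list(conj = c("Y_lo", "X_lo", "Z_lo"),
                disj = c("X_hi", "Y_hi", "Z_hi")),
    NAND = list(conj = c("Y_hi", "X_hi", "Z_lo"),
                disj = c("X_lo", "Y_lo", "Z_hi")),
    NOR  = list(conj = c("Y_lo", "X_lo", "Z_hi"),
                disj = c("X_hi", "Y_hi", "Z_lo")))
}

## reaction lines + internal pool inits for a gate embedded under a prefix,
## with the port rails renamed; z0 is the initial Boolean output (NA = none)
.gateLines <- function(kind, xBase = "X", yBase = "Y", zBase = "Z",
                       prefix = "", z0 = 0, M = 10) {
  p <- function(nm) paste0(prefix, nm)
  port <- c(X_hi = paste0(xBase, "_hi"), X_lo = paste0(xBase, "_lo"),
            Y_hi = paste0(yBase, "_hi"), Y_lo = paste0(yBase, "_lo"),
            Z_hi = paste0(zBase, "_hi"), Z_lo = paste0(zBase, "_lo"))
  if (kind == "NOT") {
    lines <- c(.cat(port["X_hi"], port["Y_hi"], port["Y_lo"]),
               .cat(port["X_lo"], port["Y_lo"], port["Y_hi"]))
    ## NOT output rails are named with the y port; no internals
    return(list(lines = lines, inits = .railInit(yBase, z0, M)))
  }
  if (kind == "XOR") {
    lH <- p("lambda1"); lL <- p("lambda2")
    mu <- function(m, o) p(paste0("mu", m, o))
    flip <- function(r)
      if (grepl("_hi$", r)) sub("_hi$", "_lo", r) else sub("_lo$", "_hi", r)
    ## each chain is reversible through the complement of its second
    ## catalyst, so a half-fired minterm cannot strand the shared pool
    chain <- function(a, b, pool, m, target) c(
      .cat(port[a], pool, mu(m, "a")), .cat(port[b], mu(m, "a"), port[target]),
      .cat(port[flip(b)], mu(m, "a"), pool),
      .cat(port[b], pool, mu(m, "b")), .cat(port[a], mu(m, "b"), port[target]),
      .cat(port[flip(a)], mu(m, "b"), pool))
    lines <- c(chain("Y_hi", "X_hi", lL, "11", "Z_lo"),
               chain("Y_lo", "X_lo", lL, "00", "Z_lo"),
               chain("Y_lo", "X_hi", lH, "10", "Z_hi"),
               chain("Y_hi", "X_lo", lH, "01", "Z_hi"),
               .cat(port["Z_hi"], port["Z_lo"], lL),
               .cat(port["Z_lo"], port["Z_hi"], lH))
    inits <- c(.railInit(zBase, z0, M))
    hi0 <- if (!is.na(z0) && z0 == 1) M else 0
    lo0 <- if (!is.na(z0) && z0 == 0) M else 0
    inits[lH] <- M - hi0
    inits[lL] <- M - lo0
    return(list(lines = lines, inits = inits))
  }
  rt <- .gateRoutes(kind)
  l1 <- p("lambda1"); l2 <- p("lambda2"); l3 <- p("lambda3")
  P <- port[rt$conj[3]]; Q <- port[rt$disj[3]]
  flipRail <- function(r) {
    if (grepl("_hi$", r)) sub("_hi$", "_lo", r) else sub("_lo$", "_hi", r)
  }
  lines <- c(.cat(port[rt$conj[1]], l2, l1),
             .cat(port[rt$conj[2]], l1, P),
             ## a staged lambda1 without its second catalyst would be a
             ## stale vote; the complementary rail returns it to the pool
             .cat(port[flipRail(rt$conj[2])], l1, l2),
             .cat(port[rt$disj[1]], l3, Q),
             .cat(port[rt$disj[2]], l3, Q),
             .cat(P, Q, l3),
             .cat(Q, P, l2))
  inits <- .railInit(zBase, z0, M)
  P0 <- if (!is.na(z0)) unname(inits[P]) else 0
  Q0 <- if (!is.na(z0)) unname(inits[Q]) else 0
  inits[l2] <- M - P0
  inits[l3] <- M - Q0
  list(lines = lines, inits = inits)
}

#' Truth table of a gate kind
#' @param kind one of NOT, AND, OR, NAND, NOR, XOR
#' @return data.frame with columns x, y (NA for NOT) and z
#' @export
gateTruthTable <- function(kind) {
  kind <- match.arg(kind, .GATE_KINDS)
  if (kind == "NOT")
    return(data.frame(x = c(0, 1), y = NA, z = c(1, 0)))
  g <- expand.grid(x = c(0, 1), y = c(0, 1))
  g$z <- switch(kind,
                AND = g$x & g$y, OR = g$x | g$y,
                NAND = !(g$x & g$y), NOR = !(g$x | g$y),
                XOR = xor(g$x, g$y)) + 0
  g
}

#' Dual-rail logic gates
#'
#' Builds one of the six dual-rail gates over inputs X, Y (X only for NOT)
#' and output Z.  All gates account for both rails of every signal, obey
#' dual-rail exclusivity at convergence, and (except where noted for XOR's
#' source pools) respond to later input changes.  The behavioural contract
#' is the Boolean truth table, evaluated by thresholding the output rails at
#' convergence for every input assignment; [sweepTruthTable()] runs that
#' check.
#'
#' Internal pools: the monotone gates hold their output-producing source
#' pools \code{lambda2} (conjunctive route, via the staging species
#' \code{lambda1}) and \code{lambda3} (disjunctive route), sized so that
#' every conserved output group totals \code{M}.  XOR holds a hi-source and
#' a lo-source pool (\code{lambda1}, \code{lambda2}) of \code{M} molecules
#' each, drawn on by two-step minterm chains in both catalyst orders.
#'
#' @param kind one of \code{"NOT"}, \code{"AND"}, \code{"OR"},
#'   \code{"NAND"}, \code{"NOR"}, \code{"XOR"}
#' @param x,y initial input values (0, 1, NA); \code{y} ignored for NOT
#' @param output initial output value (0, 1 or NA); default 0 for the
#'   monotone gates and NA (neutral) for XOR, matching how the gates are
#'   exercised in the validation scenarios
#' @param M signal amplitude
#' @return a [DualRailCircuit-class] with the truth table attached as its
#'   contract
#' @examples
#' g <- buildGate("AND", x = 1, y = 1)
#' traj <- simulateODE(g, 3)
#' firstPassage(traj, "Z_hi", 8)   # ~0.7 s to reach the high threshold
#' @export
buildGate <- function(kind = .GATE_KINDS, x = NA, y = NA, output = NULL,
                      M = 10) {
  kind <- match.arg(kind)
  if (is.null(output)) output <- if (kind == "XOR") NA else 0
  contract <- list(truthTable = gateTruthTable(kind))
  if (kind == "NOT") {
    gl <- .gateLines("NOT", zBase = "Y", z0 = output, M = M)
    return(.mkCircuit(gl$lines, c(.railInit("X", x, M), gl$inits),
                      inputs = "X", outputs = "Y", M = M,
                      contract = contract))
  }
  gl <- .gateLines(kind, z0 = output, M = M)
  .mkCircuit(gl$lines,
             c(.railInit("X", x, M), .railInit("Y", y, M), gl$inits),
             inputs = c("X", "Y"), outputs = "Z", M = M,
             contract = contract)
}
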
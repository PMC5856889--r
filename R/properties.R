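## Time-bounded temporal properties over SSA paths, estimated by Monte
## Carlo -- the statistical analogue of the bounded-until queries run
## against the induced CTMC in a probabilistic model checker.  Atoms are
## threshold predicates over species; path formulas are evaluated on the
## exact jump path (no grid aliasing): the state is piecewise constant
## between jumps, so each formula is decided by scanning jump intervals.

#' Threshold atom of a temporal property
#' @param species species name
#' @param comparator one of \code{">"}, \code{">="}, \code{"<"}, \code{"<="}
#' @param level threshold (\code{Th}), user-settable; a common choice is
#'   the high threshold 0.8 * railMax
#' @return an object of class \code{crnAtom}
#' @export
propAtom <- function(species, comparator, level) {
  stopifnot(comparator %in% c(">", ">=", "<", "<="), level >= 0)
  structure(list(species = species, comparator = comparator, level = level),
            class = "crnAtom")
}

#' Time-bounded path formulas
#'
#' \code{boundedEventually(a, t1, t2)}: atom \code{a} holds at some time in
#' \code{[t1, t2]}.  \code{boundedUntil(a, b, t1, t2)}: atom \code{b} holds
#' at some time \eqn{t \in [t1, t2]} and atom \code{a} holds at every time
#' before \eqn{t}.  \code{boundedGlobally(a, t1, t2)}: atom \code{a} holds
#' throughout \code{[t1, t2]}.
#'
#' @param a,b [propAtom()] objects
#' @param t1,t2 time bounds, \code{0 <= t1 <= t2}
#' @return an object of class \code{crnProperty}
#' @export
boundedEventually <- function(a, t1, t2) {
  stopifnot(t1 <= t2)
  structure(list(form = "F", a = a, t1 = t1, t2 = t2),
            class = "crnProperty")
}

#' @rdname boundedEventually
#' @export
boundedUntil <- function(a, b, t1, t2) {
  stopifnot(t1 <= t2)
  if (t1 == t2)
    warning("vacuous bounded-until: t1 == t2")
  structure(list(form = "U", a = a, b = b, t1 = t1, t2 = t2),
            class = "crnProperty")
}

#' @rdname boundedEventually
#' @export
boundedGlobally <- function(a, t1, t2) {
  stopifnot(t1 <= t2)
  structure(list(form = "G", a = a, t1 = t1, t2 = t2),
            class = "crnProperty")
}

.atomOnStates <- function(atom, states) {
  v <- states[, atom$species]
  switch(atom$comparator,
         ">" = v > atom$level, ">=" = v >= atom$level,
         "<" = v < atom$level, "<=" = v <= atom$level)
}

## evaluate a path formula on one SSA jump path
.holdsOnPath <- function(prop, path, horizon) {
  s <- path@times
  e <- c(path@times[-1], max(horizon, s[length(s)]) + 1)  # interval ends
  aa <- .atomOnStates(prop$a, path@values)
  if (prop$form == "F") {
    return(any(aa & s <= prop$t2 & e > prop$t1))
  }
  if (prop$form == "G") {
    overlap <- s <= prop$t2 & e > prop$t1
    return(all(aa[overlap]))
  }
  ## bounded until: walk intervals in order
  bb <- .atomOnStates(prop$b, path@values)
  for (i in seq_along(s)) {
    witness <- bb[i] && e[i] > prop$t1 && s[i] <= prop$t2
    if (witness) {
      wt <- max(s[i], prop$t1)
      ## a must hold on [s_i, wt) if the witness is inside the interval
      if (wt <= s[i] || aa[i]) return(TRUE)
    }
    if (!aa[i]) return(FALSE)   # a fails before any later witness
  }
  FALSE
}

#' Monte-Carlo estimate of a temporal property
#'
#' Samples \code{nPaths} SSA paths (seeds \code{seed, seed+1, ...}) and
#' returns the fraction satisfying the formula together with an exact
#' (Clopper-Pearson) binomial confidence interval.
#'
#' @param net a [ReactionNetwork-class]
#' @param prop a \code{crnProperty} (see [boundedEventually()]) or a
#'   property string for [parseProperty()]
#' @param nPaths sample size (default 20, as used for the pipeline checks)
#' @param seed master seed
#' @param horizon simulation horizon; defaults to the formula's upper time
#'   bound
#' @param level confidence level of the interval
#' @return list with \code{estimate}, \code{ci}, \code{nPaths},
#'   \code{seed}, \code{satisfied} (per-path logical)
#' @export
estimateProperty <- function(net, prop, nPaths = 20L, seed = 1L,
                             horizon = NULL, level = 0.95) {
  if (is.character(prop)) prop <- parseProperty(prop)
  stopifnot(inherits(prop, "crnProperty"), nPaths >= 1)
  if (is.null(horizon)) horizon <- prop$t2
  sat <- vapply(seq_len(nPaths), function(i) {
    p <- simulateSSA(net, horizon, seed = seed + i - 1L)
    .holdsOnPath(prop, p, horizon)
  }, logical(1))
  k <- sum(sat)
  ci <- as.numeric(stats::binom.test(k, nPaths,
                                     conf.level = level)$conf.int)
  list(estimate = k / nPaths, ci = ci, nPaths = as.integer(nPaths),
       seed = as.integer(seed), satisfied = sat)
}

#' Parse the property mini-language
#'
#' Accepts PRISM-flavoured strings such as
#' \code{"P[ (B_hi < 8) U[0,3] (A_hi > 8) ]"},
#' \code{"P[ F[0,10] C_hi > 8 ]"} and \code{"P[ G[0,5] X_hi >= 2 ]"}.
#'
#' @param text property string
#' @return a \code{crnProperty}
#' @export
parseProperty <- function(text) {
  body <- sub("^\\s*P\\s*\\[(.*)\\]\\s*$", "\\1", text)
  atomRx <- paste0("\\(?\\s*(", .SP_RX, ")\\s*(>=|<=|>|<)\\s*",
                   "([0-9.]+)\\s*\\)?")
  boundRx <- "\\[\\s*([0-9.]+)\\s*,\\s*([0-9.]+)\\s*\\]"
  mU <- regmatches(body, regexec(paste0("^\\s*", atomRx, "\\s*U\\s*",
                                        boundRx, "\\s*", atomRx, "\\s*$"),
                                 body))[[1]]
  if (length(mU) == 9)
    return(boundedUntil(propAtom(mU[2], mU[3], as.numeric(mU[4])),
                        propAtom(mU[7], mU[8], as.numeric(mU[9])),
                        as.numeric(mU[5]), as.numeric(mU[6])))
  mF <- regmatches(body, regexec(paste0("^\\s*(F|G)\\s*", boundRx, "\\s*",
                                        atomRx, "\\s*$"), body))[[1]]
  if (length(mF) == 7) {
    atom <- propAtom(mF[5], mF[6], as.numeric(mF[7]))
    t1 <- as.numeric(mF[3]); t2 <- as.numeric(mF[4])
    return(if (mF[2] == "F") boundedEventually(atom, t1, t2)
           else boundedGlobally(atom, t1, t2))
  }
  stop("cannot parse property: ", text)
}
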
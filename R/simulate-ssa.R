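## Stochastic semantics: exact jump-by-jump sampling of the induced CTMC
## (Gillespie direct method).  Transition rates are N * alpha_tau(x).
##
## RNG contract: R's Mersenne-Twister, seeded once per path with
## set.seed(seed).  Each jump draws two uniforms: one for the waiting time,
## one for the reaction index (cumulative-sum inversion over reactions in
## declaration order).  meanOverPaths() derives path i's seed as
## seed + i - 1, so ensembles are reproducible from the master seed alone.

.ssaPropensities <- function(RM, rates, Npow, x) {
  a <- rates
  for (s in seq_along(x)) {
    col <- RM[, s]
    one <- col == 1L
    two <- col == 2L
    if (any(one)) a[one] <- a[one] * x[s]
    if (any(two)) a[two] <- a[two] * (x[s] * (x[s] - 1))
  }
  a / Npow
}

#' Simulate the stochastic semantics (SSA, direct method)
#'
#' Samples one exact trajectory of the continuous-time Markov chain whose
#' transition rates are \eqn{N\alpha_\tau(x)}.  Absorbing states terminate
#' early with the final state held to the horizon.  Injections truncate the
#' current waiting time at the event (the jump process is memoryless, so
#' restarting the exponential clock at the event is exact).
#'
#' @param object a [ReactionNetwork-class]
#' @param horizon end time
#' @param seed integer seed; the same seed reproduces the path bit-exactly
#' @param maxJumps safety cap on the number of jumps
#' @return an [SsaPath-class]
#' @export
setMethod("simulateSSA", "ReactionNetwork",
          function(object, horizon, seed = 1L, maxJumps = 1e6L) {
  stopifnot(horizon > 0)
  seed <- as.integer(seed)
  set.seed(seed)
  segs <- .injectionSegments(object, horizon)
  S <- length(object@species)
  x <- as.integer(round(object@x0))
  cap <- 1024L
  times <- numeric(cap)
  states <- matrix(0L, cap, S)
  n <- 1L
  states[1L, ] <- x
  t <- 0
  record <- function(tm, xx) {
    if (n + 1L > cap) {
      cap <<- cap * 2L
      times2 <- numeric(cap); times2[seq_len(n)] <- times[seq_len(n)]
      states2 <- matrix(0L, cap, S); states2[seq_len(n), ] <- states[seq_len(n), ]
      times <<- times2; states <<- states2
    }
    n <<- n + 1L
    times[n] <<- tm
    states[n, ] <<- xx
  }
  for (seg in segs) {
    RM <- seg$net@reactants
    V <- seg$net@products - RM
    rates <- seg$net@rates
    Npow <- object@N^(rowSums(RM) - 1)
    Nfac <- object@N
    t <- max(t, seg$from)
    repeat {
      a <- Nfac * .ssaPropensities(RM, rates, Npow, x)
      a0 <- sum(a)
      if (a0 <= 0) { t <- seg$until; break }        # absorbing in this segment
      tau <- -log(stats::runif(1)) / a0
      if (t + tau > seg$until) { t <- seg$until; break }
      t <- t + tau
      j <- findInterval(stats::runif(1) * a0, cumsum(a)) + 1L
      x <- x + V[j, ]
      record(t, x)
      if (n >= maxJumps) {
        warning("maxJumps reached at t = ", t)
        t <- seg$until
        break
      }
    }
  }
  new("SsaPath", times = times[seq_len(n)],
      values = `colnames<-`(states[seq_len(n), , drop = FALSE],
                            object@species),
      seed = seed)
})

#' Empirical mean over SSA paths
#'
#' Pointwise sample mean (with standard errors) of \code{nPaths} independent
#' SSA paths evaluated on a common grid.  Path \code{i} uses seed
#' \code{seed + i - 1}.
#'
#' @param object a [ReactionNetwork-class]
#' @param horizon end time
#' @param times output grid (defaults to 201 equispaced points)
#' @param nPaths number of paths (>= 1)
#' @param seed master seed
#' @return a [MeanTrajectory-class]
#' @export
setMethod("meanOverPaths", "ReactionNetwork",
          function(object, horizon, times = NULL, nPaths = 20L, seed = 1L) {
  stopifnot(nPaths >= 1)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201L)
  S <- length(object@species)
  acc <- matrix(0, length(times), S)
  acc2 <- matrix(0, length(times), S)
  for (i in seq_len(nPaths)) {
    p <- simulateSSA(object, horizon, seed = seed + i - 1L)
    idx <- findInterval(times, p@times)
    idx[idx < 1L] <- 1L
    v <- p@values[idx, , drop = FALSE]
    acc <- acc + v
    acc2 <- acc2 + v^2
  }
  m <- acc / nPaths
  se <- if (nPaths > 1)
    sqrt(pmax(acc2 / nPaths - m^2, 0) / (nPaths - 1)) else matrix(0, length(times), S)
  colnames(m) <- colnames(se) <- object@species
  new("MeanTrajectory", times = times, values = m, se = se,
      nPaths = as.integer(nPaths), seed = as.integer(seed))
})
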
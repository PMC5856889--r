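## Deterministic semantics: mass-action rate equations solved with deSolve.
## The networks shipped here are non-stiff at the paper's scale (tens of
## molecules, unit rates); lsoda with rtol 1e-8 / atol 1e-10 resolves them
## comfortably.

.odeSegment <- function(net, y0, times, rtol, atol) {
  RM <- net@reactants
  V <- net@products - RM
  k <- net@rates
  f <- function(t, y, parms) {
    list(as.numeric(crossprod(V, .odeRates(RM, k, y))))
  }
  out <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(out, "istate")[1])
  out
}

#' Simulate the deterministic semantics
#'
#' Integrates the mass-action rate equations from \eqn{\Phi(0) = x_0 / N}.
#' Scheduled injections are honoured piecewise: the solver runs to each event
#' time, the reaction set is extended, and integration continues from the
#' reached state.
#'
#' @param object a [ReactionNetwork-class]
#' @param horizon end time (> 0)
#' @param times optional output grid (defaults to 501 equispaced points)
#' @param rtol,atol solver tolerances
#' @return an [OdeTrajectory-class] in count-scale units (concentration
#'   times N)
#' @export
setMethod("simulateODE", "ReactionNetwork",
          function(object, horizon, times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0)
  if (is.null(times)) times <- seq(0, horizon, length.out = 501L)
  stopifnot(!is.unsorted(times), times[1] >= 0)
  phi0 <- setNames(object@x0 / object@N, object@species)
  segs <- .injectionSegments(object, horizon)
  rows <- list()
  y <- phi0
  for (seg in segs) {
    tt <- times[times >= seg$from & times <= seg$until]
    tseg <- sort(unique(c(seg$from, tt, seg$until)))
    if (length(tseg) < 2) tseg <- c(seg$from, seg$until)
    if (seg$until > seg$from) {
      out <- .odeSegment(seg$net, y, tseg, rtol, atol)
      y <- setNames(pmax(out[nrow(out), -1], 0), object@species)
      keep <- out[out[, 1] %in% tt, , drop = FALSE]
      rows[[length(rows) + 1L]] <- keep
    }
  }
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  vals <- m[, -1, drop = FALSE] * object@N
  vals[vals < 0 & vals > -atol * 10] <- 0
  colnames(vals) <- object@species
  new("OdeTrajectory", times = as.numeric(m[, 1]), values = vals)
})
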
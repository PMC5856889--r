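## Linear noise approximation: Y = N*Phi + sqrt(N)*Z with E[Z] = 0 and
## dC[Z]/dt = J C + C J^T + W, C[Z(0)] = 0.  Mean and covariance are
## integrated jointly; the covariance is symmetrized each step to suppress
## numerical drift.

#' Simulate the linear noise approximation
#'
#' Returns the Gaussian process characterisation of the stochastic
#' semantics: mean \eqn{E[Y(t)] = N\Phi(t)} (identical to the deterministic
#' solution scaled by N), covariance \eqn{C[Y(t)] = N\,C[Z(t)]} and the
#' per-species standard deviation (square root of the covariance diagonal).
#' Injections are handled piecewise as in [simulateODE()]; the covariance
#' accumulated so far is carried across each event.
#'
#' @param object a [ReactionNetwork-class]
#' @param horizon end time
#' @param times optional output grid
#' @param rtol,atol solver tolerances
#' @return an [LnaTrajectory-class]
#' @export
setMethod("simulateLNA", "ReactionNetwork",
          function(object, horizon, times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(horizon > 0)
  if (is.null(times)) times <- seq(0, horizon, length.out = 501L)
  S <- length(object@species)
  segs <- .injectionSegments(object, horizon)
  y <- c(object@x0 / object@N, numeric(S * S))
  rows <- list()
  for (seg in segs) {
    net <- seg$net
    RM <- net@reactants
    V <- net@products - RM
    k <- net@rates
    f <- function(t, y, parms) {
      phi <- pmax(y[seq_len(S)], 0)
      C <- matrix(y[-seq_len(S)], S, S)
      C <- (C + t(C)) / 2
      J <- jacobianMatrix(net, phi)
      W <- diffusionMatrix(net, phi)
      dC <- J %*% C + C %*% t(J) + W
      list(c(as.numeric(crossprod(V, .odeRates(RM, k, phi))),
             as.numeric(dC)))
    }
    tt <- times[times >= seg$from & times <= seg$until]
    tseg <- sort(unique(c(seg$from, tt, seg$until)))
    if (length(tseg) < 2) tseg <- c(seg$from, seg$until)
    if (seg$until > seg$from) {
      out <- deSolve::ode(y = y, times = tseg, func = f, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol)
      if (attr(out, "istate")[1] < 0)
        stop("LNA solver failed: istate = ", attr(out, "istate")[1])
      y <- out[nrow(out), -1]
      rows[[length(rows) + 1L]] <- out[out[, 1] %in% tt, , drop = FALSE]
    }
  }
  m <- do.call(rbind, rows)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  tms <- as.numeric(m[, 1])
  mean <- m[, 1 + seq_len(S), drop = FALSE] * object@N
  colnames(mean) <- object@species
  covArr <- array(0, c(length(tms), S, S),
                  dimnames = list(NULL, object@species, object@species))
  sd <- matrix(0, length(tms), S, dimnames = list(NULL, object@species))
  for (i in seq_along(tms)) {
    C <- matrix(m[i, -(1:(S + 1))], S, S) * object@N
    C <- (C + t(C)) / 2
    dg <- diag(C)
    if (any(dg < -1e-9))
      stop("negative variance in LNA solution: ", min(dg))
    dg <- pmax(dg, 0)
    diag(C) <- dg
    covArr[i, , ] <- C
    sd[i, ] <- sqrt(dg)
  }
  new("LnaTrajectory", times = tms, values = mean, sd = sd, cov = covArr)
})
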
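## Core methods on ReactionNetwork: accessors, mass-action kinetics,
## stoichiometric analysis.

#' @describeIn ReactionNetwork species names in declaration order
#' @export
setMethod("speciesNames", "ReactionNetwork", function(object) object@species)

#' @describeIn ReactionNetwork number of reactions
#' @export
setMethod("reactionCount", "ReactionNetwork",
          function(object) nrow(object@reactants))

#' @describeIn ReactionNetwork rate coefficients
#' @export
setMethod("rateConstants", "ReactionNetwork", function(object) object@rates)

#' @describeIn ReactionNetwork initial configuration (molecule counts)
#' @export
setMethod("initialCounts", "ReactionNetwork",
          function(object) setNames(object@x0, object@species))

#' @describeIn ReactionNetwork replace initial counts; accepts a full vector
#'   or a named subset
#' @export
setMethod("initialCounts<-", "ReactionNetwork", function(object, value) {
  if (!is.null(names(value))) {
    unknown <- setdiff(names(value), object@species)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    object@x0[match(names(value), object@species)] <- value
  } else {
    stopifnot(length(value) == length(object@species))
    object@x0 <- as.numeric(value)
  }
  names(object@x0) <- object@species
  validObject(object)
  object
})

#' @describeIn ReactionNetwork volumetric factor N
#' @export
setMethod("volumetricFactor", "ReactionNetwork", function(object) object@N)

#' @describeIn ReactionNetwork scheduled injection events
#' @export
setMethod("injections", "ReactionNetwork", function(object) object@injections)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("%s with %d species, %d reactions (N = %g)\n",
              class(object), length(object@species),
              reactionCount(object), object@N))
  sp <- object@species
  nz <- which(object@x0 > 0)
  if (length(nz))
    cat("  x0:", paste(sprintf("%s=%g", sp[nz], object@x0[nz]),
                       collapse = ", "), "\n")
  n <- min(reactionCount(object), 12L)
  for (j in seq_len(n))
    cat(sprintf("  %s ->{%s} %s\n",
                .formatSide(object@reactants[j, ], sp),
                .formatRate(object@rates[j]),
                .formatSide(object@products[j, ], sp)))
  if (reactionCount(object) > n)
    cat(sprintf("  ... and %d more reactions\n", reactionCount(object) - n))
  if (length(object@injections))
    cat(sprintf("  %d scheduled injection(s) at t = %s\n",
                length(object@injections),
                paste(vapply(object@injections, `[[`, numeric(1), "time"),
                      collapse = ", ")))
})

#' Net change (stoichiometry) of reactions
#'
#' The net change of reaction \eqn{\tau} is \eqn{\upsilon_\tau = p_\tau -
#' r_\tau}.  With \code{reaction} missing the full stoichiometry matrix (one
#' row per reaction) is returned.
#'
#' @param object a [ReactionNetwork-class]
#' @param reaction optional reaction index
#' @return an integer vector (one reaction) or matrix (all reactions) with
#'   one entry per species
#' @export
setMethod("netChange", "ReactionNetwork", function(object, reaction) {
  V <- object@products - object@reactants
  if (missing(reaction)) V else setNames(V[reaction, ], object@species)
})

#' Conserved species groups
#'
#' Finds non-negative integer species weightings \eqn{w} with
#' \eqn{\upsilon_\tau \cdot w = 0} for every reaction, i.e. weighted totals
#' invariant along any trajectory.  All shipped components use 2-reactant /
#' 2-product catalytic reactions, for which the groups are the connected
#' components of the conversion graph (weight 1 each, untouched species form
#' singletons).  For general networks with few species a bounded enumeration
#' of integer weight vectors is used.
#'
#' @param object a [ReactionNetwork-class]
#' @return list of named integer weight vectors, one per conserved group
#' @export
setMethod("conservedTotals", "ReactionNetwork", function(object) {
  V <- object@products - object@reactants
  sp <- object@species
  S <- length(sp)
  singleConversion <- all(apply(V, 1, function(v) {
    all(v == 0) || (sum(v == 1) == 1 && sum(v == -1) == 1 && sum(v != 0) == 2)
  }))
  if (singleConversion) {
    parent <- seq_len(S)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (j in seq_len(nrow(V))) {
      nz <- which(V[j, ] != 0)
      if (length(nz) == 2) {
        a <- find(nz[1]); b <- find(nz[2])
        if (a != b) parent[a] <- b
      }
    }
    roots <- vapply(seq_len(S), find, integer(1))
    lapply(split(seq_len(S), roots), function(idx)
      setNames(rep(1L, length(idx)), sp[idx]))
  } else {
    if (S > 8) {
      warning("network too large for integer weight enumeration")
      return(list())
    }
    ## enumerate w in {0,..,3}^S, keep minimal-support conserved vectors
    grid <- as.matrix(do.call(expand.grid, rep(list(0:3), S)))
    keep <- grid[rowSums(abs(grid %*% t(V))) == 0 & rowSums(grid) > 0, ,
                 drop = FALSE]
    res <- list()
    supports <- list()
    for (i in order(rowSums(keep != 0))) {
      supp <- which(keep[i, ] != 0)
      if (any(vapply(supports, function(s) all(s %in% supp), logical(1))))
        next
      supports[[length(supports) + 1L]] <- supp
      res[[length(res) + 1L]] <- setNames(as.integer(keep[i, supp]), sp[supp])
    }
    res
  }
})

## ---- mass-action kinetics ----

## reaction rate under the deterministic semantics: k * prod(phi^r)
.odeRates <- function(RM, rates, phi) {
  phi <- pmax(phi, 0)
  r <- rates
  for (s in seq_along(phi)) {
    col <- RM[, s]
    if (any(col > 0)) r <- r * phi[s]^col
  }
  r
}

#' Deterministic drift F(phi)
#'
#' Evaluates the right-hand side of the mass-action rate equations,
#' \eqn{F(\Phi) = \sum_\tau \upsilon_\tau k_\tau \prod_i \Phi_i^{r_{\tau,i}}}.
#'
#' @param object a [ReactionNetwork-class]
#' @param phi concentration vector (one entry per species)
#' @return named numeric vector of concentration rates
#' @export
setMethod("drift", "ReactionNetwork", function(object, phi) {
  stopifnot(length(phi) == length(object@species))
  V <- object@products - object@reactants
  setNames(as.numeric(crossprod(V, .odeRates(object@reactants, object@rates,
                                             phi))),
           object@species)
})

#' Stochastic propensities
#'
#' Evaluates the mass-action propensity
#' \eqn{\alpha_\tau(x) = k_\tau \frac{\prod_i r_{i,\tau}!}{N^{|r_\tau|-1}}
#' \prod_i \binom{x_i}{r_{i,\tau}}} for every reaction.  The CTMC transition
#' rate of reaction \eqn{\tau} is \eqn{N \alpha_\tau(x)}.  States with
#' insufficient reactants give propensity 0.
#'
#' @param object a [ReactionNetwork-class]
#' @param x integer configuration (molecule counts per species)
#' @return numeric vector, one propensity per reaction
#' @export
setMethod("propensities", "ReactionNetwork", function(object, x) {
  stopifnot(length(x) == length(object@species), all(x >= 0))
  RM <- object@reactants
  a <- object@rates
  for (s in seq_along(x)) {
    col <- RM[, s]
    one <- col == 1L
    two <- col == 2L
    if (any(one)) a[one] <- a[one] * x[s]
    if (any(two)) a[two] <- a[two] * (x[s] * (x[s] - 1))  # 2! * choose(x,2)
  }
  a / object@N^(rowSums(RM) - 1)
})

#' Jacobian of the drift
#'
#' Analytic partial derivatives of [drift()] with respect to the
#' concentrations, used by the linear noise approximation.
#' @inheritParams drift
#' @return S x S matrix
#' @export
setMethod("jacobianMatrix", "ReactionNetwork", function(object, phi) {
  stopifnot(length(phi) == length(object@species))
  phi <- pmax(phi, 0)
  RM <- object@reactants
  V <- object@products - RM
  S <- length(phi)
  R <- nrow(RM)
  G <- matrix(0, R, S)      # G[j, s] = d rate_j / d phi_s
  for (j in seq_len(R)) {
    nz <- which(RM[j, ] > 0)
    if (length(nz) == 1 && RM[j, nz] == 1L) {
      G[j, nz] <- object@rates[j]
    } else if (length(nz) == 1) {            # A + A -> ...
      G[j, nz] <- 2 * object@rates[j] * phi[nz]
    } else {                                 # A + B -> ...
      G[j, nz[1]] <- object@rates[j] * phi[nz[2]]
      G[j, nz[2]] <- object@rates[j] * phi[nz[1]]
    }
  }
  J <- crossprod(V, G)
  dimnames(J) <- list(object@species, object@species)
  J
})

#' Diffusion matrix of the linear noise approximation
#'
#' \eqn{W(\Phi) = \sum_\tau \upsilon_\tau \upsilon_\tau^T k_\tau
#' \prod_S \Phi_S^{r_{S,\tau}}}; symmetric positive semi-definite by
#' construction.
#' @inheritParams drift
#' @return S x S matrix
#' @export
setMethod("diffusionMatrix", "ReactionNetwork", function(object, phi) {
  stopifnot(length(phi) == length(object@species))
  V <- object@products - object@reactants
  r <- .odeRates(object@reactants, object@rates, phi)
  W <- crossprod(V * sqrt(r))       # sum_j r_j v_j v_j^T
  dimnames(W) <- list(object@species, object@species)
  W
})

#' Schedule a signal-change injection
#'
#' Adds reactions to the network at a given time; the simulation engines
#' treat the schedule as a piecewise network definition (integrate or
#' simulate to the event time, extend the reaction set, continue from the
#' reached state).  The canonical use is converting a signal while a circuit
#' runs, e.g. \code{addInjection(net, 1, "Req_hi -> Req_lo")}.
#'
#' @param object a [ReactionNetwork-class]
#' @param time non-negative event time
#' @param reactions reaction statements (reaction-format text); all species
#'   must already exist in the network
#' @return the network with the event appended (events kept sorted by time)
#' @export
setMethod("addInjection", "ReactionNetwork", function(object, time, reactions) {
  if (time < 0) stop("event time must be non-negative")
  tmp <- parseCRN(paste(reactions, collapse = "\n"))
  unknown <- setdiff(tmp@species, object@species)
  if (length(unknown))
    stop("injection uses unknown species: ", paste(unknown, collapse = ", "))
  S <- length(object@species)
  idx <- match(tmp@species, object@species)
  RM <- matrix(0L, reactionCount(tmp), S,
               dimnames = list(NULL, object@species))
  PM <- RM
  RM[, idx] <- tmp@reactants
  PM[, idx] <- tmp@products
  ev <- list(time = time, reactants = RM, products = PM, rates = tmp@rates)
  object@injections <- append(object@injections, list(ev))
  ord <- order(vapply(object@injections, `[[`, numeric(1), "time"))
  object@injections <- object@injections[ord]
  validObject(object)
  object
})

#' Rename species
#'
#' @param object a [ReactionNetwork-class] or [DualRailCircuit-class]
#' @param map named character vector, \code{c(old = "new")}; renaming a rail
#'   base name in a circuit renames both rails.
#' @export
setMethod("renameSpecies", "ReactionNetwork", function(object, map) {
  sp <- object@species
  hit <- sp %in% names(map)
  sp[hit] <- map[sp[hit]]
  if (anyDuplicated(sp)) stop("renaming would create duplicate species")
  object@species <- sp
  names(object@x0) <- sp
  colnames(object@reactants) <- sp
  colnames(object@products) <- sp
  object@injections <- lapply(object@injections, function(ev) {
    colnames(ev$reactants) <- sp
    colnames(ev$products) <- sp
    ev
  })
  ## port declarations of subclasses are fixed up by their own methods, so
  ## defer validation to the most specific method
  if (class(object)[1] == "ReactionNetwork") validObject(object)
  object
})

## split a piecewise-defined network into segments [t_i, t_{i+1}) each with
## the cumulative reaction set; returns list of list(until=, net=)
.injectionSegments <- function(object, horizon) {
  evs <- Filter(function(e) e$time < horizon, object@injections)
  bounds <- c(vapply(evs, `[[`, numeric(1), "time"), horizon)
  segs <- list()
  cur <- object
  cur@injections <- list()
  from <- 0
  for (i in seq_along(bounds)) {
    segs[[i]] <- list(from = from, until = bounds[i], net = cur)
    if (i <= length(evs)) {
      ev <- evs[[i]]
      cur@reactants <- rbind(cur@reactants, ev$reactants)
      cur@products <- rbind(cur@products, ev$products)
      cur@rates <- c(cur@rates, ev$rates)
      from <- ev$time
    }
  }
  segs
}
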
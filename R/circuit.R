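## DualRailCircuit: Boolean interface on top of a ReactionNetwork.

#' Construct a dual-rail circuit from a network
#'
#' @param network a [ReactionNetwork-class]; rail species \code{<base>_hi} /
#'   \code{<base>_lo} must exist for every declared signal.
#' @param inputs,outputs character vectors of signal base names
#' @param railMax signal amplitude in molecules (default 10)
#' @param contract optional behavioural contract (see
#'   [DualRailCircuit-class])
#' @return a [DualRailCircuit-class]
#' @export
dualRailCircuit <- function(network, inputs, outputs, railMax = 10,
                            contract = list()) {
  new("DualRailCircuit", network, inputs = inputs, outputs = outputs,
      railMax = railMax, contract = contract)
}

#' @describeIn DualRailCircuit input signal base names
#' @export
setMethod("inputRails", "DualRailCircuit", function(object) object@inputs)

#' @describeIn DualRailCircuit output signal base names
#' @export
setMethod("outputRails", "DualRailCircuit", function(object) object@outputs)

#' @describeIn DualRailCircuit signal amplitude in molecules
#' @export
setMethod("railMax", "DualRailCircuit", function(object) object@railMax)

#' @describeIn DualRailCircuit role of each species: \code{input_rail},
#'   \code{output_rail} or \code{internal}
#' @export
setMethod("speciesRoles", "DualRailCircuit", function(object) {
  rails <- function(b) paste0(rep(b, each = 2), c("_hi", "_lo"))
  role <- rep("internal", length(object@species))
  role[object@species %in% rails(object@inputs)] <- "input_rail"
  role[object@species %in% rails(object@outputs)] <- "output_rail"
  setNames(role, object@species)
})

setMethod("show", "DualRailCircuit", function(object) {
  cat(sprintf("DualRailCircuit: inputs {%s} outputs {%s}, railMax = %g\n",
              paste(object@inputs, collapse = ", "),
              paste(object@outputs, collapse = ", "), object@railMax))
  callNextMethod()
})

#' @describeIn renameSpecies circuit method; entries of \code{map} naming a
#'   signal base rename both rails and the port declaration.
#' @export
setMethod("renameSpecies", "DualRailCircuit", function(object, map) {
  ## expand base-name entries to their rails
  base <- intersect(names(map), c(object@inputs, object@outputs))
  full <- map[setdiff(names(map), base)]
  for (b in base) {
    full[paste0(b, "_hi")] <- paste0(map[[b]], "_hi")
    full[paste0(b, "_lo")] <- paste0(map[[b]], "_lo")
  }
  net <- callNextMethod(object, full)
  sub <- function(x) ifelse(x %in% base, map[x], x)
  net@inputs <- unname(sub(object@inputs))
  net@outputs <- unname(sub(object@outputs))
  validObject(net)
  net
})

#' Set a dual-rail input signal in the initial configuration
#'
#' Writes \code{railMax} molecules on the rail encoding \code{value} and 0 on
#' the other rail.  \code{value = NA} clears both rails (signal absent).
#'
#' @param circuit a [DualRailCircuit-class]
#' @param signal signal base name
#' @param value 0, 1 or NA
#' @param count molecules for the asserted rail (defaults to
#'   \code{railMax(circuit)})
#' @export
setSignal <- function(circuit, signal, value, count = railMax(circuit)) {
  hi <- paste0(signal, "_hi")
  lo <- paste0(signal, "_lo")
  if (!all(c(hi, lo) %in% circuit@species))
    stop("unknown signal: ", signal)
  x <- c(0, 0)
  if (!is.na(value)) {
    if (value == 1) x <- c(count, 0) else x <- c(0, count)
  }
  initialCounts(circuit) <- setNames(x, c(hi, lo))
  circuit
}

#' Series composition of dual-rail circuits
#'
#' Wires output signals of \code{first} to input signals of \code{second}.
#' Each wired pair is renamed to a fresh internal \code{lambda<k>_hi/_lo}
#' pair shared by both circuits, so the upstream outputs become the catalysts
#' that drive the downstream stage.  Non-wired species whose names collide
#' are disambiguated with instance prefixes.  With \code{crossed = TRUE} the
#' hi rail of the upstream output feeds the lo input rail and vice versa --
#' dual-rail inversion by rail crossing, with no extra reactions.
#'
#' @param first,second [DualRailCircuit-class] objects
#' @param wiring named character vector: names are output signals of
#'   \code{first}, values are input signals of \code{second}.  May be empty,
#'   giving the disjoint union.
#' @param crossed logical scalar or vector (per wire)
#' @param instances length-2 character, prefixes used to resolve collisions
#' @return the composed [DualRailCircuit-class]; inputs are the inputs of
#'   \code{first} plus unwired inputs of \code{second}, outputs those of
#'   \code{second}.
#' @export
setMethod("composeSeries", signature("DualRailCircuit", "DualRailCircuit"),
          function(first, second, wiring, crossed = FALSE,
                   instances = c("s1", "s2")) {
  if (length(wiring)) {
    if (is.null(names(wiring))) stop("wiring must be a named vector")
    if (!all(names(wiring) %in% first@outputs))
      stop("wiring names must be outputs of the first circuit")
    if (!all(wiring %in% second@inputs))
      stop("wiring values must be inputs of the second circuit")
    if (anyDuplicated(names(wiring)) || anyDuplicated(wiring))
      stop("wiring must be a bijection")
  }
  crossed <- rep_len(crossed, length(wiring))
  ## fresh wire indices, so nested compositions never collide
  used <- regmatches(c(first@species, second@species),
                     regexec("^lambda\\.w([0-9]+)_", c(first@species,
                                                       second@species)))
  used <- as.integer(vapply(Filter(length, used), `[`, character(1), 2))
  k0 <- if (length(used)) max(used) else 0L
  map1 <- character(0); map2 <- character(0)
  for (k in seq_along(wiring)) {
    out <- names(wiring)[k]; inp <- wiring[[k]]
    lam <- sprintf("lambda.w%d", k0 + k)
    map1[paste0(out, "_hi")] <- paste0(lam, "_hi")
    map1[paste0(out, "_lo")] <- paste0(lam, "_lo")
    map2[paste0(inp, "_hi")] <- paste0(lam, if (crossed[k]) "_lo" else "_hi")
    map2[paste0(inp, "_lo")] <- paste0(lam, if (crossed[k]) "_hi" else "_lo")
  }
  f <- .renameRaw(first, map1)
  s <- .renameRaw(second, map2)
  ## resolve accidental collisions among non-wired species
  shared <- setdiff(intersect(f@species, s@species),
                    unname(c(map1, map2)))
  if (length(shared)) {
    f <- .renameRaw(f, setNames(paste0(instances[1], ".", shared), shared))
    s <- .renameRaw(s, setNames(paste0(instances[2], ".", shared), shared))
  }
  species <- union(f@species, s@species)
  S <- length(species)
  pad <- function(m, sp) {
    out <- matrix(0L, nrow(m), S, dimnames = list(NULL, species))
    out[, sp] <- m
    out
  }
  x0 <- setNames(numeric(S), species)
  x0[f@species] <- x0[f@species] + f@x0
  x0[s@species] <- x0[s@species] + s@x0
  net <- new("ReactionNetwork", species = species,
             reactants = rbind(pad(f@reactants, f@species),
                               pad(s@reactants, s@species)),
             products = rbind(pad(f@products, f@species),
                              pad(s@products, s@species)),
             rates = c(f@rates, s@rates), x0 = x0, N = first@N)
  lamBases <- if (length(wiring))
    sprintf("lambda.w%d", k0 + seq_along(wiring)) else character(0)
  ins2 <- setdiff(s@inputs, lamBases)
  dualRailCircuit(net,
                  inputs = union(f@inputs, ins2),
                  outputs = s@outputs,
                  railMax = first@railMax)
})

## rename on the raw slots without rail-pair expansion of port names having
## been applied twice; used internally by composeSeries
.renameRaw <- function(object, map) {
  if (!length(map)) return(object)
  sp <- object@species
  hit <- sp %in% names(map)
  sp[hit] <- map[sp[hit]]
  object@species <- sp
  names(object@x0) <- sp
  colnames(object@reactants) <- sp
  colnames(object@products) <- sp
  if (is(object, "DualRailCircuit")) {
    fix <- function(bases) {
      his <- paste0(bases, "_hi")
      renamed <- his %in% names(map)
      bases[renamed] <- sub("_(hi|lo)$", "", map[his[renamed]])
      bases
    }
    object@inputs <- unname(fix(object@inputs))
    object@outputs <- unname(fix(object@outputs))
  }
  object
}
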
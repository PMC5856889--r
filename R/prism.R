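## Export of the induced CTMC as a PRISM model: one bounded integer
## variable per species, one guarded command per reaction whose rate
## expression equals the transition rate N * alpha_tau(x).

.prismName <- function(x) {
  nm <- gsub("[^A-Za-z0-9_]", "_", x)
  make.unique(nm, sep = "_")
}

#' Export a network as a PRISM CTMC model
#'
#' Species bounds are taken from the conserved totals where available
#' (each species is bounded by its group total divided by its weight);
#' species not covered by any conservation law must be bounded explicitly
#' through \code{bounds}.
#'
#' The rate expression of each command reproduces the mass-action CTMC
#' transition rate: \code{k*N*X} for a unimolecular reaction, \code{k*X*Y}
#' for distinct reactants and \code{k*X*(X-1)} for a paired reactant (all
#' divided by nothing further at N = 1, the convention used throughout).
#'
#' @param object a [ReactionNetwork-class]
#' @param bounds named numeric vector of per-species maximum counts,
#'   overriding/extending the derived ones
#' @param name module name in the generated file
#' @return character scalar: the PRISM model text
#' @export
setMethod("exportPrism", "ReactionNetwork",
          function(object, bounds = NULL, name = "crn") {
  sp <- object@species
  pn <- setNames(.prismName(sp), sp)
  x0 <- setNames(object@x0, sp)
  ## bounds from conservation laws
  derived <- setNames(rep(NA_real_, length(sp)), sp)
  for (grp in conservedTotals(object)) {
    total <- sum(grp * x0[names(grp)])
    for (s in names(grp))
      derived[s] <- min(derived[s], floor(total / grp[s]), na.rm = TRUE)
  }
  if (!is.null(bounds)) derived[names(bounds)] <- bounds
  if (any(is.na(derived)))
    stop("no bound available for species: ",
         paste(sp[is.na(derived)], collapse = ", "),
         " (supply via 'bounds')")
  fmtNum <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c("ctmc", "", sprintf("module %s", name))
  lines <- c(lines, sprintf("  %s : [0..%d] init %d;",
                            pn, as.integer(derived), as.integer(object@x0)))
  V <- object@products - object@reactants
  for (j in seq_len(reactionCount(object))) {
    r <- object@reactants[j, ]
    guard <- character(0)
    rate <- character(0)
    for (s in which(r > 0)) {
      guard <- c(guard, sprintf("%s>=%d", pn[s], r[s]))
      rate <- c(rate, if (r[s] == 2)
        sprintf("%s*(%s-1)", pn[s], pn[s]) else pn[s])
    }
    kN <- object@rates[j] * if (sum(r) == 1) object@N else 1
    if (kN != 1) rate <- c(fmtNum(kN), rate)
    chg <- which(V[j, ] != 0)
    for (s in chg)
      if (V[j, s] > 0)
        guard <- c(guard, sprintf("%s<=%d", pn[s],
                                  as.integer(derived[s] - V[j, s])))
    upd <- sprintf("(%s'=%s%+d)", pn[chg], pn[chg], V[j, chg])
    if (length(chg) == 0) upd <- sprintf("(%s'=%s)", pn[1], pn[1])
    lines <- c(lines, sprintf("  [] %s -> %s : %s;",
                              paste(guard, collapse = " & "),
                              paste(rate, collapse = "*"),
                              paste(upd, collapse = " & ")))
  }
  c(lines, "endmodule")
  paste(c(lines, "endmodule"), collapse = "\n")
})
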
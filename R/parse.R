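## Plain-text reaction format.
##
## One statement per line, '#' starts a comment:
##   init <species> <integer>            initial molecule count (default 0)
##   A [+ B] ->{k} C [+ D]               reaction, rate k (default 1)
##   rev A [+ B] ->{k1,k2} C [+ D]       reversible shorthand, expands to the
##                                       forward (k1) and reverse (k2) reaction
## Species appear in first-appearance order, which fixes all vector layouts.

.SP_RX <- "[A-Za-z][A-Za-z0-9_.]*"

#' Parse a reaction-format document into a ReactionNetwork
#'
#' @param text character scalar (or vector of lines) in the reaction format
#'   described under Details.
#' @param N volumetric factor of the resulting system (default 1, so counts
#'   and concentrations coincide).
#'
#' @details The grammar is line based: \code{init X 10} declares an initial
#' count; \code{X_hi + Y_lo ->\{1\} X_hi + Y_hi} declares a reaction with
#' rate coefficient 1 (the \code{\{rate\}} part may be omitted and defaults
#' to 1); a \code{rev} prefix with \code{\{k1,k2\}} expands to the two
#' irreversible reactions.  At most two reactant and two product molecules
#' are allowed per reaction.  Unknown species are declared on first use with
#' initial count 0.
#'
#' @return a [ReactionNetwork-class]
#' @examples
#' net <- parseCRN("
#'   init X_hi 10
#'   init Y_lo 10
#'   X_hi + Y_lo ->{1} X_hi + Y_hi
#'   X_lo + Y_hi ->{1} X_lo + Y_lo")
#' net
#' @export
parseCRN <- function(text, N = 1) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- character(0)
  inits <- numeric(0)
  rx <- list()   # list of list(r=, p=, k=)
  seen <- function(nm) {
    new <- setdiff(nm, species)
    if (length(new)) {
      species <<- c(species, new)
      inits <<- c(inits, setNames(numeric(length(new)), new))
    }
  }
  parseSide <- function(side, lineno) {
    parts <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    if (any(parts == "") || length(parts) < 1)
      stop(sprintf("line %d: malformed species list '%s'", lineno, side),
           call. = FALSE)
    if (length(parts) > 2)
      stop(sprintf(
        "line %d: at most two molecules per side (uni-/bi-molecular only)",
        lineno), call. = FALSE)
    bad <- !grepl(paste0("^", .SP_RX, "$"), parts)
    if (any(bad))
      stop(sprintf("line %d: invalid species name '%s'", lineno,
                   parts[bad][1]), call. = FALSE)
    parts
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (grepl("^init\\s", ln)) {
      m <- regmatches(ln, regexec(paste0("^init\\s+(", .SP_RX,
                                         ")\\s+([0-9]+)$"), ln))[[1]]
      if (length(m) != 3)
        stop(sprintf("line %d: malformed init statement '%s'", i, ln),
             call. = FALSE)
      seen(m[2])
      inits[m[2]] <- as.numeric(m[3])
      next
    }
    rev <- grepl("^rev\\s", ln)
    body <- if (rev) sub("^rev\\s+", "", ln) else ln
    m <- regmatches(body, regexec(
      "^(.*?)->(\\{([0-9.eE+-]+)(,([0-9.eE+-]+))?\\})?(.*)$", body))[[1]]
    if (length(m) == 0 || !grepl("->", body))
      stop(sprintf("line %d: cannot parse statement '%s'", i, ln),
           call. = FALSE)
    lhs <- parseSide(m[2], i)
    rhs <- parseSide(m[7], i)
    k1 <- if (m[4] == "") 1 else as.numeric(m[4])
    k2 <- if (m[6] == "") 1 else as.numeric(m[6])
    if (is.na(k1) || k1 <= 0 || (rev && (is.na(k2) || k2 <= 0)))
      stop(sprintf("line %d: rates must be positive numbers", i),
           call. = FALSE)
    seen(lhs); seen(rhs)
    rx[[length(rx) + 1L]] <- list(r = lhs, p = rhs, k = k1)
    if (rev)
      rx[[length(rx) + 1L]] <- list(r = rhs, p = lhs, k = k2)
  }
  if (length(rx) == 0)
    stop("no reactions in document", call. = FALSE)
  S <- length(species)
  R <- length(rx)
  RM <- matrix(0L, R, S, dimnames = list(NULL, species))
  PM <- RM
  for (j in seq_len(R)) {
    for (s in rx[[j]]$r) RM[j, s] <- RM[j, s] + 1L
    for (s in rx[[j]]$p) PM[j, s] <- PM[j, s] + 1L
  }
  new("ReactionNetwork", species = species, reactants = RM, products = PM,
      rates = vapply(rx, `[[`, numeric(1), "k"),
      x0 = setNames(as.numeric(inits[species]), species), N = N)
}

#' Read a reaction-format file
#' @param path file path
#' @inheritParams parseCRN
#' @export
readCRN <- function(path, N = 1) parseCRN(readLines(path), N = N)

.formatSide <- function(counts, species) {
  out <- character(0)
  for (s in which(counts > 0)) out <- c(out, rep(species[s], counts[s]))
  paste(out, collapse = " + ")
}

.formatRate <- function(k) {
  ifelse(k == round(k), format(k, scientific = FALSE), format(k, digits = 15))
}

#' Serialize a network to the reaction format
#'
#' \code{parseCRN(crnText(net))} reproduces \code{net} exactly (species
#' order, rates and initial counts), so serialized circuits round-trip.
#' @param object a [ReactionNetwork-class]
#' @return character scalar
#' @export
setMethod("crnText", "ReactionNetwork", function(object) {
  sp <- object@species
  ## declare every species explicitly so first-appearance order is preserved
  lines <- sprintf("init %s %d", sp, as.integer(round(object@x0)))
  for (j in seq_len(nrow(object@reactants)))
    lines <- c(lines, sprintf("%s ->{%s} %s",
                              .formatSide(object@reactants[j, ], sp),
                              .formatRate(object@rates[j]),
                              .formatSide(object@products[j, ], sp)))
  paste(lines, collapse = "\n")
})

#' Write a network to a reaction-format file
#' @param object a [ReactionNetwork-class]
#' @param path file path
#' @export
writeCRN <- function(object, path) {
  writeLines(crnText(object), path)
  invisible(path)
}
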
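# Shared fixtures: tiny networks built in code and independent oracles.

motifText <- "
init X_hi 10
init Y_lo 10
X_hi + Y_lo ->{1} X_hi + Y_hi
X_lo + Y_hi ->{1} X_lo + Y_lo
"

# analytic solution of the driven motif: with X_hi = c held constant,
# Y_hi(t) = A (1 - exp(-c t)) for Y starting fully low at amplitude A
motifYhi <- function(t, c = 10, A = 10) A * (1 - exp(-c * t))

# brute-force mass-action propensity (independent of the package's vectorised
# evaluation): k * prod over species of choose(x, r) * r! / N^(|r|-1)
bruteAlpha <- function(r, x, k = 1, N = 1) {
  k * prod(choose(x, r) * factorial(r)) / N^(sum(r) - 1)
}

# a network with no reactions (legal but inert)
inertNetwork <- function(x0 = c(A = 5)) {
  new("ReactionNetwork", species = names(x0),
      reactants = matrix(0L, 0, length(x0), dimnames = list(NULL, names(x0))),
      products = matrix(0L, 0, length(x0), dimnames = list(NULL, names(x0))),
      rates = numeric(0), x0 = unname(x0), N = 1)
}

# weighted totals of every conserved group along a trajectory matrix
groupTotals <- function(net, values) {
  sapply(conservedTotals(net), function(w)
    as.numeric(values[, names(w), drop = FALSE] %*% w))
}

expectConserved <- function(net, values, tol = 1e-6) {
  tot <- groupTotals(net, values)
  expect_lte(max(abs(sweep(tot, 2, tot[1, ]))), tol)
}

# simulate a handcrafted step path for validation-layer unit tests
stepPath <- function(times, values) {
  new("SsaPath", times = times, values = values, seed = 0L)
}
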
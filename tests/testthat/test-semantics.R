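# The three engines: deterministic ODE, SSA, LNA.

test_that("drift evaluates the mass-action rate equations", {
  m <- buildMotif()
  phi <- setNames(numeric(4), speciesNames(m))
  phi[c("X_hi", "Y_lo")] <- 10
  d <- drift(m, phi)
  expect_equal(d[["Y_hi"]], 100)   # k * X_hi * Y_lo
  expect_equal(d[["Y_lo"]], -100)
  expect_equal(d[["X_hi"]], 0)     # catalyst
  expect_equal(unname(drift(m, phi * 0)), rep(0, 4))
})

test_that("the driven motif matches its analytic solution", {
  traj <- simulateODE(buildMotif(input = 1), 1)
  for (t in c(0.1, 0.25, 0.4, 0.8))
    expect_equal(speciesAt(traj, "Y_hi", t), motifYhi(t), tolerance = 1e-6)
})

test_that("a network with no reactions yields a constant trajectory", {
  traj <- simulateODE(inertNetwork(c(A = 5)), 1)
  expect_true(all(trajValues(traj)[, "A"] == 5))
  p <- simulateSSA(inertNetwork(c(A = 5)), 1, seed = 1)
  expect_equal(length(trajTimes(p)), 1L)   # zero jumps
})

test_that("propensities match the brute-force mass-action oracle", {
  # exhaustively over all small states for the three reactant shapes
  net <- parseCRN("A + B -> A + C\nA + A -> A + B\nB -> C")
  for (a in 0:6) for (b in 0:6) {
    x <- c(a, b, 0)
    alpha <- propensities(net, x)
    expect_equal(alpha[1], a * b)           # k x_A x_B
    expect_equal(alpha[2], a * (a - 1))     # 2! choose(a, 2)
    expect_equal(alpha[3], b)               # k x
    expect_equal(alpha, vapply(seq_len(3), function(j)
      bruteAlpha(net@reactants[j, ], x), numeric(1)))
  }
  # volumetric factor and rate coefficient enter as printed
  net2 <- parseCRN("A + B ->{2.5} A + C", N = 4)
  expect_equal(propensities(net2, c(3, 2, 0)), 2.5 * 3 * 2 / 4)
})

test_that("SSA reaches the absorbing state of the motif and is reproducible", {
  m <- buildMotif(input = 1)
  p <- simulateSSA(m, 2, seed = 11)
  final <- trajValues(p)[length(trajTimes(p)), ]
  expect_equal(as.numeric(final["Y_hi"]), 10)   # all output converted
  expect_equal(as.numeric(final["Y_lo"]), 0)
  expect_equal(length(trajTimes(p)) - 1L, 10L)  # exactly ten conversions
  expect_identical(trajValues(simulateSSA(m, 2, seed = 11)), trajValues(p))
  expect_identical(trajTimes(simulateSSA(m, 2, seed = 11)), trajTimes(p))
  # this network visits the same state sequence on every path (the reverse
  # conversion has no catalyst), so seeds are distinguished by jump times
  expect_false(identical(trajTimes(simulateSSA(m, 2, seed = 12)),
                         trajTimes(p)))
})

test_that("consecutive SSA states differ by a reaction's net change", {
  am <- buildDualRailAM(x = 0, y = 0, output = 1)
  p <- simulateSSA(am, 1, seed = 5)
  V <- netChange(am)
  dv <- diff(trajValues(p))
  for (i in seq_len(nrow(dv))) {
    hit <- apply(V, 1, function(v) all(v == dv[i, ]))
    expect_true(any(hit))
  }
  expect_true(all(trajValues(p) >= 0))
})

test_that("empirical SSA mean agrees with the ODE solution", {
  m <- buildMotif(input = 1)
  mp <- meanOverPaths(m, 0.6, times = c(0, 0.4), nPaths = 200, seed = 3)
  se <- mp@se[2, "Y_hi"]
  expect_lt(abs(speciesAt(mp, "Y_hi", 0.4) - motifYhi(0.4)), 3 * se)
  # a single path is just that path sampled on the grid
  one <- meanOverPaths(m, 0.6, times = c(0, 0.3, 0.6), nPaths = 1, seed = 9)
  p <- simulateSSA(m, 0.6, seed = 9)
  expect_equal(speciesAt(one, "Y_hi", 0.3),
               unname(speciesAt(p, "Y_hi", 0.3)))
})

test_that("LNA mean coincides with the ODE and covariance starts at zero", {
  for (net in list(buildMotif(input = 1),
                   buildDualRailAM(x = 0, y = 1, output = 1),
                   buildCElement(x = 0, y = 0, output = 1))) {
    grid <- seq(0, 1, length.out = 101)
    ln <- simulateLNA(net, 1, times = grid)
    od <- simulateODE(net, 1, times = grid)
    expect_lt(max(abs(trajValues(ln) - trajValues(od))), 1e-6)
    expect_equal(max(abs(ln@cov[1, , ])), 0)
    expect_true(all(ln@sd[1, ] == 0))
  }
})

test_that("LNA covariance stays symmetric positive semi-definite", {
  ln <- simulateLNA(buildDualRailAM(x = 0, y = 1, output = 1), 0.5)
  for (i in seq(1, length(trajTimes(ln)), by = 50)) {
    C <- ln@cov[i, , ]
    expect_equal(C, t(C), tolerance = 1e-8)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
              -1e-7)
  }
})

test_that("the analytic Jacobian matches central finite differences", {
  for (net in list(buildMotif(), buildDualRailAM())) {
    S <- length(speciesNames(net))
    set.seed(1)
    phi <- runif(S, 0.5, 8)
    J <- jacobianMatrix(net, phi)
    h <- 1e-6
    for (s in seq_len(S)) {
      up <- phi; up[s] <- up[s] + h
      dn <- phi; dn[s] <- dn[s] - h
      expect_equal(unname(J[, s]),
                   unname((drift(net, up) - drift(net, dn)) / (2 * h)),
                   tolerance = 1e-5)
    }
  }
})

test_that("the diffusion matrix equals its defining sum and vanishes at zero", {
  net <- buildDualRailAM()
  S <- length(speciesNames(net))
  expect_equal(unname(diffusionMatrix(net, numeric(S))),
               matrix(0, S, S))
  set.seed(2)
  phi <- runif(S, 0, 5)
  V <- netChange(net)
  rates <- vapply(seq_len(reactionCount(net)), function(j)
    net@rates[j] * prod(phi^net@reactants[j, ]), numeric(1))
  W <- Reduce(`+`, lapply(seq_len(nrow(V)), function(j)
    rates[j] * tcrossprod(V[j, ])))
  expect_equal(unname(diffusionMatrix(net, phi)), W, tolerance = 1e-10)
})

test_that("injections are honoured by ODE and SSA alike", {
  m <- addInjection(buildMotif(input = 1), 1, "X_hi -> X_lo")
  traj <- simulateODE(m, 6)
  expect_lt(speciesAt(traj, "X_hi", 6), 0.1)
  expect_equal(signalValue(traj, "Y", 6), 0)
  p <- simulateSSA(m, 12, seed = 4)
  final <- trajValues(p)[length(trajTimes(p)), ]
  expect_equal(as.numeric(final["X_hi"]), 0)
  expect_equal(as.numeric(final["Y_lo"]), 10)
})
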
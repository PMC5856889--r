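# Component builders and their documented behaviours (deterministic runs).

test_that("the motif has exactly the two catalytic reactions", {
  m <- buildMotif()
  expect_equal(reactionCount(m), 2L)
  expect_equal(length(speciesNames(m)), 4L)
  # without any input the output is frozen (every reaction needs a catalyst)
  m2 <- buildMotif(input = NA, output = 0)
  traj <- simulateODE(m2, 1)
  expect_true(all(trajValues(traj)[, "Y_lo"] == 10))
})

test_that("single-rail AM drives the minority to extinction", {
  am <- buildAM(X = 8, Y = 2)
  traj <- simulateODE(am, 3)
  expect_gt(speciesAt(traj, "X", 3), 9.5)
  expect_lt(speciesAt(traj, "Y", 3), 0.5)
  expectConserved(am, trajValues(traj))
  # symmetric start stays permutation-symmetric for all time
  traj <- simulateODE(buildAM(X = 5, Y = 5), 2)
  expect_lt(max(abs(trajValues(traj)[, "X"] - trajValues(traj)[, "Y"])),
            1e-8)
})

test_that("dual-rail AM converges on agreeing inputs", {
  am <- buildDualRailAM(x = 0, y = 0, output = 1)
  traj <- simulateODE(am, 1)
  expect_gt(speciesAt(traj, "Z_lo", 0.5), 9.5)
  tot <- trajValues(traj)[, "Z_hi"] + trajValues(traj)[, "Z_lo"] +
    trajValues(traj)[, "lambda"]
  expect_equal(max(abs(tot - 10)), 0, tolerance = 1e-6)
})

test_that("arbiter resolves the present input and is mirror-symmetric", {
  a1 <- buildArbiter(output = "lambda"); initialCounts(a1) <- c(X_hi = 5)
  a0 <- buildArbiter(output = "lambda"); initialCounts(a0) <- c(X_lo = 5)
  t1 <- simulateODE(a1, 1)
  t0 <- simulateODE(a0, 1)
  expect_gt(speciesAt(t1, "Y_hi", 0.4), 9.5)
  expect_equal(trajValues(t1)[, "Y_hi"], trajValues(t0)[, "Y_lo"],
               tolerance = 1e-8, ignore_attr = TRUE)
  # no input, no catalyst: the undecided pool never moves
  idle <- buildArbiter(output = "lambda")
  expect_true(all(trajValues(simulateODE(idle, 1))[, "lambda"] == 10))
})

test_that("the C-element satisfies its contract on all assignments and states", {
  sweep <- sweepTruthTable("C", horizon = 5)
  expect_true(all(sweep$pass))
})

test_that("the C-element is reusable: swapping both inputs flips the output", {
  ce <- buildCElement(x = 1, y = 1, output = 0)
  ce <- addInjection(ce, 2, c("X_hi -> X_lo", "Y_hi -> Y_lo"))
  traj <- simulateODE(ce, 8)
  expect_gt(speciesAt(traj, "Z_hi", 2), 9.5)    # committed high first
  expect_gt(speciesAt(traj, "Z_lo", 8), 9.5)    # then flipped low
})

test_that("latches store, hold and reset", {
  for (kind in c("simple", "with_reset")) {
    l <- buildLatch(kind, input = 1, output = 0)
    traj <- simulateODE(l, 1)
    expect_gt(speciesAt(traj, "Y_hi", 0.5), 9.3)
  }
  # holding: no input present, last state retained
  l <- buildLatch("simple", input = NA, output = 1)
  expect_true(all(trajValues(simulateODE(l, 5))[, "Y_hi"] == 10))
  # reset drains both rails into the neutral pool
  l <- buildLatch("with_reset", input = NA, output = 1, reset = 1)
  traj <- simulateODE(l, 3)
  expect_lt(speciesAt(traj, "Y_hi", 3), 0.5)
  expect_gt(speciesAt(traj, "lambda", 3), 9.5)
  expect_true(is.na(signalValue(traj, "Y", 3)))  # neutral state: no value
})

test_that("the fork splits a signal into two equal branches", {
  f <- buildFork(input = 1)
  traj <- simulateODE(f, 1)
  expect_gt(speciesAt(traj, "Y1_hi", 0.6), 9.5)
  expect_equal(trajValues(traj)[, "Y1_hi"], trajValues(traj)[, "Y2_hi"],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the join requires both inputs", {
  j <- buildJoin(x1 = 1, x2 = 1)
  expect_gt(speciesAt(simulateODE(j, 3), "Y_hi", 3), 9.5)
  j1 <- buildJoin(x1 = 1)          # one input only: chain stalls
  traj <- simulateODE(j1, 5)
  expect_lt(max(trajValues(traj)[, "Y_hi"]), 8)
})

test_that("the lambda sink converts outputs unless an input holds them", {
  s <- buildLambdaSink(Y_hi = 5, lambda = 5)
  traj <- simulateODE(s, 5)
  expect_lt(speciesAt(traj, "Y_hi", 5), 0.5)
  expect_gt(speciesAt(traj, "lambda", 5), 9.5)
  # no lambda and no input: deadlock, nothing moves
  s <- buildLambdaSink(Y_hi = 10, lambda = 0)
  expect_true(all(trajValues(simulateODE(s, 2))[, "Y_hi"] == 10))
  # input present: lambda is recruited to the matching rail
  s <- buildLambdaSink(input = 1, lambda = 10)
  expect_gt(max(trajValues(simulateODE(s, 2))[, "Y_hi"]), 5)
})

test_that("a one-stage pipeline is a single C-element between Req and Acc", {
  p <- buildPipeline(1, req = 1)
  expect_equal(outputRails(p), "A")
  traj <- simulateODE(p, 2)
  expect_gt(speciesAt(traj, "A_hi", 1), 9.5)
})

test_that("the full adder implements its arithmetic on all carry-relevant rows", {
  cases <- list(c(1, 0, 0, 1, 0),   # a, b, cin, sum, cout
                c(1, 1, 0, 0, 1),
                c(1, 1, 1, 1, 1),
                c(0, 0, 0, 0, 0),
                c(0, 1, 1, 0, 1))
  for (cs in cases) {
    fa <- buildFullAdder(a = cs[1], b = cs[2], cin = cs[3])
    traj <- simulateODE(fa, 8)
    expect_equal(signalValue(traj, "Sum", 8), cs[4],
                 label = paste("sum of", paste(cs[1:3], collapse = "+")))
    expect_equal(signalValue(traj, "Cout", 8), cs[5],
                 label = paste("carry of", paste(cs[1:3], collapse = "+")))
  }
})

test_that("queue latches load strictly after their stage controls", {
  q <- buildQueue(3, am = 1, req = 1)
  q <- addInjection(q, 1.5, "Am_hi -> Am_lo")
  traj <- simulateODE(q, 8, times = seq(0, 8, length.out = 801))
  firstUp <- function(s) {
    tt <- trajTimes(traj)[trajValues(traj)[, s] >= 8]
    if (length(tt)) min(tt) else NA_real_
  }
  expect_gt(firstUp("Ams_hi"), firstUp("A_hi"))
  expect_gt(firstUp("Bms_hi"), firstUp("B_hi"))
  expect_gt(firstUp("Cms_hi"), firstUp("C_hi"))
  # the 1 is later displaced by the injected 0: rise-then-fall oscillation
  expect_gt(max(trajValues(traj)[, "Ams_hi"]), 8)
  expect_lt(speciesAt(traj, "Ams_hi", 8), 2)
  # with no request, no control fires and no latch output rises
  idle <- buildQueue(2, am = 1, req = NA)
  expect_lt(max(trajValues(simulateODE(idle, 3))[, "Ams_hi"]), 0.5)
})
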
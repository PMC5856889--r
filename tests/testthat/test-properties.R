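# Temporal property parsing and Monte-Carlo estimation.

test_that("the property mini-language parses all three forms", {
  p <- parseProperty("P[ (B_hi < 8) U[0,3] (A_hi > 8) ]")
  expect_equal(p$form, "U")
  expect_equal(p$a$species, "B_hi")
  expect_equal(p$b$level, 8)
  expect_equal(c(p$t1, p$t2), c(0, 3))
  p <- parseProperty("P[ F[0,10] C_hi > 8 ]")
  expect_equal(p$form, "F")
  expect_equal(p$a$species, "C_hi")
  p <- parseProperty("P[ G[0.5,5] X_hi >= 2 ]")
  expect_equal(p$form, "G")
  expect_equal(p$t1, 0.5)
  expect_error(parseProperty("P[ nonsense ]"), "cannot parse")
  expect_warning(boundedUntil(propAtom("A", ">", 1), propAtom("B", ">", 1),
                              2, 2), "vacuous")
})

test_that("path formulas are decided exactly on handcrafted jump paths", {
  # A rises at t=1, B rises at t=2; piecewise-constant path
  path <- stepPath(c(0, 1, 2),
                   matrix(c(0, 10, 10,
                            0, 0, 10), 3, 2,
                          dimnames = list(NULL, c("A", "B"))))
  ev <- function(txt) CRNlogic:::.holdsOnPath(parseProperty(txt), path, 5)
  expect_true(ev("P[ F[0,5] A > 8 ]"))
  expect_false(ev("P[ F[0,0.5] A > 8 ]"))
  expect_true(ev("P[ (B < 8) U[0,3] (A > 8) ]"))   # A first, B later
  expect_false(ev("P[ (A < 8) U[0,3] (B > 8) ]"))  # A violates before B
  expect_true(ev("P[ G[2.5,5] B > 8 ]"))
  expect_false(ev("P[ G[0,5] B > 8 ]"))
  # witness inside the window even though the atom held earlier
  expect_true(ev("P[ (B < 8) U[1.5,3] (A > 8) ]"))
})

test_that("a tautological eventually has estimate 1 on any network", {
  res <- estimateProperty(buildMotif(input = 1),
                          boundedEventually(propAtom("Y_hi", ">=", 0), 0, 1),
                          nPaths = 5, seed = 2)
  expect_equal(res$estimate, 1)
})

test_that("monotone reachability agrees with the deterministic indicator", {
  # the motif is absorbing at full conversion, so the SSA estimate of
  # eventually-high matches the ODE outcome (probability one)
  res <- estimateProperty(buildMotif(input = 1),
                          "P[ F[0,2] Y_hi > 8 ]", nPaths = 40, seed = 6)
  expect_equal(res$estimate, 1)
  expect_true(res$ci[1] > 0.85)
  expect_equal(length(res$satisfied), 40L)
})
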
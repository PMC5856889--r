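# PRISM CTMC export: structure, rate expressions, and a distributional
# cross-check of the exported model against the native SSA engine.

test_that("the motif exports with conserved bounds and product rates", {
  txt <- exportPrism(buildMotif(input = 1))
  expect_match(txt, "^ctmc")
  expect_match(txt, "X_hi : \\[0..10\\] init 10;")
  expect_match(txt, "Y_lo : \\[0..10\\] init 10;")
  expect_match(txt, "X_hi\\*Y_lo", all = FALSE)
  expect_match(txt, "endmodule")
})

test_that("a paired reactant exports the falling-factorial rate", {
  txt <- exportPrism(parseCRN("init A 6\nA + A -> A + B"), bounds = c(B = 6))
  expect_match(txt, "A\\*\\(A-1\\)")
})

test_that("species without a conservation bound must be bounded explicitly", {
  net <- parseCRN("init A 4\nA -> A + B")    # B is created without bound
  expect_error(exportPrism(net), "no bound")
  expect_match(exportPrism(net, bounds = c(B = 8)), "B : \\[0..8\\]")
})

test_that("a network with no reactions exports a valid absorbing module", {
  txt <- exportPrism(inertNetwork(c(A = 3)), bounds = c(A = 3))
  expect_match(txt, "A : \\[0..3\\] init 3;")
  expect_false(grepl("\\[\\]", txt))
})

## minimal independent CTMC simulator over the exported text: parses the
## guarded commands and samples with R's exponential clocks.  This exercises
## the exported rate expressions through a separate code path.
simulateExported <- function(txt, horizon, seed) {
  lines <- strsplit(txt, "\n")[[1]]
  decls <- regmatches(lines, regexec(
    "^  (\\w+) : \\[0\\.\\.(\\d+)\\] init (\\d+);", lines))
  decls <- Filter(length, decls)
  state <- setNames(as.numeric(vapply(decls, `[`, character(1), 4)),
                    vapply(decls, `[`, character(1), 2))
  cmds <- regmatches(lines, regexec(
    "^  \\[\\] (.*) -> (.*) : (.*);$", lines))
  cmds <- Filter(length, cmds)
  guards <- lapply(cmds, function(m)
    parse(text = gsub("&", "&&", m[2]))[[1]])
  rates <- lapply(cmds, function(m) parse(text = m[3])[[1]])
  upds <- lapply(cmds, function(m) {
    pieces <- strsplit(m[4], "\\)\\s*&\\s*\\(")[[1]]
    pieces <- gsub("[()']", "", pieces)
    do.call(rbind, lapply(strsplit(pieces, "="), function(p)
      data.frame(var = p[1], expr = p[2])))
  })
  set.seed(seed)
  t <- 0
  repeat {
    env <- as.list(state)
    a <- vapply(seq_along(cmds), function(j)
      if (isTRUE(eval(guards[[j]], env))) eval(rates[[j]], env) else 0,
      numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t > horizon) break
    j <- sample.int(length(a), 1, prob = a)
    for (r in seq_len(nrow(upds[[j]])))
      state[upds[[j]]$var[r]] <- eval(parse(text = upds[[j]]$expr[r]),
                                      as.list(state))
  }
  state
}

test_that("the exported CTMC matches the native SSA distribution", {
  m <- buildMotif(input = 1)
  txt <- exportPrism(m)
  n <- 400
  native <- vapply(seq_len(n), function(i)
    unname(speciesAt(simulateSSA(m, 0.4, seed = i), "Y_hi", 0.4)),
    numeric(1))
  exported <- vapply(seq_len(n), function(i)
    simulateExported(txt, 0.4, seed = 10000 + i)[["Y_hi"]], numeric(1))
  ks <- suppressWarnings(stats::ks.test(native, exported))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(native) - mean(exported)), 1)
})
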
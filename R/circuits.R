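## Larger structures: Muller C-pipeline, queue, full and ripple-carry adder.

## C-element embedded under a stage prefix with explicit port species.
## The attacking ports (xh/xl) receive the inverted acknowledge signal, the
## amplifying ports (yh/yl) the forward data signal.
.cElementLines <- function(xh, xl, yh, yl, zBase, prefix) {
  wb <- paste0(prefix, "w")
  wh <- paste0(wb, "_hi"); wl <- paste0(wb, "_lo")
  lam1 <- paste0(prefix, "lambda1")
  c(.cat(xh, wl, lam1), .cat(wh, wl, lam1),
    .cat(xl, wh, lam1), .cat(wl, wh, lam1),
    .cat(yh, lam1, wh), .cat(wh, lam1, wh),
    .cat(yl, lam1, wl), .cat(wl, lam1, wl),
    .arbiterLines(wb, zBase, paste0(prefix, "lambda2")))
}

## pipeline reaction lines + neutral initial pools; stage outputs are the
## rails A, B, C, ...
##
## Between consecutive C-elements sits a fork on the stage output: one path
## carries the data forward into the next element, the other is crossed
## (dual-rail NOT is a wire swap) and fed back as the acknowledge of the
## element one position upstream.  Each fork path is an amplifying
## (arbiter-style) buffer with its own undecided pool, so -- like the
## C-elements themselves -- it asserts nothing until its driver commits;
## this is also what spaces the stages far enough apart that their
## first-passage ordering is robust under the stochastic semantics.
.pipelineLines <- function(nStages) {
  stages <- LETTERS[seq_len(nStages)]
  lines <- character(0)
  inits <- numeric(0)
  for (i in seq_len(nStages)) {
    pre <- paste0(stages[i], ".")
    dat <- if (i == 1) "Req" else paste0(stages[i - 1], ".fwd")
    ack <- if (i == nStages) "Acc"
           else if (i == nStages - 1) stages[nStages]
           else paste0(stages[i + 1], ".bck")
    lines <- c(lines,
               .cElementLines(xh = paste0(ack, "_lo"),   # inverted feedback
                              xl = paste0(ack, "_hi"),
                              yh = paste0(dat, "_hi"),   # forward data
                              yl = paste0(dat, "_lo"),
                              zBase = stages[i], prefix = pre))
    inits[paste0(pre, "lambda1")] <- 10
    inits[paste0(pre, "lambda2")] <- 10
    if (i < nStages) {       # fork on this stage's output
      for (path in c("fwd", "bck")) {
        pool <- paste0(pre, path, ".lambda")
        lines <- c(lines, .arbiterLines(stages[i], paste0(pre, path), pool))
        inits[pool] <- 10
      }
    }
  }
  list(lines = lines, inits = inits, stages = stages)
}

#' Muller C-pipeline
#'
#' \code{nStages} C-elements in series implementing the four-phase
#' request/acknowledge handshake.  Each stage amplifies the output of its
#' predecessor (stage 1: the \code{Req} rails) and receives the inverted
#' output of its successor as acknowledge; the inversion is a rail crossing
#' in the wiring, which costs no reactions (dual-rail NOT is a wire swap).
#' The last stage's acknowledge port is the crossed environment signal
#' \code{Acc}.
#'
#' All C-elements start neutral (both internal groups in their undecided
#' lambda pools), so no stage asserts an output until its data arrives; with
#' \code{req = 1} the stage outputs A, B, C, ... rise strictly one after
#' another.  Converting the request afterwards (e.g.
#' \code{addInjection(p, 1, "Req_hi -> Req_lo")}) releases the stages in the
#' same order.
#'
#' @param nStages number of C-elements (>= 1)
#' @param req initial request value (0, 1, NA)
#' @param acc initial acknowledge value; the default 1 models a receiver
#'   that is always ready, without which the final stage can latch but never
#'   be released
#' @param M signal amplitude
#' @return a [DualRailCircuit-class] with inputs Req, Acc and one output
#'   signal per stage
#' @export
buildPipeline <- function(nStages = 3, req = NA, acc = 1, M = 10) {
  if (nStages < 1) stop("nStages must be >= 1")
  pl <- .pipelineLines(nStages)
  inits <- pl$inits / 10 * M
  .mkCircuit(pl$lines,
             c(.railInit("Req", req, M), .railInit("Acc", acc, M), inits),
             inputs = c("Req", "Acc"), outputs = pl$stages, M = M)
}

## gated storage element for the queue: data is staged from the undecided
## pool whenever present, committed to the output rails only while the
## stage-control catalyst G is high, and the committed rails displace each
## other back into the pool so a newly loaded value replaces the old one.
.queueLatchLines <- function(dBase, yBase, ctrl) {
  lam <- paste0(yBase, ".lambda")
  p1 <- paste0(yBase, ".p1"); p0 <- paste0(yBase, ".p0")
  yh <- paste0(yBase, "_hi"); yl <- paste0(yBase, "_lo")
  c(.cat(paste0(dBase, "_hi"), lam, p1),
    .cat(ctrl, p1, yh),
    .cat(paste0(dBase, "_lo"), lam, p0),
    .cat(ctrl, p0, yl),
    ## a changed data value withdraws the stale committed rail and any
    ## stale staged vote into the pool (so reloading is possible at all);
    ## the new rail still cannot rise before the stage control commits it
    .cat(paste0(dBase, "_hi"), yl, lam),
    .cat(paste0(dBase, "_lo"), yh, lam),
    .cat(paste0(dBase, "_hi"), p0, lam),
    .cat(paste0(dBase, "_lo"), p1, lam),
    .cat(yh, yl, lam),
    .cat(yl, yh, lam))
}

#' Asynchronous queue
#'
#' A [buildPipeline()] control pipeline with one gated storage latch per
#' stage.  The data signal \code{Am} is read into the first latch
#' (output \code{Ams}) when the first C-element fires, and each subsequent
#' latch copies its predecessor's output when its own stage control rises,
#' so a value entered at the head travels one latch per handshake wave.  No
#' latch output can rise before its stage control.
#'
#' @inheritParams buildPipeline
#' @param am initial data value (0, 1, NA)
#' @return a [DualRailCircuit-class]; latch outputs are \code{Ams},
#'   \code{Bms}, \code{Cms}, ...
#' @export
buildQueue <- function(nStages = 3, am = NA, req = NA, acc = 1, M = 10) {
  if (nStages < 1) stop("nStages must be >= 1")
  pl <- .pipelineLines(nStages)
  lines <- pl$lines
  inits <- pl$inits / 10 * M
  latches <- paste0(pl$stages, "ms")
  for (i in seq_len(nStages)) {
    dat <- if (i == 1) "Am" else latches[i - 1]
    lines <- c(lines, .queueLatchLines(dat, latches[i],
                                       paste0(pl$stages[i], "_hi")))
    inits[paste0(latches[i], ".lambda")] <- M
  }
  .mkCircuit(lines,
             c(.railInit("Am", am, M), .railInit("Req", req, M),
               .railInit("Acc", acc, M), inits),
             inputs = c("Am", "Req", "Acc"),
             outputs = c(pl$stages, latches), M = M)
}

## gate network of one full adder over given input rail bases; returns
## list(lines, inits)
.fullAdderLines <- function(in1, in2, cin, sumBase, coutBase, prefix, M) {
  x1 <- paste0(prefix, "x1")
  g1 <- paste0(prefix, "g1")
  g2 <- paste0(prefix, "g2")
  parts <- list(
    .gateLines("XOR", in1, in2, x1, paste0(prefix, "xor1."), z0 = NA, M = M),
    .gateLines("XOR", x1, cin, sumBase, paste0(prefix, "xor2."), z0 = NA,
               M = M),
    .gateLines("AND", in1, in2, g1, paste0(prefix, "and1."), z0 = 0, M = M),
    .gateLines("AND", cin, x1, g2, paste0(prefix, "and2."), z0 = 0, M = M),
    .gateLines("OR", g1, g2, coutBase, paste0(prefix, "or."), z0 = 0, M = M))
  list(lines = unlist(lapply(parts, `[[`, "lines")),
       inits = do.call(c, lapply(parts, `[[`, "inits")))
}

#' One-bit full adder
#'
#' Composed from two XOR gates (sum), two AND gates and an OR gate (carry):
#' \code{Sum = A1 xor A2 xor Cin}, \code{Cout = (A1 and A2) or (Cin and (A1
#' xor A2))}.  All wiring is catalytic species identification; the gates
#' respond to later input changes, so a late-settling carry input corrects
#' the outputs.
#'
#' @param a,b,cin initial input bits (0, 1, NA)
#' @param M signal amplitude
#' @return a [DualRailCircuit-class] with inputs A1, A2, Cin and outputs
#'   Sum, Cout
#' @export
buildFullAdder <- function(a = NA, b = NA, cin = 0, M = 10) {
  fa <- .fullAdderLines("A1", "A2", "Cin", "Sum", "Cout", "fa.", M)
  .mkCircuit(fa$lines,
             c(.railInit("A1", a, M), .railInit("A2", b, M),
               .railInit("Cin", cin, M), fa$inits),
             inputs = c("A1", "A2", "Cin"), outputs = c("Sum", "Cout"),
             M = M)
}

#' Ripple-carry adder controlled by a C-pipeline
#'
#' \code{nBits} full adders in series: the carry output of each adder feeds
#' the next adder's carry input, and a [buildPipeline()] of the same length
#' provides control.  Each stage's operand rails are loaded (converted from
#' their source species) only when the stage's C-element output rises, so
#' each sum is produced in its pipeline stage, strictly after the stage
#' control -- which gives the preceding adder's carry time to settle.
#'
#' @param nBits number of adder stages (>= 1)
#' @param a,b integer vectors of bits (length \code{nBits}, least
#'   significant first); the default encodes the worked example 0+1, 1+1,
#'   1+1
#' @param M signal amplitude
#' @return a [DualRailCircuit-class]; outputs are the per-stage sums
#'   \code{A.sum}, \code{B.sum}, ..., the final \code{Carry} and the stage
#'   controls A, B, C, ...
#' @export
buildRippleCarryAdder <- function(nBits = 3, a = c(0, 1, 1), b = c(1, 1, 1),
                                  M = 10) {
  if (nBits < 1) stop("nBits must be >= 1")
  stopifnot(length(a) == nBits, length(b) == nBits)
  pl <- .pipelineLines(nBits)
  lines <- pl$lines
  inits <- pl$inits / 10 * M
  inits <- c(inits, .railInit("Req", 1, M), .railInit("Acc", 1, M))
  for (s in seq_len(nBits)) {
    P <- pl$stages[s]
    pre <- paste0(P, ".")
    ctrl <- paste0(P, "_hi")
    ## operand sources and control-gated loading
    for (o in 1:2) {
      src <- paste0(pre, "a", o)
      dst <- paste0(pre, "in", o)
      bit <- if (o == 1) a[s] else b[s]
      inits <- c(inits, .railInit(src, bit, M), .railInit(dst, NA, M))
      lines <- c(lines,
                 .cat(ctrl, paste0(src, "_hi"), paste0(dst, "_hi")),
                 .cat(ctrl, paste0(src, "_lo"), paste0(dst, "_lo")))
    }
    cin <- paste0(pre, "cin")
    if (s == 1) inits <- c(inits, .railInit(cin, 0, M))
    cout <- if (s == nBits) "Carry" else paste0(pl$stages[s + 1], ".cin")
    fa <- .fullAdderLines(paste0(pre, "in1"), paste0(pre, "in2"), cin,
                          paste0(pre, "sum"), cout, pre, M)
    lines <- c(lines, fa$lines)
    inits <- c(inits, fa$inits)
  }
  .mkCircuit(lines, inits,
             inputs = c("Req", "Acc"),
             outputs = c(pl$stages, paste0(pl$stages, ".sum"), "Carry"),
             M = M)
}
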
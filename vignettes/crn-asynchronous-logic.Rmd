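---
title: "Asynchronous logic circuits as chemical reaction networks: models, designs and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronous logic circuits as chemical reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CRNlogic)
```

# The modelling problem

A chemical reaction network (CRN) is a finite set of species
$\Lambda$ and reactions $\tau = (r_\tau, p_\tau, k_\tau)$: reactant and
product count vectors plus a positive rate coefficient.  CRNlogic restricts
itself to uni- and bi-molecular reactions, and every circuit it ships is
built from *catalytic conversions* $X + Y \to X + Z$: the catalyst $X$ is
unchanged while one molecule of $Y$ becomes $Z$.  Because every shipped
reaction has two reactant and two product molecules, the total molecule
count — and the total of each signal group — is an exact invariant, which
the test suite uses as a cross-engine oracle.

Boolean signals are carried by *dual-rail* species pairs
$(X_\mathrm{hi}, X_\mathrm{lo})$: logic 1 is a populated hi rail, logic 0 a
populated lo rail, and a correct circuit never stabilises with both
populated.  A high rail is read as asserted when its mean exceeds
$0.8\,M - \mathrm{SD}$ and a low rail as clear when its mean is below
$0.2\,M + \mathrm{SD}$, where $M$ is the signal amplitude (10 molecules
throughout) and SD is the standard deviation of the read (zero under the
deterministic semantics).  At $M = 10$ the high threshold is the familiar
8 molecules.

## The three semantics

*Deterministic.*  Concentrations $\Phi(t)$ follow the mass-action rate
equations
$\dot\Phi = \sum_\tau \upsilon_\tau\, k_\tau \prod_i \Phi_i^{r_{\tau,i}}$
with net change $\upsilon_\tau = p_\tau - r_\tau$, solved by `lsoda`
(deSolve) at `rtol = 1e-8`, `atol = 1e-10`.  The networks are non-stiff at
this scale (tens of molecules, unit rates), so an implicit/explicit
switching solver resolves them essentially to machine precision.

*Stochastic.*  Molecule counts evolve as a continuous-time Markov chain
with propensities
$\alpha_\tau(x) = k_\tau \frac{\prod_i r_{i,\tau}!}{N^{|r_\tau|-1}}
\prod_i \binom{x_i}{r_{i,\tau}}$ and transition rate $N\alpha_\tau(x)$.
`simulateSSA()` samples exact jump paths with the Gillespie direct method:
reactions are scanned in declaration order, each jump consumes two
uniforms (waiting time, cumulative-sum inversion for the index), and R's
Mersenne–Twister seeded once per path makes every path bit-reproducible.
`meanOverPaths()` derives path $i$'s seed as `seed + i - 1`.

*Linear noise approximation.*  $Y = N\Phi + \sqrt{N}Z$ where $Z$ is a
zero-mean Gaussian process whose covariance obeys
$\dot C = J C + C J^\top + W$ from $C(0) = 0$, with $J$ the analytic
Jacobian of the drift and
$W = \sum_\tau \upsilon_\tau \upsilon_\tau^\top k_\tau \prod_S
\Phi_S^{r_{S,\tau}}$.  Mean and covariance are integrated jointly; the
covariance is symmetrised each step, diagonal entries below $-10^{-9}$
raise an error and smaller negative ones clamp to zero.  By construction
the LNA mean equals the deterministic solution, which the tests check to a
sup-norm of $10^{-6}$.

All rate coefficients default to 1 and the volumetric factor to $N = 1$,
so counts and concentrations coincide; time is in seconds.  These are the
conventions under which all quoted convergence times below hold.

# The Approximate-Majority motif and the Muller C-element

The conversion motif
$\{X_\mathrm{hi} + Y_\mathrm{lo} \to X_\mathrm{hi} + Y_\mathrm{hi},\;
X_\mathrm{lo} + Y_\mathrm{hi} \to X_\mathrm{lo} + Y_\mathrm{lo}\}$
copies the input value onto the output.  Driven by a full input rail the
output converges as $10(1 - e^{-10t})$, i.e. to within 2% of full
amplitude by 0.4 s:

```{r}
m <- buildMotif(input = 1)
speciesAt(simulateODE(m, 1), "Y_hi", 0.4)
```

Bistable switching comes from the Approximate Majority (AM) pattern: two
populations convert each other into an undecided intermediary
$\lambda$, which either side recruits.  The dual-rail AM circuit
(`buildDualRailAM()`) drives an output pair $Z$ from two input signals.
Its catalytic arcs are, in the package's transcription:

* the X rails *attack*: $X_\mathrm{hi}$ catalyses
  $Z_\mathrm{lo} \to \lambda$ and $X_\mathrm{lo}$ catalyses
  $Z_\mathrm{hi} \to \lambda$;
* the Y rails *amplify*: $Y_\mathrm{hi}$ catalyses
  $\lambda \to Z_\mathrm{hi}$, $Y_\mathrm{lo}$ catalyses
  $\lambda \to Z_\mathrm{lo}$;
* the Z rails do both, so the current majority reinforces itself.

This split was a genuinely open transcription choice (the printed circuit
is a diagram); the deciding evidence is the published failure mode.  On
the conflicting assignment $X = 0, Y = 1$ with $Z$ committed high the
design above has the analytic fixed point
$Z_\mathrm{hi}^* = (\sqrt{500}-10)/2 \approx 6.18$,
$\lambda^* \approx 3.82$, $Z_\mathrm{lo}^* = 0$ — matching the quoted
6-and-4-molecule mixed state, whereas the fully symmetric transcription
(every rail both attacking and amplifying) converges to the symmetric
point $10/3$ on all three species and cannot reproduce it:

```{r}
tr <- simulateODE(buildDualRailAM(x = 0, y = 1, output = 1), 0.5)
c(Z_hi = speciesAt(tr, "Z_hi", 0.3), lambda = speciesAt(tr, "lambda", 0.3))
```

Since 6.18 is below the 8-molecule threshold, a single AM stage fails the
C-element contract.  `buildCElement()` therefore composes two AM stages in
series (`composeSeries()` wires the first stage's output pair into the
second as the shared internal pair `lambda.w1`): the first stage computes
the input consensus, the second — an `buildArbiter()`-style amplifier —
restores full amplitude and suppresses the residual $\lambda$.  The first
stage's rail group is initialised to mirror the declared output state (the
element remembers its last committed value); with that memory state the
attack rate on the held rail under conflicting inputs is exactly zero, so
the "unchanged" rows of the C-element contract hold to machine precision.
`sweepTruthTable("C")` exercises all four assignments from both initial
output states.

# Components

*Latches.*  The simple latch is the motif plus mutually antagonistic
feedback (each output rail catalyses the conversion of the other into
itself); the feedback cancels deterministically but stabilises the
committed state stochastically.  The reset latch is AM-shaped around a
central undecided pool and adds a reset rail that drains both outputs into
it.  From input high/output low both designs reach full output by about
0.5 s; neither can reach it by 0.2 s, because a single catalytic
conversion at unit rates and amplitude 10 is rate-limited to
$10\,\mathrm{s}^{-1}$ ($10(1-e^{-2}) \approx 8.6$ molecules at 0.2 s).
The package reports the faster design's value as measured rather than
adopting a rate convention that would contradict the motif timing.

*Gates.*  NOT is a crossed motif.  AND, OR, NAND and NOR share a
two-route template: a conjunctive two-step chain
($c_1: \lambda_2 \to \lambda_1$, then $c_2: \lambda_1 \to P$) detects the
one assignment that must assert output $P$, a disjunctive route (either
catalyst converts $\lambda_3 \to Q$) asserts the complement, and the
output rails suppress each other back into the opposite source pools,
which both enforces dual-rail exclusivity and refills the pools so the
gates are reusable.  A staged $\lambda_1$ whose second catalyst is absent
is returned to its pool by the *complementary* rail — without this
reverse arc a stale staged vote from an earlier input epoch could fire
later and corrupt the output.  Pools are sized so each conserved output
group totals $M$.  XOR detects all four minterms with two-step chains in
both catalyst orders, drawn from one shared hi-source and one shared
lo-source pool; the both-order chains double the throughput, giving
$Z_\mathrm{lo}(0.4\,\mathrm{s}) \approx 9.6$ on inputs $(0,0)$, and the
same reverse-arc rule plus output suppression makes the gate reusable.

*Control flow.*  The fork duplicates a signal through two parallel motifs
(under deterministic semantics the branches are exactly equal — the CRN
analogue of an isochronous fork); the join asserts an output only when
both inputs agree, via conjunctive chains per polarity.

# Pipeline, queue, adder

`buildPipeline(n)` places $n$ C-elements in series.  Stage $i$ receives
its predecessor's output (stage 1: the request rails) on the amplifying
port and the *inverted* output of its successor (stage $n$: the
environment's acknowledge) on the attacking port; inversion is a rail
crossing in the wiring, costing no reactions.  Between consecutive
elements sits a fork on the stage output: one path carries the data
forward, the other is crossed and fed back as the upstream acknowledge.
Each fork path is an amplifying buffer with its own undecided pool, so no
wire asserts a value before its driver commits, and the buffer delay
spaces the stages far enough apart that the first-passage ordering
$t(A_\mathrm{hi}) < t(B_\mathrm{hi}) < t(C_\mathrm{hi})$ holds not just
deterministically but in at least 19 of 20 SSA paths.

Two environment conventions required a decision.  First, the scenario that
exercises the pipeline sets the acknowledge input to "receiver ready"
(`acc = 1`); with no acknowledgement at all the final C-element can latch
its value but never be released, and the published release of the last
stage would be impossible.  Second, signal changes are injected as
scheduled reactions (`addInjection(p, 1, "Req_hi -> Req_lo")`), treated by
all engines as a piecewise network redefinition.  At unit rate the
injected conversion has a one-second time constant, so the request
majority only tips about $0.69$ s after the injection; the three stages
then release strictly in order, completing shortly *after* the nominal
2 s mark (about 1.9/2.4/2.9 s).  The package reports these times as
computed; meeting a 2 s completion under unit-rate injection would require
a faster conversion than the uniform-rate convention supports.

`buildQueue(n)` adds one gated storage latch per stage: data is staged
from the latch's undecided pool whenever present, committed to the output
rails only while the stage control is high, and a changed data value
withdraws the stale rail back into the pool.  A value entered at the head
therefore travels one latch per handshake wave, and no latch output can
rise before its stage control — the oscillatory rise-then-fall of the
latch outputs when a 1 is followed by a 0 is checked in the `queue`
scenario.

`buildRippleCarryAdder(n)` composes $n$ full adders (two XOR, two AND and
one OR gate each: sum $= a \oplus b \oplus c_\mathrm{in}$, carry
$= ab + c_\mathrm{in}(a \oplus b)$) with the carry of each stage feeding
the next, control-interleaved with a pipeline of the same length: operand
rails are loaded by control-catalysed conversions only when the stage
fires, so each sum rises strictly after its stage control and the
preceding carry has time to settle; a late-correcting carry is absorbed
by the gates' reusability.  The textbook carry decomposition is used
because it is the one whose outputs satisfy the worked 3-bit example
(0+1, 1+1, 1+1 giving sums 1, 0, 1 with final carry 1), which the
`adder` scenario checks end to end.

```{r}
runScenario("adder")$checks
```

# Validation machinery

`sweepTruthTable()` simulates a component for every Boolean input
assignment (and initial state where relevant) and reads the outputs
through the thresholds; undefined outputs are reported, never coerced.
`firstPassage()` measures debounced threshold crossings (the predicate
must hold through the horizon).  `estimateProperty()` evaluates
time-bounded eventually/until/globally formulas exactly on SSA jump paths
(no grid aliasing) and returns a Monte-Carlo estimate with a
Clopper–Pearson interval; the default sample size of 20 paths matches the
published verification protocol, which is why estimates are reported at a
granularity of $1/20$.  `exportPrism()` writes the induced CTMC as a
PRISM model, with species bounds taken from the conservation laws; the
test suite cross-checks the exported rate expressions by re-simulating
the exported text with an independent interpreter and comparing output
distributions (two-sample KS test at $\alpha = 0.01$).

# What the tests do and do not show

All quantitative checks run at the study conditions: amplitude 10
molecules, unit rates, $N = 1$, horizons up to 10 s, 20-path ensembles
(200 paths where a mean is compared against the ODE at 3 standard
errors).  Problem sizes range from 4 species (motif) to about 180 (3-bit
adder with control pipeline).  Within these conditions the designs are
validated against their behavioural contracts under all three semantics —
but this is simulation-based validation over all *input* configurations,
not formal verification over all reachable states, and it says nothing
about physical realisations (leak reactions, crosstalk, rate dispersion
in DNA-strand-displacement implementations) or about scaling to
amplitudes far from 10, where the LNA's Gaussian error itself changes.

# Known limitations

* The latch 0.2 s convergence figure and the pipeline's full release by
  2 s are not reproducible under the uniform-rate convention (see the
  timing analyses above); the package reports the measured values.
* XOR's minterm pools are refilled through output suppression, so
  unlike the monotone gates the XOR recovers full amplitude only while
  one of its minterms remains actively catalysed.
* `conservedTotals()` enumerates integer weightings only for networks
  with at most 8 species when the single-conversion shortcut does not
  apply; all shipped components use the shortcut.
* The CTMC is analysed by sampling (SSA) or export to PRISM; no native
  numerical solution of the chemical master equation is provided.
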
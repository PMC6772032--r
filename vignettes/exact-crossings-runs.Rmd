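---
title: "Exact joint distributions of crossings and longest runs"
author: "CrossingRuns package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact joint distributions of crossings and longest runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossingRuns)
```

## The setting

Consider $n$ independent Bernoulli observations with success probability
$p$ (failure probability $q = 1 - p$).  In statistical process control these
are the *useful observations* of a run chart: points above (success) or
below (failure) a centre line determined from previous data, with points on
the line discarded.  Two statistics summarize the randomness of such a
chart:

* the number of **crossings** $C$ — adjacent pairs of unequal observations,
  $c = 0, \dots, n - 1$;
* the **longest run** $L$ — the longest stretch of identical observations,
  $l = 1, \dots, n$.

In the symmetric case $C$ is Binomial$(n-1, 1/2)$, and recursions exist for
the distribution of $L$ alone, but run-chart rules condition on both
statistics at once, so their joint distribution
$P_n(C = c, L = l)$ is what is needed.  This package computes that joint
distribution exactly, for constant or per-position success probabilities,
and applies it to the Anhoej run-chart rules.

## The iterative recursion

The computation conditions on the side $S$ of the first observation and
builds the pair of conditional distributions
$P_n(C, L \mid S = 1)$ and $P_n(C, L \mid S = 0)$ iteratively in $n$; the
unconditional distribution is the mixture

$$P_n(C, L) = P_n(C, L \mid S = 1)\,p + P_n(C, L \mid S = 0)\,q.$$

With one observation both conditionals are degenerate at $(c, l) = (0, 1)$.
For longer sequences, partition on the end position $F$ of the first
crossing ($F = f \in 2..n$; $F = 1$ denotes no crossing):

$$P_n(F = 1 \mid S = 1) = p^{\,n-1}, \qquad
  P_n(F = f \mid S = 1) = p^{\,f-2} q,$$

with $p$ and $q$ interchanged given $S = 0$.  Given $F = f \ge 2$, the first
$f - 1$ observations form one run and the remaining $n + 1 - f$ observations
form a chart of the same kind, one step shorter and starting on the
*opposite* side — which is why both conditionals must be carried along.  Two
cases complete the step:

* **Case 1** ($f - 1 \ge n + 1 - f$): the initial run is necessarily
  longest, so the whole crossings marginal of the shorter chart lands in the
  column $l = f - 1$, with $c$ shifted by $+1$ for the first crossing.
* **Case 2** ($f - 1 < n + 1 - f$): mass of the shorter chart with longest
  run $\le f - 1$ lands at $l = f - 1$; mass with longest run
  $l \in f..(n + 1 - f)$ stays at $l$; $c$ again shifts by $+1$.

Every quantity on the right-hand side belongs to a shorter sequence and is
already available, so a single upward sweep over lengths $1..n$ produces the
pair for $n$.  `jointConditional()` implements this sweep,
`combineUnconditional()` the mixture.

## The times representation

Joint probabilities decay like $2^{-(n-1)}$, so the package follows the
convention of storing and displaying weights multiplied by $m^{\,n-1}$ with
$m = 2$ (the *times* representation).  In the symmetric case $p = 1/2$ every
times-scale weight is an exact integer and the full matrix sums to
$2^{\,n-1}$; `symmetricJoint()` computes this case directly, without
conditioning on $S$, because both conditionals coincide and every
first-crossing weight equals 1 on the times scale, leaving pure integer
additions.  `rescale()` moves between the probability and times scales; the
internal representation does not change, so a round trip is exactly the
identity.

## Exact arithmetic

All reference computations use exact rational arithmetic: weights are
arbitrary-precision integer numerators over the common denominator
$\prod_i b_i$ built from the per-trial probability denominators
$p_i = a_i / b_i$.  Large integers are stored as base-$2^{24}$ limb vectors
of doubles (whole matrices as limb arrays), with every intermediate kept
below $2^{53}$ so that double arithmetic is exact; this design vectorizes
across matrix cells and makes the recursion fast without compiled code.

Consequences worth noting:

* Results are bit-exact at every $n$: the symmetric crossings marginal
  equals the binomial coefficients $\binom{n-1}{c}$ *exactly* (verified for
  all $n \le 100$ in the tests, far beyond the $2^{53}$ range of doubles),
  and total masses equal $1$ resp. $m^{\,n-1}$ exactly by construction —
  both are enforced in the `JointPMF` validity method, together with the
  support constraint $\lceil n/(c+1)\rceil \le l \le n - c$.
* A numeric input probability is interpreted through its shortest decimal
  representation (`0.6` becomes $3/5$ exactly); probabilities without a
  terminating decimal form must be passed as fraction strings (`"1/3"`).
* When tables are displayed with a fixed number of decimals the exact
  rationals are rounded **half away from zero** (`jointWeightStrings()`,
  and the `digits` arguments elsewhere).  This convention reproduces the
  published one-decimal $p = 0.6$ table at all 256 cells and the published
  three-decimal specificity table at all 91 sequence lengths, which is the
  strongest evidence available about the rounding used there; exact ties
  cannot arise in the quantities where the convention could matter
  cosmetically (e.g. $\log_2 n + 3$ is never half-integral).
* Serialization (`writeJointCSV()`, `writeJointJSON()`) writes terminating
  decimals where the denominator is of the form $2^a 5^b$ and `num/den`
  fractions otherwise, plus the denominator factorization, so reading back
  is exactly lossless.

A fixed-precision floating-point mode was considered and rejected: the
exact path is fast enough for every supported problem size, and exactness
removes the need for a precision parameter altogether.

## Varying success probabilities

For independent observations with per-position probabilities $p_1..p_n$,
`jointConditionalVarying()` runs the same recursion over *suffixes* of the
probability sequence: conditional on the side of the first observation of
the suffix starting at position $k$, a first crossing ending at position $t$
has weight $\bigl(\prod_{i=k+1}^{t-1} p_i^{(S)}\bigr)(1 - p_t^{(S)})$, where
$p^{(S)}_i$ is the stay-on-side probability, and the remainder is the suffix
starting at $t$ with the opposite start side; the Case 1 / Case 2 logic is
unchanged.  This is the minimal generalization consistent with the constant
case — the observations after the first crossing are literally a suffix of
the observation list.  Because no published formulas exist for this
construction, its correctness evidence is (a) exact reduction to
`jointConditional()` for constant vectors and (b) exact cell-for-cell
agreement with brute-force enumeration over seeded random probability
vectors, both in the test suite.  Note that the construction is
direction-specific: no claim is made that reversing the probability vector
preserves the joint distribution.

## The Anhoej rules

For a run chart with $n$ useful observations the combined Anhoej rules
signal non-random variation when

* **shift rule**: some run is longer than
  $\mathrm{la}(n) = \mathrm{round}(\log_2 n + 3)$, or
* **crossings rule**: there are fewer than $\mathrm{ca}(n)$ crossings, where
  $\mathrm{ca}(n)$ is the lower 5th percentile of Binomial$(n-1, 1/2)$.

`crossingsLimit()` determines the percentile by exact integer comparison:
the smallest $k$ with $20 \sum_{j \le k} \binom{n-1}{j} \ge 2^{\,n-1}$,
i.e. the smallest $k$ with CDF $\ge 0.05$ — the convention of standard
quantile functions (it coincides with `qbinom(0.05, n-1, 0.5)`, which the
tests assert for $n \le 100$).  Alternative readings of "lower 5th
percentile" (strict inequality, or signalling at $C \le k$) fail to
reproduce the published specificity table, so this convention is settled by
that table rather than by fiat.

The **specificity** at length $n$ is the probability that a random
($p = 1/2$) chart does not signal: the mass of the box
$\{C \ge \mathrm{ca}(n),\ L \le \mathrm{la}(n)\}$ under the symmetric joint
distribution, computed exactly by `specificity()` / `boxMass()`.
`sensitivity()` is the complementary signal probability under an arbitrary
$p$, using the unconditional joint distribution at that $p$.
`anhoejSpecificities()` tabulates limits and specificities over a range of
$n$, building the symmetric tables once: the recursion for length $n$
consumes every shorter length, so all shorter-$n$ results are retained and
shared (they are also cached across calls within a session).  Specificities
are *not* monotone in $n$ — e.g. they drop to 0.891 at $n = 90$ and jump to
0.931 at $n = 91$ where the run limit steps from 9 to 10 — which is the
practical motivation for computing them exactly.

## Oracle and simulator

Two independent ground-truth implementations validate the recursion:

* `enumerateJoint()` iterates over all $2^n$ binary sequences (capped at
  $n = 16$ by default), scoring each with its exact product-of-probability
  weight via `sequenceStats()`.  The test suite asserts exact cell-for-cell
  equality with the recursion for all $n \le 12$ at $p \in \{0.3, 0.5,
  0.8\}$ and for 20 seeded random probability vectors at $n \le 10$.
* `simulateJoint()` draws seeded Monte-Carlo charts and reports empirical
  joint frequencies plus the sample mean and standard error of $C \cdot L$.
  At $n = 200$, where enumeration is impossible, the exact
  $\mathrm{E}(C\,L)$ from `expectedCL(symmetricJoint(200))` is checked
  against $10^5$ simulated charts with a 4-standard-error acceptance band
  (the replicate count balances a tight band against runtime; at $10^5$
  replicates the standard error is about 0.5 on a mean of about 789).

The simulator emulates exactly what the exact computation models:
independent Bernoulli observations classified against a *known* centre
line.  It does not emulate two features of real run-chart practice — a
median estimated from the same data (which makes observations dependent)
and autocorrelated series — so agreement between the exact computation,
the oracle and the simulator says nothing about those settings; both are
explicitly out of scope.

## Problem sizes and degenerate inputs

The package's own reference computations use: full joint tables at
$n = 16$ (where published integer and one-decimal tables exist),
specificities for $n = 10..100$, exact binomial marginals for
$n \le 100$, enumeration up to $n = 12$ (oracle cap 16), and one
$n = 200$ symmetric computation for the simulation cross-check.  These
sizes keep the whole validation suite comfortably fast while covering the
full published range; the recursion itself has no intrinsic ceiling —
`jointConditional()` merely warns beyond $n = 200$ that cost (not
precision) grows, with $O(n^3)$ exact numbers held in memory.

Degenerate cases follow the definitions: $n = 1$ gives the point mass at
$(0, 1)$; $p$ must lie strictly in $(0, 1)$ (a chart with $p \in \{0, 1\}$
has no distribution to compute beyond the constant sequence);
`crossingsLimit()` requires $n \ge 2$, and at $n = 2$ it is 0, so no chart
can signal on crossings alone.  Empty sequences, non-binary values, and
out-of-range $(c, l, f)$ arguments are rejected with informative errors.

## Limitations

* Observations must be independent with a predetermined centre line.
  Charts whose median is estimated from the same data, and autocorrelated
  series, require different recursions and are not supported.
* Runtime and memory grow polynomially ($O(n^4)$ work, $O(n^3)$ storage of
  exact numbers), so very long sequences (thousands) are impractical.
* The varying-probability construction is validated against enumeration,
  not against any published table, because none exists.
* Modified rule sets with flatter specificity profiles are not included;
  the exact joint distribution computed here is the tool for deriving
  them, not the derivation itself.
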
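# CrossingRuns

Exact joint distribution of the number of crossings and the longest run in
independent Bernoulli sequences, with the Anhoej run-chart rules.

## The problem

A run chart plots observations around a centre line determined from
previous data.  For the n *useful* observations (those not on the line),
two statistics separate random from non-random variation:

* **C**, the number of crossings of the centre line (adjacent unequal
  pairs), c = 0..n−1;
* **L**, the length of the longest run (longest same-side stretch),
  l = 1..n.

Rules in statistical process control — notably the Anhoej rules — signal on
both statistics at once, so assessing them requires the **joint**
distribution P<sub>n</sub>(C = c, L = l), for which no closed form is
known.  This package computes it exactly, for practitioners and
methodologists in statistical process control / healthcare quality
improvement who need exact (rather than simulated) operating
characteristics of run-chart rules.

## The method

The recursion conditions on the side S of the first observation and
partitions on the end position F of the first crossing:

* P<sub>n</sub>(F = 1 | S = 1) = p<sup>n−1</sup> (no crossing),
  P<sub>n</sub>(F = f | S = 1) = p<sup>f−2</sup> q for f = 2..n;
* given F = f, the last n+1−f observations form the same kind of chart,
  shorter and starting on the opposite side, giving
  P<sub>n</sub>(C = c, L = f−1 | S=1, F=f) = P<sub>n+1−f</sub>(C = c−1, L ≤ f−1 | S=0)
  and
  P<sub>n</sub>(C = c, L = l | S=1, F=f) = P<sub>n+1−f</sub>(C = c−1, L = l | S=0)
  for l ≥ f (with the marginal over L when the initial run dominates,
  f−1 ≥ n+1−f);
* P<sub>n</sub>(C, L) = P<sub>n</sub>(C, L | S=1) p + P<sub>n</sub>(C, L | S=0) q.

All arithmetic is **exact rational** (arbitrary-precision integer
numerators over a common denominator — no floating point in the reference
path), and results are also kept in the "times" representation, multiplied
by 2<sup>n−1</sup>, in which the symmetric p = 1/2 case is a table of exact
integers.  A brute-force enumeration oracle, a seeded Monte-Carlo
simulator, the generalization to per-position success probabilities, and
the Anhoej rules (shift limit round(log2(n)+3); crossings limit = lower 5th
percentile of Binomial(n−1, 1/2)) with exact specificities/sensitivities
are included.

## Worked example

```r
library(CrossingRuns)

pair <- jointConditional(16, "1/2", scale = "times")
u <- combineUnconditional(pair)
u
#> JointPMF: n = 16, scale = times (m = 2), conditioning = unconditional, total mass = 32768
#> highest cells: (c=7, l=4): 2716, (c=8, l=4): 2646, (c=9, l=3): 2640

jointWeights(u)[6:9, 2:7]
#>     l=2  l=3  l=4  l=5 l=6 l=7
#> c=5   0   21  525  960 741 420
#> c=6   0  266 1652 1617 882 392
#> c=7   1 1106 2716 1652 672 224
#> c=8  36 2268 2646 1080 324  72
```

These integers are 2^15 × the joint probabilities: e.g. 741 sequences of
the 32768 equally likely length-16 continuations have exactly 5 crossings
and a longest run of 6 (P = 741/32768 ≈ 0.023), and (c=7, l=4) is the most
likely combination, 2716/32768 ≈ 0.083.

```r
ruleLimits(16)
#> Anhoej rule limits for n = 16: signal if L > 7 or C < 4

anhoejSpecificities(10, 14)
#>    n longestRunLimit crossingsLimit specificity
#> 1 10               6              2       0.955
#> 2 11               6              2       0.951
#> 3 12               7              3       0.957
#> 4 13               7              3       0.963
#> 5 14               7              4       0.939

sensitivity(16, 0.7, digits = 3)
#> [1] 0.207
```

So with 16 useful observations a random chart stays clear of both rules
with probability 0.939–0.963 for nearby n, and a true shift to p = 0.7 is
detected with probability 0.207 — exact values, not simulation estimates.

A command-line wrapper is installed as
`system.file("scripts", "crossing-runs", package = "CrossingRuns")`, with
subcommands `joint`, `joint-varying`, `limits`, `specificity`,
`sensitivity`, `simulate` and `oracle`, writing exact CSV/JSON.

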
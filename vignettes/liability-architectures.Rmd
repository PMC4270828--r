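---
title: "Simulating hierarchical epistatic architectures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hierarchical epistatic architectures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistasim)
```

## The model

Most genotype–phenotype simulators specify the map from genotypes to disease
risk directly, through regression coefficients or penetrance tables.
`epistasim` instead builds the map out of a small biological scaffold: a
protein-coding gene with one coding variant, its promoter and an enhancer
(one regulatory variant each), two transcription-factor genes (one coding
variant each), a microRNA variant, and an environmental exposure. Each of
the six genetic variants is biallelic and coded 0/1/2 (minor-allele count);
the environment is coded on a five-point scale −2..2.

The seven inputs are combined along a fixed chain that mirrors the flow of
regulation into protein product:

```
r1 = f1(TF1, enhancer)
r2 = f2(r1, TF2)
r3 = f3(r2, promoter)
r4 = f4(r3, coding)
r5 = f5(r4, microRNA)
liability = f6(r5, environment)
```

Each slot `f1..f6` holds one of 25 integer-valued functions (see
`math_functions()`), grouped as Basic (`ADD`, `SUB`, `MULT`, `DIV`, `MOD`,
`MOD2`), Logical (`GT`, `LT`, `AND`, `OR`, `XOR`), Bitwise (`BITA`, `BITO`,
`BITX`), Unary (`ABS`, `NOT`, `FAC`, `LEFT`, `RIGHT`), Large (`POW`, `LOG`,
`PER`, `CHS`) and Miscellaneous (`MIN`, `MAX`). There are therefore
25^6 ≈ 2.4 × 10^8 distinct architectures over the fixed wiring.

The liability is a discrete random variable. Its distribution is computed
*exactly* by pushing the locus distributions through the chain
(`liability_distribution()`): the probability of an output value is the sum,
over all input combinations that the chain maps to that value, of the
product of per-locus probabilities. Because each chain step is a pushforward
of a finite distribution, the support never exceeds the 3^6 × 5 = 3,645
input combinations, so the fold is both exact and cheap. The equivalence of
the fold with brute-force enumeration over all 3,645 combinations is a
tested invariant.

Disease is the upper tail of the liability: `select_threshold()` picks the
support value whose tail probability is closest to the requested prevalence
(ties toward the smaller prevalence — the conservative disease definition).
Discreteness means the achieved prevalence rarely equals the target exactly;
for the all-additive architecture at a target of 0.10 the closest
achievable value is `r  round(liability_distribution(hierarchy_model("ADD"), 0.1)$achieved_prevalence, 4)`.
The achieved value is always reported and is used, not the target, in any
downstream comparison.

## Function semantics

Only the function *names* are fixed by convention; total integer semantics
are this package's own specification, chosen so that no input can raise an
error and chained evaluation cannot overflow:

* undefined cases map to 0: division/modulus by zero, factorial of a
  negative, `POW` with negative exponent, `PER`/`CHS` outside
  `0 ≤ b ≤ a`;
* every result saturates at the 32-bit two's-complement range (symmetric,
  ±(2³¹−1)), which bounds `FAC`/`POW`/`PER` growth;
* unary functions (`ABS`, `NOT`, `FAC`, `LOG`) act on the left operand and
  ignore the right, consistent with `LEFT`/`RIGHT` being operand selectors;
* `MOD2` is arithmetic parity `(a + b) mod 2`; `XOR` is the logical
  exclusive-or on truthiness (exactly one operand non-zero). With genotype
  probabilities 0.25/0.5/0.25 the parity of a genotype is a fair coin, so
  `MOD2` of two genotypes is 0 or 1 with equal probability yet fully
  determined once both are known — the canonical two-locus pure-epistasis
  mechanism. The truthiness `XOR` is a related but distinct interaction
  (its output is 1 with probability 0.375 on two genotypes). Reports about
  the original prototype do not distinguish the two, so architectures
  built on `XOR` may differ slightly between implementations.

## Default study conditions

The default generator settings are the study conditions used throughout the
tests and the acceptance script:

* genotype distributions: Hardy–Weinberg with equal allele frequencies,
  0.25/0.5/0.25 per locus;
* environment: uniform over −2..2. The original description leaves this
  distribution unstated; uniform is the minimal assumption and it is
  configurable per locus;
* prevalence target 0.10; populations of 100,000 subjects; samples of
  1,000 cases and 1,000 controls drawn without replacement within class;
* noise SNPs: none by default; when requested, each gets a minor-allele
  frequency uniform in [0.05, 0.5] and HWE genotypes independent of status.

The simulation pipeline is population-then-sample: a finite population is
drawn i.i.d. from the locus distributions, status is assigned by the
threshold selected on the exact distribution (never re-estimated from the
sample), and the case-control sample is drawn within class. This reproduces
finite-population variability; the search fitness (below) instead samples
directly from the exact conditional distributions P(genotypes | status),
which is the infinite-population limit of the same law and roughly an order
of magnitude faster per candidate model.

Exported datasets keep only the six genotype columns plus a 0/1 `Class`
column — the environment and the latent liability are dropped, as in a
genetic study where they are unmeasured — in the tab-delimited dialect of
the MDR software family.

## Interaction metrics

All information quantities are plug-in estimates in bits from empirical
contingency tables. For a locus triple (A, B, C) and status Y,

* main effects: I(A;Y), I(B;Y), I(C;Y);
* pairwise synergy: IG(A;B;Y) = I(A,B;Y) − I(A;Y) − I(B;Y);
* pure three-way interaction:
  IG(A;B;C;Y) = I(A,B,C;Y) − I(A,B;Y) − I(A,C;Y) − I(B,C;Y)
  + I(A;Y) + I(B;Y) + I(C;Y).

The three-way term is the synergy left after removing all lower-order
effects and can be negative (redundancy). The exact-limit benchmark is the
parity fixture (`parity_dataset()`): genotype combinations weighted by HWE
with class = (A+B+C) mod 2 give main and pairwise IG exactly 0 and
three-way IG exactly 1 bit.

The MDR classifier (`mdr()`) labels a genotype cell high-risk when its
case:control ratio is at least the overall ratio (ties high-risk; empty
cells low-risk, i.e. baseline in the absence of evidence) and reports
*training* accuracy on the evaluated loci. Cross-validation is deliberately
not the default: the headline accuracies this package reproduces are
training accuracies of pre-specified 3-locus models, not model-selection
results.

Two permutation tests validate a fitted model, both using MDR accuracy as
the statistic and the add-one estimator p = (1 + #{perm ≥ obs})/(n_perm+1):

* the standard test shuffles case-control labels — the null of no
  association;
* the explicit test of epistasis shuffles each variant's genotypes within
  cases and within controls separately, preserving all marginal
  genotype–status association while destroying inter-variant interaction —
  the null of independent effects only.

A caveat worth knowing: a liability *threshold* applied to a sum of
independent effects induces small but real two-way interactions on the
case-control scale. The explicit test on the all-additive architecture at
full scale is therefore genuinely borderline — across seeds its p-value has
median ≈ 0.03 and exceeds 0.05 in roughly a third of draws — rather than
comfortably non-significant. The clean specificity case is an architecture
with a single effective locus (e.g. `LEFT` chains with an additive
environment), for which the explicit test is reliably non-significant while
the standard test remains highly significant.

## Heuristic search

Random search and a generational genetic algorithm explore the 25^6
architecture space for pure three-way epistasis. Candidates are encoded as
30-bit strings (6 slots × 5 bits, each field decoded modulo 25, so all
2^30 encodings are valid; the 7 function indices below 32 − 25 are hit
twice as often, a mild non-uniformity we accept for totality). Fitness
simulates one case-control dataset (1,000/1,000 at prevalence 0.10 by
default) from the decoded model and returns the three-way IG of
(TF1, TF2, enhancer); models whose liability collapses to a point — no
two-class split exists — receive −∞.

GA defaults: tournament selection of size 2, uniform crossover at rate 0.9,
per-bit mutation at rate 1/30, elitism 1. These are standard settings for
a 30-bit encoding, not claims about the original prototype, and all are
configurable. Elites carry their realised fitness forward (so the
best-so-far trace is non-decreasing); every new offspring is re-evaluated,
and fitness is intentionally stochastic — a fresh derived seed per
evaluation — matching the single-dataset evaluation design. The total
evaluation budget never exceeds population × generations.

## Numerical and design choices

* Probabilities in a `discrete_dist` must sum to 1 within 1e−9 on
  construction; folded distributions agree with enumeration to 1e−12 in the
  tests.
* Saturation uses the symmetric range ±(2³¹−1): R's integer type reserves
  −2³¹, and the single representable value lost at the lower cap is
  unreachable in practice.
* Threshold selection excludes the support minimum (whose tail probability
  is 1 and yields no two-class split) and errors on single-point
  distributions.
* Sampling without replacement within class; replicate datasets use the
  derived seed sequence seed, seed+1, … so a logged configuration
  reproduces byte-identical files.
* Permutation p-values use the add-one estimator, so the smallest
  achievable p at 1,000 permutations is 1/1001 ≈ 0.001.

## Problem sizes used in the tests

Unit tests run at reduced scale (populations of 5,000–20,000, samples of
100–600 per class, 59–500 permutations, GA populations of 6–12). The
end-to-end checks reproduce the reference study conditions exactly —
eight architectures × 5 seeds at 1,000/1,000 from populations of 100,000,
1,000 permutations for the association tests — and scale the GA to
population 50 × 30 generations (≤ 1,500 evaluations per run, five seeds),
which is ample to clear the additive baseline by the tested margin.

## What the generator does and does not emulate

The generator produces unlinked variants with exact HWE genotype
frequencies and i.i.d. subjects; noise SNPs are independent of status by
construction. It does **not** simulate linkage disequilibrium, haplotype
structure, population stratification, genotyping error or missingness —
realistic variation of that kind should come from a population-genetic
simulator, with this package supplying the genotype–phenotype map. Effect
sizes are moderate to large: genotypes contribute whole units to the
liability, so passing tests here say nothing about power at the small
effect sizes typical of common-disease variants. The scaffold is fixed at
six variants and one environment; extending it (multiple variants per
element, protein–protein layers, epigenetic marks) would require a
different wiring type, not just different functions.
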
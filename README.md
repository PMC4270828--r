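# epistasim

Biology-structured simulation of epistatic case-control genotype data, with
entropy-based interaction metrics and heuristic search for strongly
epistatic architectures.

## The problem

Method developers in genetic epidemiology need simulated case-control data
in which the true genetic architecture — main effects, gene–gene and
gene–environment interaction — is known exactly. Most simulators specify
the genotype–phenotype map statistically (regression coefficients or
penetrance tables). `epistasim` instead organises six genetic variants on a
biological scaffold — two transcription factors (TF1, TF2), an enhancer, a
promoter, a coding variant and a microRNA variant, plus an environmental
exposure — and combines them along a fixed regulatory chain of six
integer-valued functions:

    r1 = f1(TF1, enhancer);  r2 = f2(r1, TF2);  r3 = f3(r2, promoter);
    r4 = f4(r3, coding);     r5 = f5(r4, microRNA);
    liability = f6(r5, environment)

Each slot holds one of 25 total integer functions (`ADD` … `MAX`; see
`math_functions()`), giving 25⁶ architectures. Genotypes are coded 0/1/2
(HWE, 0.25/0.5/0.25 by default), the environment −2..2 (uniform). The
liability distribution is computed **exactly** — the probability of each
output value is Σ over input combinations mapping to it of the product of
locus probabilities — and disease is the upper tail: the threshold *t* is
chosen so that P(liability ≥ t) is the achievable prevalence closest to the
target (0.10 by default). Populations are sampled i.i.d., status assigned
by the exact threshold, and case-control samples exported in the
tab-delimited `Class`-column format of the MDR software family.

Architectures are scored by plug-in information metrics in bits: main
effects I(X;Y), pairwise synergies IG(Xi;Xj;Y), and the pure three-way
interaction information

    IG(A;B;C;Y) = I(A,B,C;Y) − I(A,B;Y) − I(A,C;Y) − I(B,C;Y)
                  + I(A;Y) + I(B;Y) + I(C;Y)

together with a multifactor dimensionality reduction (MDR) classifier
(high-risk cells: case:control ratio ≥ overall ratio; training accuracy)
and two permutation tests — the standard label-shuffling test and the
explicit test of epistasis, which shuffles genotypes within cases and
within controls to destroy interactions while preserving marginal effects.
A random search and a genetic algorithm over 30-bit encodings (6 × 5 bits,
modulo-25 decoding) maximise three-way IG to *discover* purely epistatic
architectures.

## Worked example

The double-exclusive-or architecture (`f1 = f2 = XOR`, the rest additive)
carries almost no marginal signal but a clear three-way interaction:

```r
library(epistasim)

m4 <- hierarchy_model(c("XOR", "XOR", "ADD", "ADD", "ADD", "ADD"))
ld <- liability_distribution(m4, prevalence = 0.1)
ld
#> Exact liability distribution: 12 support values in [-2, 9]
#>   disease threshold: liability >= 7 (achieved prevalence 0.06367, target 0.1)

pop <- simulate_population(m4, 100000, prevalence = 0.1, seed = 1)
d   <- sample_case_control(pop, 1000, 1000, seed = 2)

res <- run_evaluate(d, loci = c("TF1", "TF2", "enhancer"),
                    n_perm = 1000, seed = 3)
res$interaction
#> Interaction information (bits), n = 2000
#>   main effects:      TF1=0.0059  TF2=0.0089  enhancer=0.0033
#>   pairwise synergy:  TF1:TF2=0.0107  TF1:enhancer=0.0083  TF2:enhancer=0.0115
#>   pure three-way:    0.0284
res$mdr
#> MDR model on (TF1, TF2, enhancer)
#>   27 observed genotype combinations, 14 high-risk
#>   threshold case:control ratio 1, training accuracy 0.6365
res$p_epistasis
#> explicit test of epistasis (within-class genotype shuffling)
#>   loci: TF1, TF2, enhancer
#>   observed MDR accuracy 0.6365, p = 0.000999 (1000 permutations)
```

Reading the numbers: each variant alone carries under 0.01 bits about
status, while the triple jointly carries ≈ 0.028 bits beyond all
lower-order effects — the signature of pure three-way epistasis — and the
3-locus MDR model classifies 63.7% of subjects correctly. The explicit
test confirms the signal is interactive: shuffling genotypes within each
class destroys it (p ≈ 0.001), not merely associated. Contrast the
all-`ADD` architecture, whose accuracy (≈ 0.73) comes entirely from main
effects with three-way IG ≈ 0.004.

Results are tidyverse-friendly throughout: `tidy()`/`glance()` methods for
interaction results, MDR fits, permutation tests and searches, and
`autoplot()` for liability distributions, interaction decompositions and
GA traces. To hunt for new epistatic architectures:

```r
res <- ga_search(search_config(pop_size = 50, generations = 30), seed = 7)
head(tidy(res))   # ranked hall of fame: f1..f6, fitness (three-way IG)
autoplot(res)     # best and best-so-far fitness per generation
```

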
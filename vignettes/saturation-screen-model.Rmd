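---
title: "Modeling saturation mutagenesis screens with CDS-length-proportional hit rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling saturation mutagenesis screens with CDS-length-proportional hit rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmut)
```

## The model

A point mutagen such as ENU introduces single-nucleotide substitutions
essentially uniformly along the genome. In a positive-selection screen on
haploid cells, a clone survives selection when its causative mutation
disrupts one of the `n` genes essential for the target pathway, and each
independently isolated clone contributes one mutant allele (occasionally
two, when a clone carries two causative hits). Because most causative
mutations are exonic substitutions, the chance that a given gene is the one
hit is, to good approximation, proportional to its coding-sequence length.

`satmut` encodes this as the *concatenated-CDS model*: the CDSs of the `n`
genes, with lengths $L_1, \dots, L_n$ and total $T = \sum_i L_i$, are laid
end to end; a mutagenic hit is a uniform draw of a nucleotide coordinate on
$[1, T]$, mapped back to the owning gene. Gene $i$ is therefore hit with
probability $p_i = L_i / T$, and a screen of $m$ alleles is a multinomial
sample of size $m$ on $(p_1, \dots, p_n)$. Coordinates are 1-based and
inclusive, with gene $i$ owning the closed interval
$[1 + \sum_{j<i} L_j,\; \sum_{j \le i} L_j]$; any consistent convention is
equivalent, so this one is fixed and asserted by tests. Sampling is
implemented as categorical draws on $p_i$ rather than by materializing the
block — the two routes are distributionally identical (a test checks the
coordinate route against $p_i$ at $10^5$ draws) and the categorical form
needs no $O(T)$ memory.

The model deliberately ignores clone survival, selection efficiency,
diploid contamination and any sequence-context mutability bias: it is a
model of *which* essential gene a causative hit lands in, conditional on a
clone having been recovered.

## Coverage analytics

The screen's progress is summarized by its *coverage* $C_m$: the number of
distinct genes hit after $m$ alleles. This is the occupancy problem with
unequal cell probabilities, and three views of it are provided.

**Closed-form expectation.**
$\mathbb{E}[C_m] = \sum_i \bigl(1 - (1 - p_i)^m\bigr)$, computed as
`sum(-expm1(m * log1p(-p)))` so that large $m$ and small $p_i$ lose no
precision. This is the exact mean of the simulated histograms.

**Exact distribution.** For any gene subset $B$,
$\Pr[\text{all } m \text{ hits fall in } B] = (\sum_{i \in B} p_i)^m$, and
Möbius inversion gives
$\Pr[C_m = k] = \sum_{c=0}^{k} (-1)^{k-c} \binom{n-c}{k-c} S_c$ with
$S_c$ the sum of $(\sum_{i \in B} p_i)^m$ over subsets of size $c$. Only
the size-grouped sums $S_c$ enter, but computing them enumerates all $2^n$
subsets (by iterative doubling, in stable order), so the routine is guarded
at $n \le 25$; beyond that the Monte Carlo route applies. Alternating-sum
round-off can leave masses a hair below zero in the far tail; magnitudes
under $10^{-9}$ are clamped to zero and the total mass is verified to 1
within $10^{-9}$. Tests check the distribution against brute-force
enumeration of all $n^m$ ordered hit sequences on tiny models, and its mean
against the closed form on random models.

**Monte Carlo.** `coverageDistributionMC()` draws $R$ multinomial screens
and tabulates coverage. The default $R = 10^5$ keeps a desk-scale run in
seconds while leaving Monte Carlo standard errors well below the
distinctions that matter here; $R$ is a plain argument, so the
$10^7$-replicate scale is a flag away. `replicateRuns()` provides the
box-plot view (medians, type-7 quartiles, whiskers at the most extreme
points within $1.5 \times$ IQR) used to compare simulated per-gene allele
counts with observed ones.

**Discovery probability.** If one more essential gene of length $L$ exists
beyond the known total $T$, each allele misses it with probability
$T/(T+L)$, so $m$ alleles discover it with probability
$1 - (T/(T+L))^m$ — rising with both $m$ and $L$. Reported percentages
(discovery, saturation degree) round to the nearest whole percent, half
away from zero.

## Estimating the number of essential genes

For a pathway whose gene count $n$ is unknown, CDS lengths are assigned
from the deciles of the CDS-length distribution of all mouse genes: the
5th–95th percentile values 378, 615, 825, 954, 1131, 1365, 1617, 2022,
2628 and 4131 bp. An $n$-gene pseudo-pathway cycles these ten bins,
smallest first ($n = 40$ concatenates four copies of each); for $n$ not a
multiple of 10 — which the decile construction does not itself define — the
final cycle takes the leading bins, a deterministic round-robin extension.

Observed screening steps $(m_j, C_j)$ are compared against the exact
expected-coverage curves of these pseudo-pathways on a candidate grid
(default $n = 10, 20, \dots, 100$), and the estimate is the candidate
minimizing $\sum_j (C_j - \mathbb{E}[C_{m_j}])^2$. Unweighted least squares
is the simplest defensible formalization of curve matching here; the
per-candidate discrepancies are kept in the result so the sharpness of the
minimum can be inspected. Expectation curves, not single simulation draws,
are the canonical comparison (an MC mode reproduces the simulation
procedure literally). Candidates smaller than the largest observed coverage
cannot have produced the data and are excluded from the arg-min, though
their discrepancies are still reported; ties resolve to the smallest
candidate. Tests verify that the estimator recovers every grid size from
its own curve, and recovers $n = 20$ from stochastic screens of a 20-gene
pseudo-pathway in at least 90% of 200 seeded repetitions.

```{r estimate}
steps <- readScreenSteps(system.file("extdata", "gpi_screen_steps.tsv",
                                     package = "satmut"))
est <- estimateGeneNumber(steps)
discrepancies(est)
bestN(est)
```

## Haploid variant-call analytics

In haploid clones every true mutation is effectively homozygous, so a
candidate call is accepted as true-positive when (i) the caller designated
it homozygous, (ii) strictly more than 90% of the mutant clone's reads
carry the alteration, and (iii) strictly more than 95% of the untreated
control's reads at the same site carry the reference. The strict
inequalities follow the ">90%/>95%" phrasing of the criteria; values at
exactly the threshold fail. When a zygosity flag is absent from the input,
a mutant alternate fraction of at least 0.90 proxies the designation — a
documented fallback, not the canonical path. Validation tables
(filter-positive/-negative vs. Sanger detected/not) are assessed with the
two-sided Fisher exact test under the point-probability rule — the sum of
hypergeometric probabilities of all tables no more probable than the
observed one — with a degenerate margin returning $p = 1$ by convention.
The implementation delegates to `stats::fisher.test()`, which applies
exactly this rule; an independent full-enumeration oracle in the test suite
checks it on random small tables.

Substitutions are collapsed to the six strand-symmetric base-pair classes
(`G>A` and `C>T` both count as `G:C>A:T`), labeled transition or
transversion, with class fractions computed over classified substitutions
only. Effect labels map to impact categories as: nonsense, splice site,
frameshift and start-loss are *high*; nonsynonymous and in-frame codon
insertions/deletions are *moderate*; synonymous is *low*; everything else
(start gained, synonymous stop, noncoding) is *modifier*. The mean per-clone
mutation count over a captured exome of 49.3 Mb gives the mutation rate per
Mb; its display truncates toward zero at two decimals (233.1/49.3 = 4.728
displays as 4.72) while the raw value stays in the result. For candidate
triage, per-gene allele counts are normalized by CDS length, so a short
gene hit often outranks a long gene hit equally often; ties prefer the
shorter CDS, then name order.

## The synthetic-data generator

The generator produces the inputs the analytics consume, with truth
attached, and is itself validated before it validates anything else
(parameter-recovery tests run it at fixed seeds and check its configured
rates within three standard errors).

**Screens.** `generateScreen()` emulates independent clone isolation: each
clone carries one causative hit from the hit-probability measure, or two
with a small double-hit probability (default $1/\text{clones}$, putting one
double mutant in an average screen — the observed rate in the model system,
114 clones yielding 115 alleles). Alleles, not clones, are counted.

**Call sets.** `generateCloneCallset()` draws a per-clone true-mutation
count from a negative binomial with mean 233.1 and size 2 — the
method-of-moments fit to the ten observed per-clone totals (10–511,
mean 233.1), chosen because the observed counts are far too dispersed for a
Poisson and no mechanistic model of the clone-to-clone divergence exists;
the parameters are configuration, not claims. Sites are placed uniquely on
a linearized 49.3-Mb exome; 98.5% are substitutions whose classes follow
the ENU exome spectrum (G:C>A:T 46.7%, A:T>G:C 20.4%, A:T transversions
25.1%, G:C transversions 7.9%, renormalized; strand orientation uniform),
the remainder indels/other types. True sites draw mutant alternate
fractions from Beta(60, 1.5) and control reference fractions from
Beta(90, 1.5) — concentrated near 1, as haploid homozygous calls are, yet
leaving a small mass near the 0.90 line so filter sensitivity is not
trivially 1. Decoy sites (default 10% of candidates) draw intermediate
fractions, Beta(8, 4) and Beta(12, 3), straddling the thresholds to
exercise boundary behavior. All shapes are configurable; tests that need
exact truth recovery use shapes placed clear of the thresholds.

**What it does not emulate.** No read-level error model, no capture bias or
coverage depth, no linkage between sites, no sequence context, no
chromosome structure beyond a label. Passing tests therefore demonstrate
that the analytics are correct under the stated statistical structure — not
that real pipelines upstream (alignment, calling, effect prediction) are
error-free.

## Numerical and design choices

- Percentages round half away from zero to whole percent; the displayed
  mutation rate truncates (see above).
- `expectedCoverage()` uses `log1p`/`expm1` throughout; the
  inclusion–exclusion path clamps sub-$10^{-9}$ negative round-off.
- Randomness: all simulation functions take an optional `seed` applied via
  a scoped RNG (the caller's random state is untouched); R's default
  Mersenne-Twister is the generator, so a seed plus the package version
  pins a result exactly.
- Genes flagged unavailable in a gene table (the excluded, hypomorphic or
  screen-protected rows) are dropped at load with a message rather than an
  error: they are annotations of scope, not malformed data.
- Problem sizes in the test suite are desk-scale by design: Monte Carlo at
  $R = 10^4$–$10^5$, exact enumeration at $n \le 22$, estimator recovery
  over 200 stochastic repetitions. These sizes put every assertion's
  sampling error well below its tolerance.

## Limitations

The hit model conditions on recovery and so says nothing about genes whose
loss fails to produce the selected phenotype (hypomorphs escape saturation
accounting entirely — they must be excluded from the essential set, as the
packaged fixture does). The decile construction represents an "average"
pathway; a pathway whose genes are systematically short or long will bias
the size estimate in the obvious direction, and no uncertainty interval on
the estimate is attempted. The least-squares fit criterion is a package
choice where the original visual-fit procedure was informal. The
negative-binomial clone-count model is a stand-in for an unexplained
overdispersion phenomenon.
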
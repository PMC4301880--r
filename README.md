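# satmut

Quantitative modeling of saturation mutagenesis screens in haploid cell
systems.

In a phenotype-driven forward genetic screen with a point mutagen such as
ENU, loss-of-function hits accumulate in the genes of the target pathway at
a rate governed almost entirely by coding-sequence (CDS) length: a mutagenic
hit is well approximated as a uniform draw of a nucleotide position along
the concatenation of the pathway's CDSs. `satmut` implements this model and
the analytics that hang off it, for researchers planning or interpreting
haploid-cell screens:

- **Hit model.** For genes with CDS lengths `L_1..L_n` and `T = sum(L_i)`,
  one allele hits gene `i` with probability `p_i = L_i / T`. A screen of `m`
  independent alleles is a multinomial draw on `(p_1..p_n)`.
- **Coverage (occupancy) analytics.** The number of distinct genes hit by
  `m` alleles has exact expectation `E[C_m] = sum_i (1 - (1 - p_i)^m)`; the
  full distribution is available exactly by inclusion–exclusion (`n <= 25`)
  or by Monte Carlo, alongside replicate box-plot summaries of per-gene
  allele counts.
- **Discovery probability.** An unseen gene of length `L` beyond a known
  total `T` is missed per allele with probability `T / (T + L)`, so it is
  discovered among `m` alleles with probability `1 - (T / (T + L))^m`.
- **Pathway-size estimation.** Pseudo-pathways built from the ten decile
  CDS lengths of all mouse genes (378–4,131 bp) give expected-coverage
  curves for `n = 10..100` genes; least squares against observed screening
  steps `(m_j, C_j)` estimates how many genes a pathway needs.
- **Haploid WES analytics.** Read-fraction filtering of homozygous-
  designated calls (alteration > 90% in the mutant, reference > 95% in the
  untreated control), Fisher exact validation, transition/transversion
  spectrum classification, impact-category tallies, per-Mb mutation rates,
  and CDS-normalized candidate gene ranking.
- **Synthetic data.** Seed-deterministic generators for screens and paired
  mutant/control call sets with truth labels, so every stage is testable
  without sequencing data.

The package ships a gene table for the GPI-anchor biosynthesis pathway
(22 essential genes, 23,982 bp of CDS, 115 observed mutant alleles), the
model system on which all of the above can be exercised end to end.

## Worked example

```r
library(satmut)

gpi <- gpiPathway()
gpi
#> PathwayModel with 22 genes, 23982 bp concatenated CDS
#>   genes: Pigc, Pigm, Dpm1, Dpm2, Pigt ...
#>   observed alleles: 115

round(correlateAllelesWithLength(gpi), 2)
#> [1] 0.59

expectedCoverage(gpi, c(22, 40, 71, 115, 407))
#> [1] 12.65336 16.46721 19.23619 20.68054 21.94971

est <- estimateGeneNumber(readScreenSteps(
  system.file("extdata", "gpi_screen_steps.tsv", package = "satmut")))
est
#> SizeEstimate over grid {10, 20, 30, 40, 50, 60, 70, 80, 90, 100}
#>   best n = 20 (least-squares fit to 4 screening steps)

round(100 * discoveryProbability(23982, 213, 115))
#> [1] 64
```

Reading the numbers: the observed per-gene allele counts correlate with CDS
length at `r = 0.59`, as the proportional-hit model predicts. The expected
coverage climbs from 12.7 distinct genes at 22 alleles to 21.9 at 407 — the
point where the screen saturates all 22 essential genes. Fitting the four
observed screening steps (11, 15, 18, 20 genes at 22, 40, 71, 115 alleles)
against decile-bin coverage curves selects a 20-gene pathway. A hypothetical
23rd gene as short as 213 bp would still have been discovered among the 115
alleles with 64% probability.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "satmut-cli.R", package = "satmut")` with
subcommands `simulate`, `coverage`, `discover`, `estimate-n`, `filter`,
`spectrum`, `rate`, `rank` and `synth`, all emitting JSON.

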
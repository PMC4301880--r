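Package: satmut
Title: Saturation Mutagenesis Screen Modeling for Haploid Cell Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models phenotype-driven saturation mutagenesis screens in which
    mutagenic hits land on pathway genes with probability proportional to
    coding-sequence (CDS) length. Provides the concatenated-CDS hit model,
    Monte Carlo screen simulation with replicate summaries, closed-form and
    exactly enumerated coverage distributions (an unequal-probability
    occupancy model), discovery probabilities for unseen genes, a
    percentile-bin estimator of the number of genes essential for a pathway,
    and companion analytics for haploid whole-exome variant calls: read
    fraction filtering of homozygous-designated mutations, Fisher exact
    validation, substitution-spectrum classification, impact tallies,
    per-megabase mutation rates, and CDS-normalized candidate gene ranking.
    A synthetic-data module generates screens and paired mutant/control call
    sets with known truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
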
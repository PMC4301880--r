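test_that("the read-fraction filter applies strict thresholds", {
  calls <- data.frame(
    chrom = "exome", pos = 1:5, ref = "G", alt = "A",
    mutantAltFraction = c(0.99, 0.90, 0.95, 0.99, 0.99),
    controlRefFraction = c(0.99, 0.99, 0.95, 0.96, 0.99),
    zygosity = c("homozygous", "homozygous", "homozygous", "homozygous",
                 "heterozygous")
  )
  kept <- filterTrueMutations(calls)
  # row 1 passes; row 2 fails (alt == 0.90, strict >); row 3 fails
  # (ref == 0.95, strict >); row 4 passes; row 5 fails (heterozygous)
  expect_identical(kept$pos, c(1L, 4L))
})

test_that("a missing zygosity column falls back to the fraction proxy", {
  calls <- data.frame(mutantAltFraction = c(0.99, 0.905, 0.89),
                      controlRefFraction = c(0.99, 0.99, 0.99))
  expect_identical(nrow(filterTrueMutations(calls)), 2L)
})

test_that("malformed fractions error, or are skipped in lenient mode", {
  calls <- data.frame(mutantAltFraction = c(0.99, 1.2, NA),
                      controlRefFraction = c(0.99, 0.99, 0.99),
                      zygosity = "homozygous")
  expect_error(filterTrueMutations(calls), "malformed")
  expect_warning(kept <- filterTrueMutations(calls, lenient = TRUE),
                 "skipping 2")
  expect_identical(nrow(kept), 1L)
  expect_error(filterTrueMutations(calls, altThreshold = 1), "thresholds")
})

test_that("the filter recovers exactly the planted true mutations", {
  calls <- generateCloneCallset(clearMarginConfig(decoyFraction = 0.5),
                                nClones = 1, seed = 77)
  kept <- filterTrueMutations(calls)
  expect_identical(sort(kept$pos), sort(calls$pos[calls$isTrue]))
  expect_true(all(kept$isTrue))
})

test_that("two-sided Fisher matches the enumeration oracle", {
  expect_equal(signif(fisherExactTwoSided(matrix(c(19, 0, 1, 22), 2)), 2),
               4.5e-11)
  expect_equal(fisherExactTwoSided(matrix(1, 2, 2)), 1)
  expect_equal(fisherExactTwoSided(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-9)
  expect_message(p <- fisherExactTwoSided(matrix(c(0, 0, 5, 7), 2)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisherExactTwoSided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")

  withr::local_seed(14)
  for (rep in 1:20) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExactTwoSided(tab), fisherEnumOracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("substitutions collapse to strand-symmetric classes", {
  g <- classifySubstitution("G", "A")
  expect_identical(g$class, "G:C>A:T")
  expect_identical(g$type, "transition")
  expect_identical(classifySubstitution("C", "T")$class, "G:C>A:T")
  ac <- classifySubstitution("A", "C")
  expect_identical(ac$class, "A:T>C:G")
  expect_identical(ac$type, "transversion")
  expect_error(classifySubstitution("A", "A"), "differ")
  expect_error(classifySubstitution("N", "A"), "single bases")
})

test_that("classification is invariant under strand complementation", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      direct <- classifySubstitution(r, a)
      flipped <- classifySubstitution(comp[r], comp[a])
      expect_identical(direct$class, flipped$class)
      expect_identical(direct$type, flipped$type)
    }
  }
})

test_that("spectrum summaries tally classes, indels and unclassifiable", {
  allGA <- data.frame(ref = rep("G", 5), alt = rep("A", 5))
  s <- spectrumSummary(allGA)
  expect_identical(unname(classCounts(s)["G:C>A:T"]), 5L)
  expect_equal(unname(classFractions(s)["G:C>A:T"]), 1)
  expect_equal(sum(classFractions(s)), 1, tolerance = 1e-9)

  empty <- spectrumSummary(data.frame())
  expect_identical(sum(classCounts(empty)), 0L)
  expect_true(all(is.na(classFractions(empty))))

  mixed <- data.frame(ref = c("G", "N", "A", "T"),
                      alt = c("A", "T", "ins", "del"),
                      type = c("substitution", "substitution",
                               "indel", "indel"))
  sm <- spectrumSummary(mixed)
  expect_identical(sm@unclassified, 1L)
  expect_identical(sm@indel, 2L)
})

test_that("the generated call set recovers the configured spectrum", {
  cfg <- callsetConfig(meanMutations = 2000, dispersion = 1e8,
                       substitutionFraction = 1, decoyFraction = 0)
  calls <- generateCloneCallset(cfg, nClones = 1, seed = 19)
  s <- spectrumSummary(calls)
  n <- sum(classCounts(s))
  expect_gt(n, 1500)
  p <- defaultEnuSpectrum()
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(classFractions(s) - p) < 3 * se))
  # headline transition rates sit inside their binomial bands
  fr <- classFractions(s)
  expect_lt(abs(fr[["G:C>A:T"]] - 0.467), 3 * se[["G:C>A:T"]])
  expect_lt(abs(fr[["A:T>G:C"]] - 0.204), 3 * se[["A:T>G:C"]])
})

test_that("impact tallies map the effect vocabulary", {
  tal <- impactTally(c(rep("nonsense", 2), "splice_site", "frameshift",
                       "start_lost", rep("nonsynonymous", 7),
                       "codon_insertion", rep("synonymous", 3), "intron",
                       "start_gained"))
  expect_identical(tal, c(high = 5L, moderate = 8L, low = 3L,
                          modifier = 2L))
  expect_identical(impactTally("synonymous")[["low"]], 1L)
  expect_identical(sum(impactTally(character())), 0L)
  expect_warning(w <- impactTally("mystery_label"), "unknown effect")
  expect_identical(w[["modifier"]], 1L)
})

test_that("mutation rate reproduces the per-clone WES accounting", {
  totals <- utils::read.table(
    system.file("extdata", "wes_clone_totals.tsv", package = "satmut"),
    header = TRUE, sep = "\t"
  )$total_mutations
  mr <- mutationRate(totals)
  expect_equal(mr$meanCount, 233.1)
  expect_equal(mr$rateDisplay, 4.72)
  expect_gt(mr$ratePerMb, mr$rateDisplay)  # truncation, not rounding
  zero <- mutationRate(0)
  expect_equal(zero$meanCount, 0)
  expect_equal(zero$ratePerMb, 0)
})

test_that("candidate genes rank by CDS-normalized allele frequency", {
  rk <- rankCandidateGenes(gpiPathway())
  expect_lt(which(rk$gene == "Pigu"), which(rk$gene == "Pigo"))
  expect_true(all(diff(rk$allelesPerBp) <= 0))

  tie <- PathwayModel(c("long", "short"), c(300L, 100L),
                      observedAlleles = c(3L, 3L))
  expect_identical(rankCandidateGenes(tie)$gene[1L], "short")
  none <- PathwayModel(c("b", "a"), c(10L, 10L),
                       observedAlleles = c(0L, 0L))
  expect_identical(rankCandidateGenes(none)$gene, c("a", "b"))
})

test_that("site calls round-trip through delimited text and VCF", {
  calls <- generateCloneCallset(callsetConfig(meanMutations = 30),
                                nClones = 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readSiteCalls(f)
  expect_equal(back$mutantAltFraction, calls$mutantAltFraction)
  expect_identical(nrow(filterTrueMutations(back)),
                   nrow(filterTrueMutations(calls)))

  # minimal paired single-sample VCFs: AD-derived fractions, GT zygosity
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  mutF <- withr::local_tempfile(fileext = ".vcf")
  ctlF <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr,
               "chr1\t100\t.\tG\tA\t50\tPASS\t.\tGT:AD\t1:2,98",
               "chr1\t200\t.\tA\tC\t50\tPASS\t.\tGT:AD\t1:40,60",
               "chr1\t300\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:55,45"), mutF)
  writeLines(c(hdr,
               "chr1\t200\t.\tA\tC\t50\tPASS\t.\tGT:AD\t0:90,10"), ctlF)
  pairs <- readVcfCallPairs(mutF, ctlF)
  expect_identical(nrow(pairs), 3L)
  expect_equal(pairs$mutantAltFraction, c(0.98, 0.60, 0.45))
  expect_equal(pairs$controlRefFraction, c(1, 0.90, 1))
  expect_identical(pairs$zygosity,
                   c("homozygous", "homozygous", "heterozygous"))
  expect_identical(filterTrueMutations(pairs)$pos, 100L)
})
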
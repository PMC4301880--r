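test_that("synthetic screens are seed-deterministic with truth attached", {
  gpi <- gpiPathway()
  a <- generateScreen(gpi, clones = 114, seed = 6)
  b <- generateScreen(gpi, clones = 114, seed = 6)
  expect_identical(a, b)
  expect_identical(sum(a$alleles), a$totalAlleles)
  expect_identical(nrow(a$truth), 114L)
  # every causative gene in the truth table is a pathway gene
  expect_true(all(unlist(strsplit(a$truth$genes, ",")) %in% geneNames(gpi)))
})

test_that("a single clone without double hits yields exactly one allele", {
  one <- generateScreen(gpiPathway(), clones = 1, doubleHitProb = 0,
                        seed = 2)
  expect_identical(one$totalAlleles, 1L)
  expect_identical(sum(one$alleles), 1L)
})

test_that("the double-hit rate calibrates the expected allele total", {
  gpi <- gpiPathway()
  totals <- vapply(1:100, function(s) {
    generateScreen(gpi, clones = 114, doubleHitProb = 1 / 114,
                   seed = 1000 + s)$totalAlleles
  }, integer(1L))
  expect_true(all(totals >= 114))
  # E[total] = 114 * (1 + 1/114) = 115; SE of the mean over 100 screens
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 115), 3 * se + 0.05)
})

test_that("call sets recover the configured per-clone mean count", {
  calls <- generateCloneCallset(callsetConfig(), nClones = 60, seed = 31)
  perClone <- tapply(calls$isTrue, calls$clone, sum)
  expect_identical(length(perClone), 60L)
  se <- sd(perClone) / sqrt(length(perClone))
  expect_lt(abs(mean(perClone) - 233.1), 3 * se)
})

test_that("call-set positions are unique within each clone", {
  calls <- generateCloneCallset(callsetConfig(), nClones = 4, seed = 8)
  expect_false(any(tapply(calls$pos, calls$clone,
                          function(x) any(duplicated(x)))))
  expect_identical(calls,
                   generateCloneCallset(callsetConfig(), nClones = 4,
                                        seed = 8))
})

test_that("an exome too small for the requested sites errors", {
  tiny <- callsetConfig(exomeSizeMb = 1e-5, meanMutations = 500,
                        dispersion = 1e6)
  expect_error(generateCloneCallset(tiny, nClones = 1, seed = 1),
               "exome too small")
})

test_that("without decoys the filter reproduces the truth set exactly", {
  calls <- generateCloneCallset(clearMarginConfig(decoyFraction = 0),
                                nClones = 2, seed = 13)
  expect_true(all(calls$isTrue))
  expect_identical(nrow(filterTrueMutations(calls)), nrow(calls))
})

test_that("non-substitution mutation types appear at the configured rate", {
  calls <- generateCloneCallset(
    callsetConfig(meanMutations = 3000, dispersion = 1e8,
                  decoyFraction = 0),
    nClones = 1, seed = 23
  )
  frac <- mean(calls$type == "substitution")
  se <- sqrt(0.985 * 0.015 / nrow(calls))
  expect_lt(abs(frac - 0.985), 3 * se)
})

test_that("the validation experiment reproduces its design points", {
  expect_identical(generateValidationExperiment(),
                   matrix(c(19L, 1L, 0L, 22L), 2, byrow = TRUE,
                          dimnames = list(c("filterPositive",
                                            "filterNegative"),
                                          c("sangerDetected",
                                            "sangerNotDetected"))))
  perfect <- generateValidationExperiment(confirmRateTrue = 1,
                                          detectRateFalse = 0)
  expect_identical(as.integer(perfect), c(20L, 0L, 0L, 22L))
  expect_equal(signif(fisherExactTwoSided(generateValidationExperiment()),
                      2), 4.5e-11)
  degen <- generateValidationExperiment(nTrue = 0)
  expect_message(p <- fisherExactTwoSided(degen), "degenerate")
  expect_equal(p, 1)
  # stochastic mode is seed-deterministic and respects margins
  s1 <- generateValidationExperiment(deterministic = FALSE, seed = 4)
  s2 <- generateValidationExperiment(deterministic = FALSE, seed = 4)
  expect_identical(s1, s2)
  expect_identical(rowSums(s1), c(filterPositive = 20, filterNegative = 22))
})

test_that("sampled percentile pathways draw lengths from the bins", {
  pm <- samplePercentilePathway(50, seed = 5)
  expect_identical(nGenes(pm), 50L)
  expect_true(all(cdsLengths(pm) %in% defaultPercentileLengths()))
  expect_identical(cdsLengths(samplePercentilePathway(50, seed = 5)),
                   cdsLengths(pm))
})
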
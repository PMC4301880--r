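#' Simulate one saturation-mutagenesis screen
#'
#' Assigns `m` mutagenic hits (mutant alleles) to the genes of `model`, each
#' hit independently landing in gene `i` with probability proportional to its
#' CDS length. This categorical sampling is equivalent to drawing a uniform
#' nucleotide coordinate on the concatenated CDS block and mapping it back
#' with [locateGene()]; the categorical form avoids materializing the block.
#'
#' Randomness comes from R's global generator (Mersenne-Twister by default);
#' passing `seed` gives a reproducible result without disturbing the caller's
#' random-number state.
#'
#' @param model a [PathwayModel-class].
#' @param m positive integer, number of alleles to assign.
#' @param seed optional integer seed for reproducibility.
#' @return A [ScreenResult-class] with per-gene counts summing to `m`.
#' @examples
#' res <- simulateScreen(gpiPathway(), m = 115, seed = 1)
#' genesCovered(res)
#' @export
simulateScreen <- function(model, m, seed = NULL) {
  stopifnot(is(model, "PathwayModel"))
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be >= 1")
  m <- as.integer(m)
  if (!is.null(seed)) withr::local_seed(seed)
  hits <- sample.int(nGenes(model), m, replace = TRUE,
                     prob = hitProbabilities(model))
  counts <- tabulate(hits, nbins = nGenes(model))
  new("ScreenResult",
      m = m,
      counts = stats::setNames(as.integer(counts), geneNames(model)),
      covered = sum(counts > 0L))
}

#' @describeIn ScreenResult-accessors per-gene allele counts, named by gene
#' @export
setMethod("alleleCounts", "ScreenResult", function(object) object@counts)

#' Accessors for ScreenResult and ReplicateSummary
#'
#' @param object a [ScreenResult-class] or [ReplicateSummary-class].
#' @name ScreenResult-accessors
#' @describeIn ScreenResult-accessors number of distinct genes hit
#' @export
setMethod("genesCovered", "ScreenResult", function(object) object@covered)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", object@m, "alleles over", length(object@counts),
      "genes;", object@covered, "genes covered\n")
})

#' Replicate screen simulations with box-plot summaries
#'
#' Runs `R` independent screens of `m` alleles each and summarizes the
#' per-gene allele counts as medians, quartiles (type-7 sample quantiles) and
#' whisker bounds: the most extreme replicate values still within 1.5 times
#' the interquartile range beyond the quartiles.
#'
#' @param model a [PathwayModel-class].
#' @param m positive integer, alleles per screen.
#' @param R positive integer, number of replicate screens.
#' @param seed optional integer seed.
#' @return A [ReplicateSummary-class].
#' @examples
#' rs <- replicateRuns(gpiPathway(), m = 115, R = 20, seed = 1)
#' head(rs@stats)
#' @export
replicateRuns <- function(model, m, R, seed = NULL) {
  stopifnot(is(model, "PathwayModel"))
  if (length(R) != 1L || is.na(R) || R < 1) stop("R must be >= 1")
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be >= 1")
  R <- as.integer(R)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- t(stats::rmultinom(R, as.integer(m), hitProbabilities(model)))
  colnames(counts) <- geneNames(model)
  q <- apply(counts, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE)
  iqr <- q[3L, ] - q[1L, ]
  lo <- q[1L, ] - 1.5 * iqr
  hi <- q[3L, ] + 1.5 * iqr
  whisk <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    inside <- x[x >= lo[j] & x <= hi[j]]
    c(min(inside), max(inside))
  }, numeric(2L))
  stats <- data.frame(
    gene = geneNames(model),
    median = q[2L, ],
    q1 = q[1L, ],
    q3 = q[3L, ],
    whiskerLow = whisk[1L, ],
    whiskerHigh = whisk[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  new("ReplicateSummary", m = as.integer(m), replicates = R,
      stats = stats, counts = counts)
}

setMethod("show", "ReplicateSummary", function(object) {
  cat("ReplicateSummary:", object@replicates, "replicate screens of",
      object@m, "alleles over", nrow(object@stats), "genes\n")
})

#' Monte Carlo coverage distribution
#'
#' Empirical distribution of the number of distinct genes covered by `m`
#' alleles, over `R` simulated screens. `m = 0` is the degenerate
#' distribution at 0 covered genes. The exact counterpart is
#' [exactCoverageDistribution()]; the closed-form mean is
#' [expectedCoverage()].
#'
#' @param model a [PathwayModel-class].
#' @param m non-negative integer, alleles per screen.
#' @param R positive integer, number of simulated screens.
#' @param seed optional integer seed.
#' @return A [CoverageDistribution-class] with `replicates = R`.
#' @examples
#' cd <- coverageDistributionMC(gpiPathway(), m = 115, R = 1e4, seed = 1)
#' coverageMean(cd)
#' @export
coverageDistributionMC <- function(model, m, R = 1e5, seed = NULL) {
  stopifnot(is(model, "PathwayModel"))
  if (length(R) != 1L || is.na(R) || R < 1) stop("R must be >= 1")
  if (length(m) != 1L || is.na(m) || m < 0) stop("m must be >= 0")
  n <- nGenes(model)
  m <- as.integer(m)
  R <- as.integer(R)
  if (m == 0L) {
    pmf <- c(1, rep(0, n))
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    counts <- stats::rmultinom(R, m, hitProbabilities(model))
    covered <- colSums(counts > 0L)
    pmf <- tabulate(covered + 1L, nbins = n + 1L) / R
  }
  newCoverageDistribution(m, pmf, replicates = if (m == 0L) 0L else R)
}

# shared constructor; pmf over 0..n
newCoverageDistribution <- function(m, pmf, replicates) {
  names(pmf) <- as.character(seq_along(pmf) - 1L)
  new("CoverageDistribution",
      m = as.integer(m), pmf = pmf,
      expectation = sum((seq_along(pmf) - 1L) * pmf),
      replicates = as.integer(replicates))
}

#' @describeIn CoverageDistribution-accessors probability mass over 0..n
#'   covered genes
#' @export
setMethod("coverageMass", "CoverageDistribution",
          function(object) object@pmf)

#' Accessors for CoverageDistribution
#'
#' @param object a [CoverageDistribution-class].
#' @name CoverageDistribution-accessors
#' @describeIn CoverageDistribution-accessors distribution mean (expected
#'   number of covered genes)
#' @export
setMethod("coverageMean", "CoverageDistribution",
          function(object) object@expectation)

setMethod("show", "CoverageDistribution", function(object) {
  kind <- if (object@replicates == 0L) "exact" else
    paste0("Monte Carlo (R = ", object@replicates, ")")
  cat("CoverageDistribution (", kind, "): m = ", object@m,
      ", E[covered] = ", format(object@expectation, digits = 6), "\n",
      sep = "")
})
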
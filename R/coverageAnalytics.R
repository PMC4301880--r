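#' Closed-form expected coverage
#'
#' Expected number of distinct genes hit by `m` independent alleles under the
#' CDS-length-proportional model: `E[covered] = sum_i (1 - (1 - p_i)^m)`.
#' This is the exact mean of the simulated coverage histograms. Evaluated via
#' `exp(m * log1p(-p))` for numerical stability at large `m`.
#'
#' @param model a [PathwayModel-class].
#' @param m non-negative integer (vectorized), number of alleles.
#' @return Numeric vector of expected distinct-gene counts in `[0, n]`,
#'   one per element of `m`.
#' @examples
#' expectedCoverage(gpiPathway(), c(22, 40, 71, 115, 407))
#' @export
expectedCoverage <- function(model, m) {
  stopifnot(is(model, "PathwayModel"))
  if (any(is.na(m)) || any(m < 0)) stop("m must be >= 0")
  p <- hitProbabilities(model)
  vapply(m, function(mm) sum(-expm1(mm * log1p(-p))), numeric(1L))
}

#' Exact coverage distribution by inclusion-exclusion
#'
#' Exact probability mass of the number of distinct genes covered by `m`
#' alleles. For any gene subset `B`, the probability that all hits fall
#' inside `B` is `(sum_{i in B} p_i)^m`; Moebius inversion over subsets gives
#' `P(covered = k) = sum_c (-1)^(k-c) * choose(n-c, k-c) * S_c`, where `S_c`
#' is the sum of `(sum_{i in B} p_i)^m` over subsets of size `c`. Only the
#' size-grouped sums are needed, but they require enumerating all `2^n`
#' subsets, so `n` is guarded at 25; use [coverageDistributionMC()] beyond
#' that.
#'
#' @param model a [PathwayModel-class] with at most 25 genes.
#' @param m non-negative integer, number of alleles.
#' @return A [CoverageDistribution-class] with `replicates = 0` (exact).
#' @examples
#' d <- exactCoverageDistribution(PathwayModel(c("a", "b", "c"),
#'                                             c(1L, 1L, 2L)), m = 2)
#' coverageMass(d)
#' @export
exactCoverageDistribution <- function(model, m) {
  stopifnot(is(model, "PathwayModel"))
  if (length(m) != 1L || is.na(m) || m < 0) stop("m must be >= 0")
  n <- nGenes(model)
  if (n > 25L) {
    stop("exact enumeration guarded at n <= 25 genes; ",
         "use coverageDistributionMC() for larger models")
  }
  m <- as.integer(m)
  if (m == 0L) return(newCoverageDistribution(0L, c(1, rep(0, n)), 0L))
  p <- unname(hitProbabilities(model))
  # subset sums and sizes by iterative doubling over genes
  sums <- 0
  sizes <- 0L
  for (i in seq_len(n)) {
    sums <- c(sums, sums + p[i])
    sizes <- c(sizes, sizes + 1L)
  }
  q <- sums^m                       # P(all m hits inside the subset)
  S <- as.numeric(rowsum(q, sizes)) # S_c, c = 0..n, in stable order
  pmf <- vapply(0:n, function(k) {
    cc <- 0:k
    sum((-1)^(k - cc) * choose(n - cc, k - cc) * S[cc + 1L])
  }, numeric(1L))
  pmf[pmf < 0 & pmf > -1e-9] <- 0
  newCoverageDistribution(m, pmf, 0L)
}

#' Probability of discovering an unknown pathway gene
#'
#' If an additional, so far unseen gene of CDS length `newBp` exists beyond
#' the known genes totalling `totalBp`, each isolated allele misses it with
#' probability `totalBp / (totalBp + newBp)`; across `alleles` independent
#' alleles the discovery probability is
#' `1 - (totalBp / (totalBp + newBp))^alleles`.
#'
#' @param totalBp positive number, summed CDS length of the known genes (bp).
#' @param newBp positive number, CDS length of the hypothetical gene (bp).
#' @param alleles non-negative integer, number of isolated mutant alleles.
#' @return Probability in `[0, 1]`, increasing in both `alleles` and `newBp`.
#' @examples
#' discoveryProbability(23982, 213, 115)       # short, Pigy-sized gene
#' discoveryProbability(23982, 23982 / 22, 115) # average-sized gene
#' @export
discoveryProbability <- function(totalBp, newBp, alleles) {
  if (totalBp < 1) stop("totalBp must be >= 1")
  if (newBp <= 0) stop("newBp must be > 0")
  if (any(alleles < 0)) stop("alleles must be >= 0")
  -expm1(alleles * (log(totalBp) - log(totalBp + newBp)))
}

#' Degree of saturation of a screen
#'
#' Percentage of the essential genes recovered at least once, rounded to the
#' nearest whole percent (half away from zero).
#'
#' @param covered non-negative integer, distinct essential genes recovered.
#' @param essential positive integer, total essential genes.
#' @return Whole-percent saturation degree.
#' @examples
#' saturationDegree(20, 22)  # 91
#' @export
saturationDegree <- function(covered, essential) {
  if (essential < 1) stop("essential must be >= 1")
  if (covered < 0 || covered > essential) {
    stop("covered must lie in [0, essential]")
  }
  floor(100 * covered / essential + 0.5)
}

#' Correlation between CDS length and observed allele count
#'
#' Pearson product-moment correlation between per-gene CDS lengths and the
#' observed mutant-allele counts stored in the model, over genes with an
#' observed count.
#'
#' @param model a [PathwayModel-class] with `observedAlleles` for at least
#'   three genes.
#' @return Pearson correlation coefficient.
#' @examples
#' correlateAllelesWithLength(gpiPathway())  # about 0.59
#' @export
correlateAllelesWithLength <- function(model) {
  stopifnot(is(model, "PathwayModel"))
  keep <- !is.na(model@observedAlleles)
  if (sum(keep) < 3L) stop("need observed allele counts for >= 3 genes")
  x <- model@cdsLength[keep]
  y <- model@observedAlleles[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in lengths or allele counts")
  }
  stats::cor(x, y)
}
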
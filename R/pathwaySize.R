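#' CDS-length percentile bins of all mouse genes
#'
#' The 5th through 95th percentile (step 10) CDS lengths of all mouse genes,
#' used as ten representative bins when building pseudo-pathways for an
#' arbitrary pathway of `n` genes.
#'
#' @return Integer vector of the ten percentile CDS lengths (bp),
#'   non-decreasing.
#' @export
defaultPercentileLengths <- function() {
  c(378L, 615L, 825L, 954L, 1131L, 1365L, 1617L, 2022L, 2628L, 4131L)
}

#' Build a percentile-bin pseudo-pathway
#'
#' Constructs a [PathwayModel-class] of `n` genes whose CDS lengths cycle
#' through the ten percentile bins, smallest first (so `n = 40` concatenates
#' four copies of each bin; an `n` that is not a multiple of 10 takes the
#' leading bins of the final cycle).
#'
#' @param n positive integer, number of genes in the pseudo-pathway.
#' @param lengths percentile bin lengths; ten non-decreasing positive
#'   integers (default [defaultPercentileLengths()]).
#' @return A [PathwayModel-class] with genes `g1..gn`.
#' @examples
#' totalLength(buildPercentilePathway(10))  # 15666
#' @export
buildPercentilePathway <- function(n, lengths = defaultPercentileLengths()) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  if (length(lengths) != 10L || any(diff(lengths) < 0) || any(lengths < 1)) {
    stop("lengths must be ten non-decreasing positive bin lengths")
  }
  n <- as.integer(n)
  PathwayModel(paste0("g", seq_len(n)), rep(lengths, length.out = n))
}

#' Expected-coverage curve for an n-gene pseudo-pathway
#'
#' Expected number of distinct genes covered as a function of the cumulative
#' allele count, on the percentile-bin pseudo-pathway of `n` genes. The
#' default mode is the exact expectation (the mean of the simulated
#' distribution); `mode = "mc"` reproduces the Monte Carlo procedure
#' literally.
#'
#' @param n positive integer, pathway gene number.
#' @param mGrid positive integers, allele counts at which to evaluate.
#' @param mode `"exact"` (closed form) or `"mc"` (Monte Carlo mean).
#' @param lengths percentile bin lengths (default
#'   [defaultPercentileLengths()]).
#' @param R Monte Carlo replicates per grid point when `mode = "mc"`.
#' @param seed optional integer seed for the Monte Carlo mode.
#' @return data.frame with columns `m` and `expectedCovered`, ordered as
#'   `mGrid`.
#' @examples
#' coverageCurve(20, c(22, 40, 71, 115))
#' @export
coverageCurve <- function(n, mGrid, mode = c("exact", "mc"),
                          lengths = defaultPercentileLengths(),
                          R = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(mGrid)) stop("mGrid must be non-empty")
  model <- buildPercentilePathway(n, lengths)
  expected <- if (mode == "exact") {
    expectedCoverage(model, mGrid)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    vapply(mGrid, function(m) {
      coverageMean(coverageDistributionMC(model, m, R = R))
    }, numeric(1L))
  }
  data.frame(m = mGrid, expectedCovered = expected)
}

#' Estimate the number of genes essential for a pathway
#'
#' Compares observed screening steps (cumulative mutant alleles, cumulative
#' distinct genes covered) against the exact expected-coverage curves of
#' percentile-bin pseudo-pathways over a grid of candidate gene numbers, and
#' returns the candidate minimizing the summed squared deviation. Candidates
#' smaller than the maximum observed coverage cannot explain the data and are
#' excluded from the arg-min (their discrepancies are still reported); ties
#' resolve to the smallest candidate.
#'
#' @param observations data.frame with columns `alleles` and `covered`,
#'   non-decreasing in both, `covered <= alleles` row-wise.
#' @param nGrid candidate gene numbers (default `seq(10, 100, by = 10)`).
#' @param lengths percentile bin lengths (default
#'   [defaultPercentileLengths()]).
#' @return A [SizeEstimate-class].
#' @examples
#' steps <- data.frame(alleles = c(22, 40, 71, 115),
#'                     covered = c(11, 15, 18, 20))
#' bestN(estimateGeneNumber(steps))  # 20
#' @export
estimateGeneNumber <- function(observations, nGrid = seq(10L, 100L, by = 10L),
                               lengths = defaultPercentileLengths()) {
  if (!is.data.frame(observations) ||
      !all(c("alleles", "covered") %in% names(observations)) ||
      nrow(observations) < 1L) {
    stop("observations must be a data.frame with alleles and covered rows")
  }
  obs <- observations[order(observations$alleles), , drop = FALSE]
  if (any(diff(obs$covered) < 0)) {
    stop("covered must be non-decreasing in cumulative alleles")
  }
  if (any(obs$covered > obs$alleles) || any(obs$covered < 0)) {
    stop("covered must lie in [0, alleles] for every step")
  }
  if (!length(nGrid)) stop("nGrid must be non-empty")
  nGrid <- as.integer(sort(unique(nGrid)))
  disc <- vapply(nGrid, function(n) {
    curve <- coverageCurve(n, obs$alleles, mode = "exact", lengths = lengths)
    sum((obs$covered - curve$expectedCovered)^2)
  }, numeric(1L))
  feasible <- nGrid >= max(obs$covered)
  if (!any(feasible)) {
    stop("all candidate gene numbers are below the maximum observed coverage")
  }
  best <- nGrid[feasible][which.min(disc[feasible])]
  new("SizeEstimate", nGrid = nGrid, discrepancy = disc,
      bestN = as.integer(best),
      observations = data.frame(alleles = obs$alleles, covered = obs$covered))
}

#' Read screening steps from a delimited file
#'
#' Expects header columns `alleles` and `covered` (tab- or comma-delimited).
#'
#' @param path path to the steps file.
#' @return data.frame suitable for [estimateGeneNumber()].
#' @export
readScreenSteps <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("alleles", "covered") %in% names(tab))) {
    stop("steps file must have columns alleles and covered")
  }
  tab
}

#' @describeIn SizeEstimate-accessors the selected candidate gene number
#' @export
setMethod("bestN", "SizeEstimate", function(object) object@bestN)

#' Accessors for SizeEstimate
#'
#' @param object a [SizeEstimate-class].
#' @name SizeEstimate-accessors
#' @describeIn SizeEstimate-accessors per-candidate summed squared deviation,
#'   named by candidate gene number
#' @export
setMethod("discrepancies", "SizeEstimate", function(object) {
  stats::setNames(object@discrepancy, object@nGrid)
})

setMethod("show", "SizeEstimate", function(object) {
  cat("SizeEstimate over grid {", paste(object@nGrid, collapse = ", "),
      "}\n", sep = "")
  cat("  best n =", object@bestN, "(least-squares fit to",
      nrow(object@observations), "screening steps)\n")
})
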
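#' @import methods
NULL

#' PathwayModel: concatenated-CDS hit model for a pathway gene set
#'
#' Represents an ordered set of pathway genes with their coding-sequence (CDS)
#' lengths, conceptually concatenated into one continuous block of
#' `totalLength` nucleotides. A mutagenic hit lands on a uniformly drawn
#' coordinate of the block, so gene `i` is hit with probability
#' `L_i / totalLength`. Per-gene coordinate intervals are 1-based, closed, and
#' partition `[1, totalLength]` in gene order.
#'
#' @slot gene character vector of unique gene names, in input order.
#' @slot chromosome character vector of chromosome labels (may be `NA`).
#' @slot cdsLength integer vector of CDS lengths in bp, all `>= 1`.
#' @slot observedAlleles integer vector of observed mutant-allele counts
#'   (`NA` when the screen reported none for a gene set).
#' @slot totalLength integer, sum of `cdsLength`.
#'
#' @seealso [loadGeneTable()], [hitProbabilities()], [locateGene()]
#' @export
setClass("PathwayModel",
  representation(
    gene = "character",
    chromosome = "character",
    cdsLength = "integer",
    observedAlleles = "integer",
    totalLength = "integer"
  )
)

setValidity("PathwayModel", function(object) {
  msg <- character()
  n <- length(object@gene)
  if (n < 1L) msg <- c(msg, "model must contain at least one gene")
  if (anyDuplicated(object@gene)) msg <- c(msg, "gene names must be unique")
  if (length(object@cdsLength) != n || length(object@chromosome) != n ||
      length(object@observedAlleles) != n) {
    msg <- c(msg, "per-gene slots must have equal length")
  }
  if (any(is.na(object@cdsLength)) || any(object@cdsLength < 1L)) {
    msg <- c(msg, "all CDS lengths must be positive integers")
  }
  if (length(object@totalLength) != 1L ||
      !identical(object@totalLength, as.integer(sum(object@cdsLength)))) {
    msg <- c(msg, "totalLength must equal the sum of CDS lengths")
  }
  p <- object@cdsLength / sum(object@cdsLength)
  if (abs(sum(p) - 1) > 1e-12) msg <- c(msg, "hit probabilities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ScreenResult: one simulated or observed screen of m mutant alleles
#'
#' @slot m integer, number of mutagenic hits (mutant alleles) assigned.
#' @slot counts named integer vector of per-gene allele counts summing to `m`.
#' @slot covered integer, number of genes with at least one allele.
#' @export
setClass("ScreenResult",
  representation(m = "integer", counts = "integer", covered = "integer")
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (sum(object@counts) != object@m) msg <- c(msg, "counts must sum to m")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@covered != sum(object@counts > 0L)) {
    msg <- c(msg, "covered must count genes with at least one allele")
  }
  if (length(msg)) msg else TRUE
})

#' ReplicateSummary: box-plot summaries of replicate screen simulations
#'
#' Per-gene medians, quartiles and whisker bounds (most extreme replicate
#' values still within 1.5 times the interquartile range of the quartiles)
#' over `replicates` independent screens of `m` alleles each.
#'
#' @slot m integer, alleles per replicate screen.
#' @slot replicates integer, number of replicate screens.
#' @slot stats data.frame with columns `gene`, `median`, `q1`, `q3`,
#'   `whiskerLow`, `whiskerHigh`.
#' @slot counts integer matrix, replicates x genes, the raw simulated counts.
#' @export
setClass("ReplicateSummary",
  representation(m = "integer", replicates = "integer",
                 stats = "data.frame", counts = "matrix")
)

setValidity("ReplicateSummary", function(object) {
  s <- object@stats
  if (!all(c("gene", "median", "q1", "q3", "whiskerLow", "whiskerHigh") %in%
           names(s))) {
    return("stats must have gene/median/q1/q3/whiskerLow/whiskerHigh columns")
  }
  if (any(s$q1 > s$median | s$median > s$q3)) {
    return("quartiles must bracket the median for every gene")
  }
  TRUE
})

#' CoverageDistribution: probability mass of the number of covered genes
#'
#' Distribution of the number of distinct genes hit by `m` alleles, either
#' exact (inclusion-exclusion; `replicates == 0`) or Monte Carlo.
#'
#' @slot m integer, number of alleles.
#' @slot pmf numeric vector of probabilities for 0..n covered genes
#'   (names "0".."n"), summing to 1 within 1e-9.
#' @slot expectation numeric, the distribution mean.
#' @slot replicates integer, Monte Carlo replicate count (0 when exact).
#' @export
setClass("CoverageDistribution",
  representation(m = "integer", pmf = "numeric", expectation = "numeric",
                 replicates = "integer")
)

setValidity("CoverageDistribution", function(object) {
  msg <- character()
  if (abs(sum(object@pmf) - 1) > 1e-9) msg <- c(msg, "pmf must sum to 1")
  if (any(object@pmf < -1e-12)) msg <- c(msg, "pmf must be non-negative")
  k <- seq_along(object@pmf) - 1
  if (abs(sum(k * object@pmf) - object@expectation) > 1e-6) {
    msg <- c(msg, "expectation must equal the pmf mean")
  }
  if (length(msg)) msg else TRUE
})

#' SizeEstimate: essential-gene-number estimate from screening steps
#'
#' Result of fitting observed (cumulative alleles, cumulative covered genes)
#' screening steps against exact expected-coverage curves of percentile-bin
#' pseudo-pathways over a grid of candidate gene numbers.
#'
#' @slot nGrid integer vector of candidate gene numbers.
#' @slot discrepancy numeric vector, summed squared deviation between observed
#'   and expected coverage per candidate.
#' @slot bestN integer, feasible candidate minimizing the discrepancy
#'   (smallest candidate on ties).
#' @slot observations data.frame with columns `alleles`, `covered`.
#' @export
setClass("SizeEstimate",
  representation(nGrid = "integer", discrepancy = "numeric",
                 bestN = "integer", observations = "data.frame")
)

setValidity("SizeEstimate", function(object) {
  msg <- character()
  if (length(object@nGrid) != length(object@discrepancy)) {
    msg <- c(msg, "one discrepancy per candidate required")
  }
  if (any(object@discrepancy < 0)) msg <- c(msg, "discrepancies must be >= 0")
  if (!(object@bestN %in% object@nGrid)) {
    msg <- c(msg, "bestN must be a grid candidate")
  }
  if (length(msg)) msg else TRUE
})

#' SpectrumSummary: substitution-spectrum and impact tallies for a call set
#'
#' Counts of single-nucleotide substitutions per strand-collapsed base-pair
#' class, plus unclassified substitutions, indels and other mutation types,
#' and (when effect annotations are supplied) impact-category tallies.
#' Class fractions are computed over classified substitutions only.
#'
#' @slot classCounts named integer vector over the six base-pair classes.
#' @slot unclassified integer, substitutions without a resolvable class.
#' @slot indel integer, indel records.
#' @slot other integer, other mutation types.
#' @slot impact named integer vector: high, moderate, low, modifier.
#' @export
setClass("SpectrumSummary",
  representation(classCounts = "integer", unclassified = "integer",
                 indel = "integer", other = "integer", impact = "integer")
)

setValidity("SpectrumSummary", function(object) {
  msg <- character()
  if (!identical(names(object@classCounts), substitutionClasses())) {
    msg <- c(msg, "classCounts must cover the six base-pair classes in order")
  }
  if (!identical(names(object@impact),
                 c("high", "moderate", "low", "modifier"))) {
    msg <- c(msg, "impact must have high/moderate/low/modifier counts")
  }
  if (any(c(object@classCounts, object@unclassified, object@indel,
            object@other, object@impact) < 0L)) {
    msg <- c(msg, "all tallies must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
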
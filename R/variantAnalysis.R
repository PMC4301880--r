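#' The six strand-collapsed substitution classes
#'
#' Base-pair substitution classes in conventional order, anchored at the A:T
#' or G:C pair of the reference base.
#'
#' @return Character vector of the six class labels.
#' @export
substitutionClasses <- function() {
  c("A:T>G:C", "A:T>C:G", "A:T>T:A", "G:C>A:T", "G:C>C:G", "G:C>T:A")
}

#' Classify a single-nucleotide substitution
#'
#' Collapses a ref/alt base pair to its strand-symmetric base-pair class
#' (e.g. G>A and C>T both map to `G:C>A:T`) and labels it a transition
#' (purine-purine or pyrimidine-pyrimidine) or transversion.
#'
#' @param ref,alt character vectors of single bases in `A`, `C`, `G`, `T`;
#'   recycled to a common length; `ref[i] != alt[i]` required.
#' @return data.frame with columns `class` and `type`
#'   (`"transition"`/`"transversion"`).
#' @examples
#' classifySubstitution(c("G", "C", "A"), c("A", "T", "C"))
#' @export
classifySubstitution <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be single bases in A, C, G, T")
  }
  if (any(ref == alt)) stop("ref and alt must differ for a substitution")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # anchor at the A or G strand: complement pairs whose ref is T or C
  flip <- ref %in% c("T", "C")
  aRef <- ifelse(flip, comp[ref], ref)
  aAlt <- ifelse(flip, comp[alt], alt)
  pair <- c(A = "A:T", G = "G:C")[aRef]
  altPair <- c(A = "A:T", C = "C:G", G = "G:C", T = "T:A")[aAlt]
  cls <- paste0(pair, ">", altPair)
  purine <- c("A", "G")
  type <- ifelse((ref %in% purine) == (alt %in% purine),
                 "transition", "transversion")
  data.frame(class = cls, type = type, stringsAsFactors = FALSE)
}

#' Filter haploid true-positive mutations by read fractions
#'
#' A candidate mutation in a haploid clone is accepted as true-positive when
#' it is designated homozygous by the caller, strictly more than
#' `altThreshold` of the mutant clone's reads carry the alteration, and
#' strictly more than `refThreshold` of the untreated control's reads carry
#' the reference. When no `zygosity` column is supplied, a mutant alternate
#' fraction `>= 0.90` proxies the homozygous designation.
#'
#' @param calls data.frame with columns `mutantAltFraction`,
#'   `controlRefFraction`, and optionally `zygosity`
#'   (`"homozygous"`/`"heterozygous"`).
#' @param altThreshold alteration-read fraction cutoff in (0, 1); strict.
#' @param refThreshold control reference-read fraction cutoff in (0, 1);
#'   strict.
#' @param lenient when `TRUE`, rows with malformed fractions are dropped with
#'   a warning instead of raising an error.
#' @return The accepted rows of `calls`.
#' @export
filterTrueMutations <- function(calls, altThreshold = 0.90,
                                refThreshold = 0.95, lenient = FALSE) {
  stopifnot(is.data.frame(calls))
  if (altThreshold <= 0 || altThreshold >= 1 ||
      refThreshold <= 0 || refThreshold >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  need <- c("mutantAltFraction", "controlRefFraction")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns: ", paste(need, collapse = ", "))
  }
  af <- calls$mutantAltFraction
  rf <- calls$controlRefFraction
  bad <- is.na(af) | is.na(rf) | af < 0 | af > 1 | rf < 0 | rf > 1
  if (any(bad)) {
    if (!lenient) stop(sum(bad), " record(s) with malformed read fractions")
    warning("skipping ", sum(bad), " record(s) with malformed read fractions")
    calls <- calls[!bad, , drop = FALSE]
    af <- af[!bad]
    rf <- rf[!bad]
  }
  homo <- if ("zygosity" %in% names(calls)) {
    calls$zygosity == "homozygous"
  } else {
    af >= 0.90
  }
  calls[homo & af > altThreshold & rf > refThreshold, , drop = FALSE]
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: at fixed margins, sum the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one. A table with a zero margin carries no information and
#' returns `p = 1` by convention.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisherExactTwoSided(matrix(c(19, 0, 1, 22), 2))  # about 4.5e-11
#' @export
fisherExactTwoSided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be non-negative integers")
  }
  if (sum(tab) == 0) stop("at least one cell must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("degenerate margin; returning p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Tally mutation impact categories
#'
#' Maps effect labels from a controlled vocabulary to the four impact
#' categories used for haploid screen candidate triage:
#' \describe{
#'   \item{high}{`nonsense`, `splice_site`, `frameshift`, `start_lost` --
#'     assumed disruptive to the protein}
#'   \item{moderate}{`nonsynonymous`, `codon_insertion`, `codon_deletion` --
#'     non-disruptive but possibly altering protein effectiveness}
#'   \item{low}{`synonymous`}
#'   \item{modifier}{`start_gained`, `synonymous_stop`, `noncoding`,
#'     `intergenic`, `intron`, `utr`}
#' }
#' Labels outside the vocabulary count as modifier with a warning.
#'
#' @param effects character vector of effect labels.
#' @return Named integer vector: `high`, `moderate`, `low`, `modifier`.
#' @examples
#' impactTally(c("nonsense", "nonsynonymous", "synonymous", "intron"))
#' @export
impactTally <- function(effects) {
  vocab <- c(
    nonsense = "high", splice_site = "high", frameshift = "high",
    start_lost = "high",
    nonsynonymous = "moderate", codon_insertion = "moderate",
    codon_deletion = "moderate",
    synonymous = "low",
    start_gained = "modifier", synonymous_stop = "modifier",
    noncoding = "modifier", intergenic = "modifier", intron = "modifier",
    utr = "modifier"
  )
  out <- c(high = 0L, moderate = 0L, low = 0L, modifier = 0L)
  if (!length(effects)) return(out)
  unknown <- !(effects %in% names(vocab))
  if (any(unknown)) {
    warning("unknown effect label(s) counted as modifier: ",
            paste(unique(effects[unknown]), collapse = ", "))
  }
  cat4 <- ifelse(unknown, "modifier", vocab[effects])
  tallied <- table(factor(cat4, levels = names(out)))
  out[] <- as.integer(tallied)
  out
}

#' Summarize a call set's substitution spectrum
#'
#' Counts mutations per strand-collapsed substitution class, keeping
#' unclassifiable substitutions, indels and other mutation types in separate
#' tallies. When an `effect` column is present, impact categories are tallied
#' with [impactTally()].
#'
#' @param mutations data.frame with columns `ref` and `alt`; optional `type`
#'   (`"substitution"`, `"indel"`, `"other"`; defaults to substitution) and
#'   `effect`.
#' @return A [SpectrumSummary-class].
#' @examples
#' spectrumSummary(data.frame(ref = c("G", "C", "A"),
#'                            alt = c("A", "T", "C")))
#' @export
spectrumSummary <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  cls <- substitutionClasses()
  zero <- stats::setNames(integer(length(cls)), cls)
  if (nrow(mutations) == 0L) {
    return(new("SpectrumSummary", classCounts = zero, unclassified = 0L,
               indel = 0L, other = 0L,
               impact = c(high = 0L, moderate = 0L, low = 0L,
                          modifier = 0L)))
  }
  if (!all(c("ref", "alt") %in% names(mutations))) {
    stop("mutations must have ref and alt columns")
  }
  type <- if ("type" %in% names(mutations)) mutations$type else
    rep("substitution", nrow(mutations))
  isSub <- type == "substitution"
  ref <- toupper(as.character(mutations$ref[isSub]))
  alt <- toupper(as.character(mutations$alt[isSub]))
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases &
    ref != alt
  counts <- zero
  if (any(ok)) {
    k <- classifySubstitution(ref[ok], alt[ok])$class
    tallied <- table(factor(k, levels = cls))
    counts[] <- as.integer(tallied)
  }
  impact <- if ("effect" %in% names(mutations)) {
    impactTally(as.character(mutations$effect))
  } else {
    c(high = 0L, moderate = 0L, low = 0L, modifier = 0L)
  }
  new("SpectrumSummary",
      classCounts = counts,
      unclassified = sum(isSub) - sum(ok),
      indel = sum(type == "indel"),
      other = sum(!isSub & type != "indel"),
      impact = impact)
}

#' @describeIn SpectrumSummary-accessors per-class substitution counts
#' @export
setMethod("classCounts", "SpectrumSummary", function(object) {
  object@classCounts
})

#' Accessors for SpectrumSummary
#'
#' @param object a [SpectrumSummary-class].
#' @name SpectrumSummary-accessors
#' @describeIn SpectrumSummary-accessors class fractions over classified
#'   substitutions (sum to 1; all-NA when no substitution was classified)
#' @export
setMethod("classFractions", "SpectrumSummary", function(object) {
  tot <- sum(object@classCounts)
  if (tot == 0L) {
    return(stats::setNames(rep(NA_real_, length(object@classCounts)),
                           names(object@classCounts)))
  }
  object@classCounts / tot
})

#' @describeIn SpectrumSummary-accessors impact-category tallies
#' @export
setMethod("impactCounts", "SpectrumSummary", function(object) object@impact)

setMethod("show", "SpectrumSummary", function(object) {
  cat("SpectrumSummary:", sum(object@classCounts), "classified substitutions",
      "(", object@unclassified, "unclassified ),",
      object@indel, "indels,", object@other, "other\n")
  fr <- classFractions(object)
  if (!all(is.na(fr))) {
    cat("  ", paste0(names(fr), " ", sprintf("%.1f%%", 100 * fr),
                     collapse = ", "), "\n")
  }
})

#' Per-clone mutation counts and overall mutation rate
#'
#' Mean number of mutations per clone and the rate per megabase of captured
#' exome. The displayed rate truncates toward zero at two decimals; the
#' untruncated value is retained in the result.
#'
#' @param countsPerClone non-negative integer vector, one count per clone.
#' @param exomeSizeMb positive real, captured exome size in Mb.
#' @return List with `meanCount`, `ratePerMb` (raw) and `rateDisplay`
#'   (truncated to two decimals).
#' @examples
#' mutationRate(c(220, 297, 218, 10, 41, 511, 306, 330, 23, 375))
#' @export
mutationRate <- function(countsPerClone, exomeSizeMb = 49.3) {
  if (!length(countsPerClone)) stop("countsPerClone must be non-empty")
  if (any(is.na(countsPerClone)) || any(countsPerClone < 0)) {
    stop("counts must be non-negative")
  }
  if (exomeSizeMb <= 0) stop("exomeSizeMb must be positive")
  meanCount <- mean(countsPerClone)
  rate <- meanCount / exomeSizeMb
  list(meanCount = meanCount,
       ratePerMb = rate,
       rateDisplay = trunc(rate * 100) / 100)
}

#' Rank candidate genes by CDS-normalized allele frequency
#'
#' When screening hits accumulate, genes recurrently mutated relative to
#' their CDS length are the strongest candidates: the mutant-allele count is
#' divided by the CDS length, so a short gene with many alleles outranks a
#' long gene with the same count. Ties resolve to the smaller CDS first,
#' then to gene name.
#'
#' @param model a [PathwayModel-class] with observed allele counts (genes
#'   lacking a count are ranked as zero).
#' @return data.frame ordered by rank with columns `gene`, `alleles`,
#'   `cdsLength`, `allelesPerBp`.
#' @examples
#' head(rankCandidateGenes(gpiPathway()), 3)
#' @export
rankCandidateGenes <- function(model) {
  stopifnot(is(model, "PathwayModel"))
  alleles <- model@observedAlleles
  alleles[is.na(alleles)] <- 0L
  freq <- alleles / model@cdsLength
  ord <- order(-freq, model@cdsLength, model@gene)
  data.frame(gene = model@gene[ord],
             alleles = alleles[ord],
             cdsLength = model@cdsLength[ord],
             allelesPerBp = freq[ord],
             row.names = NULL,
             stringsAsFactors = FALSE)
}
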
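#' Default substitution-class probabilities for ENU call-set simulation
#'
#' The ENU exome spectrum used by [generateCloneCallset()]: G:C>A:T
#' transitions 46.7%, A:T>G:C transitions 20.4%, A:T transversions 25.1%
#' (split equally between A:T>C:G and A:T>T:A) and G:C transversions 7.9%
#' (split equally between G:C>C:G and G:C>T:A), renormalized to sum to 1.
#'
#' @return Named numeric probability vector over [substitutionClasses()].
#' @export
defaultEnuSpectrum <- function() {
  p <- c("A:T>G:C" = 0.204, "A:T>C:G" = 0.251 / 2, "A:T>T:A" = 0.251 / 2,
         "G:C>A:T" = 0.467, "G:C>C:G" = 0.079 / 2, "G:C>T:A" = 0.079 / 2)
  p <- p[substitutionClasses()]
  p / sum(p)
}

#' Configuration for synthetic clone call-set generation
#'
#' Bundles the statistical structure of a mutagenized haploid clone's exome
#' call set: an overdispersed per-clone mutation-count model, the
#' substitution spectrum, the fraction of substitutions among mutations, and
#' Beta-distributed read fractions for true sites (concentrated near 1, the
#' haploid homozygous signature), decoy sites (intermediate, straddling the
#' filter threshold) and control reference reads.
#'
#' @param exomeSizeMb captured exome size in Mb.
#' @param meanMutations mean true-mutation count per clone.
#' @param dispersion negative-binomial size parameter of the count model
#'   (method-of-moments fit to the observed per-clone totals).
#' @param spectrum substitution-class probabilities
#'   (default [defaultEnuSpectrum()]).
#' @param substitutionFraction fraction of mutations that are
#'   single-nucleotide substitutions; the remainder are indels/other types.
#' @param decoyFraction fraction of emitted candidate sites that are decoys
#'   (sequencing/calling artifacts expected to fail the read-fraction
#'   filter).
#' @param trueAltShape,decoyAltShape,controlRefShape,decoyControlRefShape
#'   Beta shape pairs for the respective read-fraction distributions.
#' @return A validated configuration list of class `callsetConfig`.
#' @export
callsetConfig <- function(exomeSizeMb = 49.3,
                          meanMutations = 233.1,
                          dispersion = 2,
                          spectrum = defaultEnuSpectrum(),
                          substitutionFraction = 0.985,
                          decoyFraction = 0.10,
                          trueAltShape = c(60, 1.5),
                          decoyAltShape = c(8, 4),
                          controlRefShape = c(90, 1.5),
                          decoyControlRefShape = c(12, 3)) {
  if (exomeSizeMb <= 0) stop("exomeSizeMb must be positive")
  if (meanMutations <= 0 || dispersion <= 0) {
    stop("meanMutations and dispersion must be positive")
  }
  if (!identical(names(spectrum), substitutionClasses()) ||
      any(spectrum < 0)) {
    stop("spectrum must be non-negative over the six substitution classes")
  }
  if (substitutionFraction < 0 || substitutionFraction > 1 ||
      decoyFraction < 0 || decoyFraction >= 1) {
    stop("fractions must lie in [0, 1] (decoyFraction < 1)")
  }
  structure(list(
    exomeSizeMb = exomeSizeMb,
    meanMutations = meanMutations,
    dispersion = dispersion,
    spectrum = spectrum / sum(spectrum),
    substitutionFraction = substitutionFraction,
    decoyFraction = decoyFraction,
    trueAltShape = trueAltShape,
    decoyAltShape = decoyAltShape,
    controlRefShape = controlRefShape,
    decoyControlRefShape = decoyControlRefShape
  ), class = "callsetConfig")
}

#' Simulate a clone-resolved mutagenesis screen with truth labels
#'
#' Emulates independent isolation of resistant clones: each clone carries one
#' causative hit drawn from the model's hit-probability measure, or -- with a
#' small probability mirroring double mutants -- two independent hits, each
#' counted as one mutant allele.
#'
#' @param model a [PathwayModel-class] defining the pathway.
#' @param clones positive integer, number of resistant clones isolated.
#' @param doubleHitProb probability in `[0, 1)` that a clone carries two
#'   causative hits.
#' @param seed optional integer seed.
#' @return List with `alleles` (named per-gene allele counts),
#'   `truth` (data.frame `clone`, `genes` -- comma-joined causative genes),
#'   and `totalAlleles`.
#' @examples
#' sc <- generateScreen(gpiPathway(), clones = 114, seed = 1)
#' sc$totalAlleles
#' @export
generateScreen <- function(model, clones, doubleHitProb = 1 / clones,
                           seed = NULL) {
  stopifnot(is(model, "PathwayModel"))
  if (length(clones) != 1L || is.na(clones) || clones < 1) {
    stop("clones must be >= 1")
  }
  if (doubleHitProb < 0 || doubleHitProb >= 1) {
    stop("doubleHitProb must lie in [0, 1)")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  clones <- as.integer(clones)
  p <- hitProbabilities(model)
  nHits <- 1L + stats::rbinom(clones, 1L, doubleHitProb)
  genes <- lapply(nHits, function(k) {
    geneNames(model)[sample.int(nGenes(model), k, replace = TRUE, prob = p)]
  })
  counts <- table(factor(unlist(genes), levels = geneNames(model)))
  list(
    alleles = stats::setNames(as.integer(counts), geneNames(model)),
    truth = data.frame(clone = paste0("clone", seq_len(clones)),
                       genes = vapply(genes, paste, "", collapse = ","),
                       stringsAsFactors = FALSE),
    totalAlleles = sum(nHits)
  )
}

#' Generate paired mutant/control call sets for synthetic clones
#'
#' For each clone, draws a negative-binomial number of true mutations,
#' places them at unique positions on a linearized exome, assigns mutation
#' types and substitution classes from the configured spectrum (strand
#' orientation uniform), and attaches read fractions: true sites concentrate
#' near 1 in the mutant and near 1 for reference reads in the control, while
#' decoy sites draw intermediate fractions that straddle the filter
#' thresholds. All sites carry the caller's homozygous designation and a
#' truth label.
#'
#' @param config a [callsetConfig()].
#' @param nClones positive integer, number of clones.
#' @param seed optional integer seed.
#' @return data.frame with one row per candidate site: `clone`, `chrom`,
#'   `pos`, `ref`, `alt`, `type`, `class`, `mutantAltFraction`,
#'   `controlRefFraction`, `zygosity`, `isTrue`.
#' @examples
#' calls <- generateCloneCallset(callsetConfig(), nClones = 2, seed = 1)
#' table(calls$isTrue)
#' @export
generateCloneCallset <- function(config = callsetConfig(), nClones = 10,
                                 seed = NULL) {
  stopifnot(inherits(config, "callsetConfig"))
  if (nClones < 1) stop("nClones must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  exomeBp <- round(config$exomeSizeMb * 1e6)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # one strand orientation per class: (anchored ref, anchored alt)
  anchored <- list("A:T>G:C" = c("A", "G"), "A:T>C:G" = c("A", "C"),
                   "A:T>T:A" = c("A", "T"), "G:C>A:T" = c("G", "A"),
                   "G:C>C:G" = c("G", "C"), "G:C>T:A" = c("G", "T"))
  perClone <- lapply(seq_len(nClones), function(cl) {
    nTrue <- stats::rnbinom(1L, size = config$dispersion,
                            mu = config$meanMutations)
    nDecoy <- round(nTrue * config$decoyFraction /
                      (1 - config$decoyFraction))
    nSites <- nTrue + nDecoy
    if (nSites == 0L) return(NULL)
    if (nSites > exomeBp) stop("exome too small for requested site count")
    pos <- sample.int(exomeBp, nSites, replace = FALSE)
    isTrue <- rep(c(TRUE, FALSE), c(nTrue, nDecoy))
    isSub <- stats::runif(nSites) < config$substitutionFraction
    cls <- rep(NA_character_, nSites)
    ref <- alt <- rep(NA_character_, nSites)
    if (any(isSub)) {
      k <- sample(substitutionClasses(), sum(isSub), replace = TRUE,
                  prob = config$spectrum)
      flip <- stats::runif(sum(isSub)) < 0.5
      r <- vapply(anchored[k], `[`, "", 1L)
      a <- vapply(anchored[k], `[`, "", 2L)
      ref[isSub] <- ifelse(flip, comp[r], r)
      alt[isSub] <- ifelse(flip, comp[a], a)
      cls[isSub] <- k
    }
    if (any(!isSub)) {
      ref[!isSub] <- sample(names(comp), sum(!isSub), replace = TRUE)
      alt[!isSub] <- ifelse(stats::runif(sum(!isSub)) < 0.5, "ins", "del")
    }
    type <- ifelse(isSub, "substitution",
                   ifelse(alt %in% c("ins", "del"), "indel", "other"))
    af <- ifelse(isTrue,
                 stats::rbeta(nSites, config$trueAltShape[1L],
                              config$trueAltShape[2L]),
                 stats::rbeta(nSites, config$decoyAltShape[1L],
                              config$decoyAltShape[2L]))
    rf <- ifelse(isTrue,
                 stats::rbeta(nSites, config$controlRefShape[1L],
                              config$controlRefShape[2L]),
                 stats::rbeta(nSites, config$decoyControlRefShape[1L],
                              config$decoyControlRefShape[2L]))
    data.frame(clone = paste0("clone", cl), chrom = "exome", pos = pos,
               ref = ref, alt = alt, type = type, class = cls,
               mutantAltFraction = af, controlRefFraction = rf,
               zygosity = "homozygous", isTrue = isTrue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, perClone)
  if (is.null(out)) {
    stop("no sites generated; increase meanMutations or nClones")
  }
  rownames(out) <- NULL
  out
}

#' Simulate a Sanger validation experiment as a 2x2 table
#'
#' Emulates Sanger re-sequencing of filter-positive ("true-positive") and
#' filter-negative ("false-positive") candidate mutations. In deterministic
#' mode the cells are the expected counts at the configured rates; in
#' stochastic mode they are binomial draws.
#'
#' @param nTrue,nFalse numbers of filter-positive / filter-negative
#'   candidates re-sequenced.
#' @param confirmRateTrue probability a filter-positive site is confirmed.
#' @param detectRateFalse probability a filter-negative site is detected.
#' @param deterministic use expected counts instead of binomial draws.
#' @param seed optional integer seed (stochastic mode).
#' @return 2x2 integer matrix with rows `filterPositive`/`filterNegative`
#'   and columns `sangerDetected`/`sangerNotDetected`.
#' @examples
#' generateValidationExperiment()  # the 19/1/0/22 design point
#' @export
generateValidationExperiment <- function(nTrue = 20, nFalse = 22,
                                         confirmRateTrue = 19 / 20,
                                         detectRateFalse = 0,
                                         deterministic = TRUE,
                                         seed = NULL) {
  if (any(c(confirmRateTrue, detectRateFalse) < 0) ||
      any(c(confirmRateTrue, detectRateFalse) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (nTrue < 0 || nFalse < 0) stop("candidate counts must be >= 0")
  a <- if (deterministic) {
    round(nTrue * confirmRateTrue)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    stats::rbinom(1L, nTrue, confirmRateTrue)
  }
  c_ <- if (deterministic) {
    round(nFalse * detectRateFalse)
  } else {
    stats::rbinom(1L, nFalse, detectRateFalse)
  }
  matrix(as.integer(c(a, nTrue - a, c_, nFalse - c_)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("filterPositive", "filterNegative"),
                         c("sangerDetected", "sangerNotDetected")))
}

#' Sample a pathway model from the percentile length distribution
#'
#' Continuous-length analogue of [buildPercentilePathway()]: gene lengths are
#' sampled with replacement from the percentile bins rather than cycled
#' deterministically. Useful for sensitivity checks of the estimator; the
#' canonical estimation path uses the deterministic cycling.
#'
#' @param n positive integer, number of genes.
#' @param lengths percentile bin lengths (default
#'   [defaultPercentileLengths()]).
#' @param seed optional integer seed.
#' @return A [PathwayModel-class].
#' @export
samplePercentilePathway <- function(n, lengths = defaultPercentileLengths(),
                                    seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  PathwayModel(paste0("g", seq_len(n)),
               sample(lengths, as.integer(n), replace = TRUE))
}
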
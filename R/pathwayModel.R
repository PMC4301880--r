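#' Construct a PathwayModel from gene names and CDS lengths
#'
#' The genes are conceptually concatenated, in the given order, into one
#' continuous block; a mutagenic hit is a uniform draw of a nucleotide
#' coordinate on the block, so each gene is hit with probability
#' proportional to its CDS length.
#'
#' @param gene character vector of unique gene names.
#' @param cdsLength positive integer vector of CDS lengths (bp).
#' @param chromosome optional chromosome labels.
#' @param observedAlleles optional observed mutant-allele counts.
#' @return A [PathwayModel-class] object.
#' @examples
#' pm <- PathwayModel(c("a", "b"), c(3L, 2L))
#' hitProbabilities(pm)
#' @export
PathwayModel <- function(gene, cdsLength, chromosome = NULL,
                         observedAlleles = NULL) {
  gene <- as.character(gene)
  n <- length(gene)
  if (!length(cdsLength)) stop("at least one gene is required")
  if (any(is.na(cdsLength)) || any(cdsLength <= 0) ||
      any(cdsLength != as.integer(cdsLength))) {
    stop("CDS lengths must be positive integers")
  }
  if (anyDuplicated(gene)) stop("duplicate gene name: ",
                                gene[duplicated(gene)][1L])
  if (is.null(chromosome)) chromosome <- rep(NA_character_, n)
  if (is.null(observedAlleles)) observedAlleles <- rep(NA_integer_, n)
  new("PathwayModel",
      gene = gene,
      chromosome = as.character(chromosome),
      cdsLength = as.integer(cdsLength),
      observedAlleles = as.integer(observedAlleles),
      totalLength = as.integer(sum(cdsLength)))
}

#' Load a gene table into a PathwayModel
#'
#' Reads a tab- or comma-delimited table with header columns `gene`,
#' `cds_length_bp`, and optionally `chromosome` and `alleles`. Rows flagged
#' unavailable (`NA` in `cds_length_bp`, or in `alleles` when that column is
#' present) are dropped with a message: such rows mark genes excluded from
#' the screen, not data errors.
#'
#' @param path path to the delimited text file (delimiter sniffed from the
#'   header line; tab or comma).
#' @return A [PathwayModel-class] over the retained genes, in file order.
#' @examples
#' tab <- system.file("extdata", "gpi_gene_table.tsv", package = "satmut")
#' gpi <- loadGeneTable(tab)
#' totalLength(gpi)
#' @export
loadGeneTable <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("gene", "cds_length_bp")
  if (!all(required %in% names(tab))) {
    stop("gene table must have columns: ", paste(required, collapse = ", "))
  }
  drop <- is.na(tab$cds_length_bp)
  if ("alleles" %in% names(tab)) drop <- drop | is.na(tab$alleles)
  if (any(drop)) {
    message("dropping ", sum(drop), " gene(s) flagged unavailable: ",
            paste(tab$gene[drop], collapse = ", "))
    tab <- tab[!drop, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no usable genes in ", path)
  PathwayModel(
    gene = tab$gene,
    cdsLength = tab$cds_length_bp,
    chromosome = if ("chromosome" %in% names(tab)) tab$chromosome else NULL,
    observedAlleles = if ("alleles" %in% names(tab)) tab$alleles else NULL
  )
}

#' The packaged GPI-anchor pathway gene table
#'
#' Convenience loader for the bundled 26-row gene table of the GPI-anchor
#' biosynthesis pathway (gene, chromosome, CDS length, observed mutant-allele
#' count). Four genes with hypomorphic phenotypes or excluded from screening
#' are flagged `NA` and dropped, leaving the 22 essential genes whose CDS
#' lengths total 23,982 bp and whose observed alleles total 115.
#'
#' @return A 22-gene [PathwayModel-class].
#' @examples
#' gpi <- gpiPathway()
#' nGenes(gpi)
#' @export
gpiPathway <- function() {
  suppressMessages(
    loadGeneTable(system.file("extdata", "gpi_gene_table.tsv",
                              package = "satmut"))
  )
}

#' @describeIn PathwayModel-accessors gene names in model order
#' @export
setMethod("geneNames", "PathwayModel", function(object) object@gene)

#' Accessors for PathwayModel
#'
#' @param object a [PathwayModel-class].
#' @name PathwayModel-accessors
#' @describeIn PathwayModel-accessors CDS lengths (bp), named by gene
#' @export
setMethod("cdsLengths", "PathwayModel", function(object) {
  stats::setNames(object@cdsLength, object@gene)
})

#' @describeIn PathwayModel-accessors observed mutant-allele counts, named
#' @export
setMethod("observedAlleles", "PathwayModel", function(object) {
  stats::setNames(object@observedAlleles, object@gene)
})

#' @describeIn PathwayModel-accessors total concatenated CDS length (bp)
#' @export
setMethod("totalLength", "PathwayModel", function(object) object@totalLength)

#' @describeIn PathwayModel-accessors number of genes
#' @export
setMethod("nGenes", "PathwayModel", function(object) length(object@gene))

#' Per-gene hit probabilities
#'
#' Probability that a single mutagenic hit lands in each gene:
#' `p_i = L_i / sum(L)`, where `L_i` is the CDS length of gene `i`.
#'
#' @param model a [PathwayModel-class].
#' @return Named numeric vector of probabilities summing to 1.
#' @export
setMethod("hitProbabilities", "PathwayModel", function(model) {
  stats::setNames(model@cdsLength / sum(model@cdsLength), model@gene)
})

#' Map concatenated-block coordinates back to gene names
#'
#' Coordinates are 1-based and inclusive: gene `i` owns the closed interval
#' `[1 + sum(L_1..L_{i-1}), sum(L_1..L_i)]`.
#'
#' @param model a [PathwayModel-class].
#' @param coordinate integer vector of coordinates in `[1, totalLength]`.
#' @return Character vector of gene names, one per coordinate.
#' @examples
#' pm <- PathwayModel(c("a", "b"), c(3L, 2L))
#' locateGene(pm, 1:5)
#' @export
locateGene <- function(model, coordinate) {
  stopifnot(is(model, "PathwayModel"))
  if (any(is.na(coordinate)) || any(coordinate < 1) ||
      any(coordinate > model@totalLength)) {
    stop("coordinate out of range [1, ", model@totalLength, "]")
  }
  bounds <- c(0, cumsum(as.numeric(model@cdsLength)))
  idx <- findInterval(coordinate, bounds, left.open = TRUE)
  model@gene[idx]
}

#' Equal-rate null model
#'
#' The simplest null in which every gene is mutated at an identical rate,
#' built as `n` genes of unit CDS length (so `p_i = 1/n`). Used to contrast
#' the CDS-length-proportional model against the identical-rate assumption.
#'
#' @param n positive integer, number of genes.
#' @return A [PathwayModel-class] with genes `g1..gn` of length 1 bp.
#' @export
identicalRateModel <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  PathwayModel(paste0("g", seq_len(n)), rep(1L, as.integer(n)))
}

setMethod("show", "PathwayModel", function(object) {
  cat("PathwayModel with", length(object@gene), "genes,",
      object@totalLength, "bp concatenated CDS\n")
  p <- hitProbabilities(object)
  k <- min(5L, length(p))
  cat("  genes:", paste(object@gene[seq_len(k)], collapse = ", "),
      if (length(p) > k) "..." else "", "\n")
  if (!all(is.na(object@observedAlleles))) {
    cat("  observed alleles:", sum(object@observedAlleles, na.rm = TRUE),
        "\n")
  }
})
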
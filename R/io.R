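#' Read paired mutant/control site calls from delimited text
#'
#' Canonical call-table input: one row per exome site with the mutant
#' clone's alternate-read fraction and the untreated control's
#' reference-read fraction at the same position. Header columns: `chrom`,
#' `pos`, `ref`, `alt`, `mutantAltFraction`, `controlRefFraction`; optional
#' `zygosity`, `type`, `effect`, `clone`.
#'
#' @param path path to a tab- or comma-delimited file.
#' @return data.frame of site-call pairs suitable for
#'   [filterTrueMutations()] and [spectrumSummary()].
#' @export
readSiteCalls <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "mutantAltFraction",
            "controlRefFraction")
  if (!all(need %in% names(tab))) {
    stop("site-call table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Read paired mutant/control site calls from single-sample VCFs
#'
#' Consumes two single-sample VCFs (mutant clone and untreated control) and
#' pairs records by chromosome and position. Read fractions are derived from
#' the `AD` (allelic depth) FORMAT field; zygosity from `GT` (`1`, `1/1` or
#' `1|1` designate homozygous alternate). Sites absent from the control VCF
#' are taken as fully reference in the control (`controlRefFraction = 1`).
#' Multi-allelic records are skipped.
#'
#' @param mutantVcf,controlVcf paths to single-sample VCF files.
#' @return data.frame of site-call pairs as in [readSiteCalls()].
#' @export
readVcfCallPairs <- function(mutantVcf, controlVcf) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package")
  }
  parseOne <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix  # always a character matrix, even for one record
    gt <- vcfR::extract.gt(v, element = "GT")
    ad <- vcfR::extract.gt(v, element = "AD")
    keep <- !grepl(",", fix[, "ALT"])
    adMat <- do.call(rbind, lapply(strsplit(ad[keep, 1L], ","), as.numeric))
    depth <- rowSums(adMat)
    data.frame(
      chrom = fix[keep, "CHROM"],
      pos = as.integer(fix[keep, "POS"]),
      ref = fix[keep, "REF"],
      alt = fix[keep, "ALT"],
      altFraction = ifelse(depth > 0, adMat[, 2L] / depth, NA_real_),
      refFraction = ifelse(depth > 0, adMat[, 1L] / depth, NA_real_),
      zygosity = ifelse(gt[keep, 1L] %in% c("1", "1/1", "1|1"),
                        "homozygous", "heterozygous"),
      stringsAsFactors = FALSE
    )
  }
  mut <- parseOne(mutantVcf)
  ctl <- parseOne(controlVcf)
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  idx <- match(key(mut), key(ctl))
  data.frame(
    chrom = mut$chrom,
    pos = mut$pos,
    ref = mut$ref,
    alt = mut$alt,
    type = ifelse(nchar(mut$ref) == 1L & nchar(mut$alt) == 1L,
                  "substitution", "indel"),
    mutantAltFraction = mut$altFraction,
    controlRefFraction = ifelse(is.na(idx), 1, ctl$refFraction[idx]),
    zygosity = mut$zygosity,
    stringsAsFactors = FALSE
  )
}
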
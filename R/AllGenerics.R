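#' @rdname PathwayModel-accessors
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname PathwayModel-accessors
#' @export
setGeneric("cdsLengths", function(object) standardGeneric("cdsLengths"))

#' @rdname PathwayModel-accessors
#' @export
setGeneric("observedAlleles",
           function(object) standardGeneric("observedAlleles"))

#' @rdname PathwayModel-accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))

#' @rdname PathwayModel-accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname hitProbabilities
#' @export
setGeneric("hitProbabilities",
           function(model) standardGeneric("hitProbabilities"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("alleleCounts", function(object) standardGeneric("alleleCounts"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("genesCovered", function(object) standardGeneric("genesCovered"))

#' @rdname CoverageDistribution-accessors
#' @export
setGeneric("coverageMass", function(object) standardGeneric("coverageMass"))

#' @rdname CoverageDistribution-accessors
#' @export
setGeneric("coverageMean", function(object) standardGeneric("coverageMean"))

#' @rdname SizeEstimate-accessors
#' @export
setGeneric("bestN", function(object) standardGeneric("bestN"))

#' @rdname SizeEstimate-accessors
#' @export
setGeneric("discrepancies", function(object) standardGeneric("discrepancies"))

#' @rdname SpectrumSummary-accessors
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname SpectrumSummary-accessors
#' @export
setGeneric("classFractions",
           function(object) standardGeneric("classFractions"))

#' @rdname SpectrumSummary-accessors
#' @export
setGeneric("impactCounts", function(object) standardGeneric("impactCounts"))
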
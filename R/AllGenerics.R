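#' @rdname TrioCohort-class
#' @param x a TrioCohort, TransmissionSummary or result object.
#' @export
setGeneric("fatherGeno", function(x) standardGeneric("fatherGeno"))

#' @rdname TrioCohort-class
#' @export
setGeneric("motherGeno", function(x) standardGeneric("motherGeno"))

#' @rdname TrioCohort-class
#' @export
setGeneric("childGeno", function(x) standardGeneric("childGeno"))

#' @rdname TrioCohort-class
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname TrioCohort-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname TrioCohort-class
#' @export
setGeneric("mutantAllele", function(x) standardGeneric("mutantAllele"))

#' @rdname TransmissionSummary-class
#' @param x object.
#' @export
setGeneric("transmissionDiffs", function(x) standardGeneric("transmissionDiffs"))

#' @rdname TransmissionSummary-class
#' @export
setGeneric("hetParents", function(x) standardGeneric("hetParents"))

#' @rdname TransmissionSummary-class
#' @export
setGeneric("hetTotals", function(x) standardGeneric("hetTotals"))

#' @rdname TransmissionSummary-class
#' @export
setGeneric("transmittedCounts", function(x) standardGeneric("transmittedCounts"))

#' @rdname TransmissionSummary-class
#' @export
setGeneric("nontransmittedCounts",
           function(x) standardGeneric("nontransmittedCounts"))

#' @rdname TrioTestResult-class
#' @param x object.
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname TrioTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TrioTestResult-class
#' @export
setGeneric("nPermutations", function(x) standardGeneric("nPermutations"))

#' @rdname TrioLrtResult-class
#' @param x object.
#' @export
setGeneric("piHat", function(x) standardGeneric("piHat"))

#' @rdname RandomEffectsSpec-class
#' @param x object.
#' @export
setGeneric("deltaBounds", function(x) standardGeneric("deltaBounds"))

#' @rdname RandomEffectsSpec-class
#' @export
setGeneric("mafEstimates", function(x) standardGeneric("mafEstimates"))

#' @rdname RejectionExperiment-class
#' @param x object.
#' @export
setGeneric("rejectionRates", function(x) standardGeneric("rejectionRates"))

#' @rdname RejectionExperiment-class
#' @export
setGeneric("mcStandardErrors", function(x) standardGeneric("mcStandardErrors"))
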
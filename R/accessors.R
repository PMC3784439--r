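#' @rdname TrioCohort-class
#' @export
setMethod("fatherGeno", "TrioCohort",
          function(x) SummarizedExperiment::assay(x, "father"))

#' @rdname TrioCohort-class
#' @export
setMethod("motherGeno", "TrioCohort",
          function(x) SummarizedExperiment::assay(x, "mother"))

#' @rdname TrioCohort-class
#' @export
setMethod("childGeno", "TrioCohort",
          function(x) SummarizedExperiment::assay(x, "child"))

#' @rdname TrioCohort-class
#' @export
setMethod("nFamilies", "TrioCohort", function(x) ncol(x))

#' @rdname TrioCohort-class
#' @export
setMethod("nVariants", "TrioCohort", function(x) nrow(x))

#' @rdname TrioCohort-class
#' @export
setMethod("mutantAllele", "TrioCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("mutantAllele" %in% colnames(rd)) rd$mutantAllele else
    rep(NA_character_, nrow(x))
})

setMethod("show", "TrioCohort", function(object) {
  cat(sprintf("TrioCohort: %d variant(s) x %d familie(s)\n",
              nrow(object), ncol(object)))
  callNextMethod()
})

#' @rdname TransmissionSummary-class
#' @export
setMethod("transmissionDiffs", "TransmissionSummary", function(x) x@X)

#' @rdname TransmissionSummary-class
#' @export
setMethod("hetParents", "TransmissionSummary", function(x) x@hetParents)

#' @rdname TransmissionSummary-class
#' @export
setMethod("hetTotals", "TransmissionSummary", function(x) x@H)

#' @rdname TransmissionSummary-class
#' @export
setMethod("transmittedCounts", "TransmissionSummary", function(x) x@b)

#' @rdname TransmissionSummary-class
#' @export
setMethod("nontransmittedCounts", "TransmissionSummary", function(x) x@c)

#' @rdname TransmissionSummary-class
#' @export
setMethod("nFamilies", "TransmissionSummary", function(x) nrow(x@X))

#' @rdname TransmissionSummary-class
#' @export
setMethod("nVariants", "TransmissionSummary", function(x) ncol(x@X))

setMethod("show", "TransmissionSummary", function(object) {
  cat(sprintf("TransmissionSummary: %d familie(s) x %d variant(s)\n",
              nrow(object@X), ncol(object@X)))
  cat("  H:", paste(object@H, collapse = " "), "\n")
  cat("  b:", paste(object@b, collapse = " "), "\n")
  cat("  c:", paste(object@c, collapse = " "), "\n")
})

#' @rdname TrioTestResult-class
#' @export
setMethod("statistic", "TrioTestResult", function(x) x@statistic)

#' @rdname TrioTestResult-class
#' @export
setMethod("pValue", "TrioTestResult", function(x) x@pValue)

#' @rdname TrioTestResult-class
#' @export
setMethod("nPermutations", "TrioTestResult", function(x) x@nPerm)

setMethod("show", "TrioTestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, permutation p = %.4g (%d permutations, seed %d)\n",
              object@method, object@statistic, object@pValue,
              object@nPerm, object@seed))
})

#' @rdname TrioLrtResult-class
#' @export
setMethod("piHat", "TrioLrtResult", function(x) x@piHat)

setMethod("show", "TrioLrtResult", function(object) {
  cat(sprintf(
    "%s: lambda = %.4g, pi-hat = %.4g, permutation p = %.4g (gamma %.3g, %d permutations, seed %d)\n",
    object@method, object@statistic, object@piHat, object@pValue,
    object@gamma, object@nPerm, object@seed))
})

#' @rdname RandomEffectsSpec-class
#' @export
setMethod("deltaBounds", "RandomEffectsSpec", function(x) x@delta)

#' @rdname RandomEffectsSpec-class
#' @export
setMethod("mafEstimates", "RandomEffectsSpec", function(x) x@qHat)

setMethod("show", "RandomEffectsSpec", function(object) {
  cat(sprintf("RandomEffectsSpec: gamma = %.3g, %d variant(s)\n",
              object@gamma, length(object@delta)))
  cat("  delta range:", paste(signif(range(object@delta), 5), collapse = " - "),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: L = %d (%d functional), RR [%.3g, %.3g], MAF [%.4g, %.4g]\n",
    object@L, object@nFunctional, object@rrMin, object@rrMax,
    object@mafLow, object@mafHigh))
  cat(sprintf("  prevalence %.3g, %d trios, form %s, protectiveProb %.2g\n",
              object@prevalence, object@nTrios, object@form,
              object@protectiveProb))
  if (length(object@commonMaf))
    cat("  common variants:", paste(object@commonMaf, collapse = ", "), "\n")
  if (length(object@strat))
    cat(sprintf("  stratified: prop2 %.2g, prevalence2 %.3g, MAF2 [%.4g, %.4g]\n",
                object@strat$prop2, object@strat$prevalence2,
                object@strat$mafLow2, object@strat$mafHigh2))
})

#' @rdname RejectionExperiment-class
#' @export
setMethod("rejectionRates", "RejectionExperiment", function(x) x@rates)

#' @rdname RejectionExperiment-class
#' @export
setMethod("mcStandardErrors", "RejectionExperiment", function(x) x@se)

setMethod("show", "RejectionExperiment", function(object) {
  cat(sprintf(
    "RejectionExperiment: %d replicates x %d permutations, alpha = %.3g, seed %d\n",
    object@nReps, object@nPerm, object@alpha, object@seed))
  df <- data.frame(rate = object@rates, mcSE = object@se)
  print(round(df, 4))
})
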
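#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData rowRanges
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dbinom pbeta pchisq rbinom runif sd
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## TrioCohort
## ---------------------------------------------------------------------------

#' TrioCohort: genotypes of case-parents trios
#'
#' A \linkS4class{SummarizedExperiment} with three assays, \code{father},
#' \code{mother} and \code{child}, each an integer matrix of mutant-allele
#' counts in \{0, 1, 2\} with variants as rows and families as columns.
#' Row metadata may carry variant positions and the label of the allele
#' counted as mutant.  Validity requires every child genotype to be
#' Mendelian-consistent with its parents.
#'
#' @name TrioCohort-class
#' @aliases TrioCohort-class
#' @exportClass TrioCohort
setClass("TrioCohort", contains = "SummarizedExperiment")

.checkGenoMatrix <- function(m, what) {
  if (!is.matrix(m)) return(sprintf("assay '%s' is not a matrix", what))
  if (any(is.na(m))) return(sprintf("assay '%s' contains missing genotypes", what))
  if (!all(m %in% c(0L, 1L, 2L)))
    return(sprintf("assay '%s' has entries outside {0,1,2}", what))
  NULL
}

## Mendelian consistency: the set of child counts reachable from (gf, gm) is
## the integer interval [ (gf==2)+(gm==2), (gf>=1)+(gm>=1) ].
.mendelianViolations <- function(father, mother, child) {
  lo <- (father == 2L) + (mother == 2L)
  hi <- (father >= 1L) + (mother >= 1L)
  which(child < lo | child > hi, arr.ind = TRUE)
}

setValidity("TrioCohort", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("father", "mother", "child")
  if (!all(need %in% an))
    return("assays 'father', 'mother', 'child' are required")
  if (nrow(object) < 1L) return("at least one variant is required")
  if (ncol(object) < 1L) return("at least one family is required")
  fa <- SummarizedExperiment::assay(object, "father")
  mo <- SummarizedExperiment::assay(object, "mother")
  ch <- SummarizedExperiment::assay(object, "child")
  for (w in need) {
    msg <- .checkGenoMatrix(SummarizedExperiment::assay(object, w), w)
    if (!is.null(msg)) return(msg)
  }
  bad <- .mendelianViolations(fa, mo, ch)
  if (nrow(bad) > 0L) {
    i <- bad[1L, ]
    return(sprintf(
      "Mendelian violation at variant '%s', family '%s' (father=%d, mother=%d, child=%d); %d violating cell(s) in total",
      rownames(object)[i[1L]], colnames(object)[i[2L]],
      fa[i[1L], i[2L]], mo[i[1L], i[2L]], ch[i[1L], i[2L]], nrow(bad)))
  }
  TRUE
})

#' Construct a TrioCohort
#'
#' @param father,mother,child integer matrices (variants x families) of
#'   mutant-allele counts in \{0, 1, 2\}.
#' @param variantIds optional character vector of variant identifiers
#'   (defaults to \code{v1..vL}).
#' @param familyIds optional character vector of family identifiers.
#' @param positions optional 1-based variant coordinates.
#' @param mutantAllele optional per-variant label of the allele counted as
#'   mutant.
#' @param population optional per-family subpopulation labels (used by the
#'   stratified simulator).
#' @return A \linkS4class{TrioCohort}.
#' @examples
#' co <- TrioCohort(father = matrix(1L, 1, 2), mother = matrix(0L, 1, 2),
#'                  child = matrix(c(1L, 0L), 1, 2))
#' nFamilies(co)
#' @export
TrioCohort <- function(father, mother, child, variantIds = NULL,
                       familyIds = NULL, positions = NULL,
                       mutantAllele = NULL, population = NULL) {
  father <- as.matrix(father); mother <- as.matrix(mother)
  child <- as.matrix(child)
  storage.mode(father) <- "integer"
  storage.mode(mother) <- "integer"
  storage.mode(child) <- "integer"
  L <- nrow(father); n <- ncol(father)
  if (is.null(variantIds)) variantIds <- paste0("v", seq_len(L))
  if (is.null(familyIds)) familyIds <- paste0("fam", seq_len(n))
  rd <- S4Vectors::DataFrame(row.names = as.character(variantIds))
  if (!is.null(positions)) rd$position <- as.integer(positions)
  if (!is.null(mutantAllele)) rd$mutantAllele <- as.character(mutantAllele)
  cd <- S4Vectors::DataFrame(row.names = as.character(familyIds))
  if (!is.null(population)) cd$population <- population
  dimnames(father) <- dimnames(mother) <- dimnames(child) <-
    list(as.character(variantIds), as.character(familyIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(father = father, mother = mother, child = child),
    rowData = rd, colData = cd)
  new("TrioCohort", se)
}

## ---------------------------------------------------------------------------
## TransmissionSummary
## ---------------------------------------------------------------------------

#' TransmissionSummary: per-family and per-variant transmission counts
#'
#' Reduction of a \linkS4class{TrioCohort} to the quantities all tests are
#' defined on: the per-family difference matrix
#' \eqn{X_{ij} = 2 g_{child} - g_{father} - g_{mother}} (transmitted minus
#' non-transmitted mutant alleles, families x variants), the per-family
#' heterozygous-parent counts, and the per-variant totals \eqn{H_j}
#' (heterozygous parents), \eqn{b_j} (transmitted from heterozygous parents)
#' and \eqn{c_j} (non-transmitted).
#'
#' @name TransmissionSummary-class
#' @aliases TransmissionSummary-class
#' @exportClass TransmissionSummary
setClass("TransmissionSummary",
  representation(X = "matrix", hetParents = "matrix",
                 H = "numeric", b = "numeric", c = "numeric",
                 variantIds = "character"))

setValidity("TransmissionSummary", function(object) {
  X <- object@X; het <- object@hetParents
  if (!all(dim(X) == dim(het))) return("X and hetParents dimensions differ")
  if (any(abs(X) > het)) return("|X_ij| exceeds heterozygous-parent count")
  H <- colSums(het); S <- colSums(X)
  if (!isTRUE(all.equal(H, object@H))) return("H inconsistent with hetParents")
  b <- (H + S) / 2
  if (any(abs(b - round(b)) > 1e-9)) return("b_j is not an integer")
  if (!isTRUE(all.equal(object@b, b))) return("b inconsistent with X and H")
  if (!isTRUE(all.equal(object@b + object@c, H))) return("b + c != H")
  if (any(object@b < 0) || any(object@b > H)) return("b outside [0, H]")
  TRUE
})

## ---------------------------------------------------------------------------
## MultivariableScore
## ---------------------------------------------------------------------------

#' Score vector and null covariance of the multivariable test
#'
#' Holds the length-L score vector \eqn{U} (column sums of X), the null
#' variance-covariance estimate \eqn{V = \sum_i X_i X_i'} and its rank.
#'
#' @name MultivariableScore-class
#' @exportClass MultivariableScore
setClass("MultivariableScore",
  representation(U = "numeric", V = "matrix", rank = "integer"))

## ---------------------------------------------------------------------------
## Test results
## ---------------------------------------------------------------------------

#' Result of a permutation-based trio association test
#'
#' @name TrioTestResult-class
#' @exportClass TrioTestResult
setClass("TrioTestResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", nPerm = "integer", seed = "integer"))

setValidity("TrioTestResult", function(object) {
  if (!is.finite(object@statistic)) return("statistic must be finite")
  if (object@pValue <= 0 || object@pValue > 1) return("p-value outside (0,1]")
  TRUE
})

#' Result of the random-effects likelihood-ratio test
#'
#' Extends \linkS4class{TrioTestResult}; the statistic slot holds the
#' likelihood-ratio statistic \eqn{\Lambda \ge 0} and \code{piHat} the
#' maximum pseudo-likelihood estimate of the functional fraction.
#'
#' @name TrioLrtResult-class
#' @exportClass TrioLrtResult
setClass("TrioLrtResult", contains = "TrioTestResult",
  representation(piHat = "numeric", gamma = "numeric"))

setValidity("TrioLrtResult", function(object) {
  if (object@statistic < 0) return("lambda must be >= 0")
  if (object@piHat < 0 || object@piHat > 1) return("piHat outside [0,1]")
  TRUE
})

## ---------------------------------------------------------------------------
## RandomEffectsSpec
## ---------------------------------------------------------------------------

#' Specification of the random-effects transmission model
#'
#' Carries the relative-risk upper bound \code{gamma}, per-variant MAF
#' estimates from parental alleles, and the per-variant transmission
#' probability bounds \eqn{\delta_j} under the dominant model at
#' \code{gamma}.
#'
#' @name RandomEffectsSpec-class
#' @exportClass RandomEffectsSpec
setClass("RandomEffectsSpec",
  representation(gamma = "numeric", qHat = "numeric", delta = "numeric",
                 pi = "numeric"))

setValidity("RandomEffectsSpec", function(object) {
  if (object@gamma <= 1) return("gamma must exceed 1")
  if (length(object@qHat) != length(object@delta))
    return("qHat and delta lengths differ")
  if (any(object@delta <= 0.5) || any(object@delta >= 1))
    return("delta bounds must lie in (0.5, 1)")
  TRUE
})

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' Simulation design for case-parents cohorts
#'
#' All knobs of the evaluation design: region size \code{L}, number of
#' functional variants, relative-risk and MAF ranges for rare variants,
#' optional common variants with their own roles and RR range, disease
#' prevalence, target number of ascertained trios, probability that a
#' functional variant is protective, per-variant penetrance form and an
#' optional two-subpopulation stratification setting.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(L = "integer", nFunctional = "integer",
                 rrMin = "numeric", rrMax = "numeric",
                 mafLow = "numeric", mafHigh = "numeric",
                 commonMaf = "numeric", commonFunctional = "logical",
                 commonRrMin = "numeric", commonRrMax = "numeric",
                 prevalence = "numeric", nTrios = "integer",
                 protectiveProb = "numeric", form = "character",
                 strat = "list"))

setValidity("SimulationConfig", function(object) {
  if (object@L < 1L) return("L must be >= 1")
  if (object@nFunctional > object@L) return("nFunctional exceeds L")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    return("prevalence outside (0,1)")
  if (object@rrMin > object@rrMax) return("rrMin exceeds rrMax")
  if (object@mafLow >= object@mafHigh) return("mafLow must be < mafHigh")
  if (length(object@commonMaf) != length(object@commonFunctional))
    return("commonMaf and commonFunctional lengths differ")
  nCommonFun <- sum(object@commonFunctional)
  if (nCommonFun > object@nFunctional)
    return("more common functional variants than functional variants")
  if (length(object@commonMaf) - nCommonFun > object@L - object@nFunctional)
    return("more common nonfunctional variants than nonfunctional variants")
  if (!object@form %in% c("dominant", "multiplicative", "recessive"))
    return("unknown penetrance form")
  if (object@protectiveProb < 0 || object@protectiveProb > 1)
    return("protectiveProb outside [0,1]")
  if (length(object@strat) > 0L) {
    need <- c("prop2", "prevalence2", "mafLow2", "mafHigh2")
    if (!all(need %in% names(object@strat)))
      return(sprintf("strat must contain %s", paste(need, collapse = ", ")))
  }
  TRUE
})

#' Realized regional disease model
#'
#' Per-variant MAFs and relative risks (1 for nonfunctional variants) plus
#' the baseline penetrance calibrated so the population prevalence matches
#' the configured value.
#'
#' @name RegionModel-class
#' @exportClass RegionModel
setClass("RegionModel",
  representation(mafs = "numeric", rr = "numeric", f0 = "numeric",
                 form = "character", functional = "logical"))

setValidity("RegionModel", function(object) {
  if (length(object@mafs) != length(object@rr)) return("mafs/rr length mismatch")
  if (any(object@mafs <= 0 | object@mafs >= 1)) return("MAFs outside (0,1)")
  if (any(object@rr <= 0)) return("relative risks must be positive")
  TRUE
})

## ---------------------------------------------------------------------------
## RejectionExperiment
## ---------------------------------------------------------------------------

#' Monte-Carlo rejection-rate experiment result
#'
#' Per-test rejection rates at a nominal level together with their
#' Monte-Carlo standard errors \eqn{\sqrt{r(1-r)/n_{reps}}}, the replication
#' settings and the master seed.
#'
#' @name RejectionExperiment-class
#' @exportClass RejectionExperiment
setClass("RejectionExperiment",
  representation(rates = "numeric", se = "numeric", nReps = "integer",
                 nPerm = "integer", alpha = "numeric", seed = "integer",
                 config = "SimulationConfig"))

setValidity("RejectionExperiment", function(object) {
  if (any(object@rates < 0 | object@rates > 1))
    return("rejection rates outside [0,1]")
  ok <- sqrt(object@rates * (1 - object@rates) / object@nReps)
  if (!isTRUE(all.equal(ok, object@se, check.attributes = FALSE)))
    return("standard errors inconsistent with rates and nReps")
  TRUE
})
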
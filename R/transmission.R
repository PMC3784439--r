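#' Reduce a trio cohort to transmission counts
#'
#' Computes, for every family i and variant j, the difference between
#' transmitted and non-transmitted mutant alleles
#' \eqn{X_{ij} = 2 g_{c,ij} - g_{f,ij} - g_{m,ij}} and the number of
#' heterozygous parents, then the per-variant totals \eqn{H_j},
#' \eqn{b_j = (H_j + \sum_i X_{ij}) / 2} (mutant alleles transmitted from
#' heterozygous parents) and \eqn{c_j = H_j - b_j}.  Homozygous parents are
#' uninformative: they contribute 0 to both \eqn{X} and \eqn{H}.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @return A \linkS4class{TransmissionSummary}.
#' @examples
#' co <- TrioCohort(father = matrix(1L, 1, 1), mother = matrix(0L, 1, 1),
#'                  child = matrix(1L, 1, 1))
#' transmittedCounts(summarizeTransmission(co))  # b = 1
#' @export
summarizeTransmission <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  fa <- fatherGeno(cohort); mo <- motherGeno(cohort); ch <- childGeno(cohort)
  ## orient families x variants
  X <- t(2L * ch - fa - mo)
  het <- t((fa == 1L) + (mo == 1L))
  storage.mode(X) <- "double"
  storage.mode(het) <- "double"
  H <- colSums(het)
  S <- colSums(X)
  new("TransmissionSummary", X = X, hetParents = het,
      H = H, b = (H + S) / 2, c = (H - S) / 2,
      variantIds = rownames(cohort))
}

#' Swap transmitted and non-transmitted genotype vectors within families
#'
#' Applies the within-family permutation move: for family i with
#' \code{flips[i] == -1} the child's transmitted genotype vector is
#' exchanged with its complement \eqn{g_f + g_m - g_c}, which multiplies row
#' i of the difference matrix X by -1.  Heterozygous-parent counts (and
#' hence every \eqn{H_j}) are unchanged; \eqn{b_j} and \eqn{c_j} are
#' recomputed from the identities \eqn{b_j + c_j = H_j},
#' \eqn{b_j - c_j = \sum_i X_{ij}}.
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @param flips numeric vector of +1/-1, one per family.
#' @return A \linkS4class{TransmissionSummary} with flipped rows.
#' @export
complementSwap <- function(summary, flips) {
  stopifnot(is(summary, "TransmissionSummary"))
  if (length(flips) != nrow(summary@X))
    stop("flips length must equal the number of families")
  if (!all(flips %in% c(-1, 1)))
    stop("flips must be +1 or -1")
  X <- summary@X * flips   # column-major recycling applies flips row-wise
  H <- summary@H
  S <- colSums(X)
  new("TransmissionSummary", X = X, hetParents = summary@hetParents,
      H = H, b = (H + S) / 2, c = (H - S) / 2,
      variantIds = summary@variantIds)
}
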
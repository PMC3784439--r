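#' Single-variant TDT statistic
#'
#' The classical transmission disequilibrium statistic
#' \eqn{(b - c)^2 / (b + c)} comparing mutant alleles transmitted (b) and
#' not transmitted (c) from heterozygous parents.  Returns 0 when
#' \eqn{b + c = 0} (uninformative variant).
#'
#' @param b,c non-negative transmission counts (vectorized).
#' @return Numeric statistic(s).
#' @examples
#' tdtStatistic(10, 5)   # 25/15
#' @export
tdtStatistic <- function(b, c) {
  if (any(b < 0) || any(c < 0)) stop("transmission counts must be non-negative")
  n <- b + c
  ifelse(n == 0, 0, (b - c)^2 / ifelse(n == 0, 1, n))
}

#' Largest single-variant TDT over a region
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @return \eqn{\max_j (b_j - c_j)^2 / (b_j + c_j)}.
#' @export
maxTdt <- function(summary) {
  stopifnot(is(summary, "TransmissionSummary"))
  max(tdtStatistic(summary@b, summary@c))
}

#' Combined TDT over a region
#'
#' Pools transmitted and non-transmitted mutant alleles across all variants:
#' with \eqn{B = \sum_j b_j} and \eqn{C = \sum_j c_j} the statistic is
#' \eqn{(B - C)^2 / (B + C)} (0 when \eqn{B + C = 0}).
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @return Numeric statistic.
#' @export
combinedTdt <- function(summary) {
  stopifnot(is(summary, "TransmissionSummary"))
  tdtStatistic(sum(summary@b), sum(summary@c))
}

#' Multivariable score and null covariance
#'
#' The length-L score vector \eqn{U_j = \sum_i X_{ij}} and the null
#' variance-covariance estimate \eqn{V = \sum_i X_i X_i'} over families
#' (uncentered; the scores have zero mean under the null).
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @return A \linkS4class{MultivariableScore}.
#' @export
multivariableScore <- function(summary) {
  stopifnot(is(summary, "TransmissionSummary"))
  X <- summary@X
  V <- crossprod(X)
  new("MultivariableScore", U = colSums(X), V = V, rank = .matrixRank(V))
}

#' Multivariable quadratic-form statistic
#'
#' \eqn{U' V^- U} with \eqn{V^-} the Moore-Penrose generalized inverse
#' (singular values below \code{max(dim) * eps * sigma_max} treated as
#' zero).  Invariant to variant reordering; 0 when X is all zeros.
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @return Numeric statistic.
#' @export
multivariableStatistic <- function(summary) {
  sc <- multivariableScore(summary)
  drop(crossprod(sc@U, .pinv(sc@V) %*% sc@U))
}

#' Asymptotic chi-square p-value for the multivariable statistic
#'
#' Diagnostic only: the asymptotic reference distribution is chi-square with
#' degrees of freedom equal to the rank of V, and is known to be
#' conservative for sparse rare-variant data; the permutation p-value is the
#' recommended inference.
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @return Upper-tail chi-square p-value.
#' @export
multivariableAsymptoticP <- function(summary) {
  sc <- multivariableScore(summary)
  stat <- drop(crossprod(sc@U, .pinv(sc@V) %*% sc@U))
  if (sc@rank == 0L) return(1)
  stats::pchisq(stat, df = sc@rank, lower.tail = FALSE)
}

#' Within-family permutation p-value for an arbitrary statistic
#'
#' Draws \code{nPerm} independent flip vectors (each family +1/-1 with
#' probability 1/2), recomputes the statistic on the complement-swapped
#' summary, and returns the add-one estimator
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}, which
#' is a valid p-value and never exactly 0.  Deterministic given the seed.
#'
#' @param statFn function mapping a \linkS4class{TransmissionSummary} to a
#'   numeric statistic.
#' @param summary a \linkS4class{TransmissionSummary}.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param method label stored in the result.
#' @return A \linkS4class{TrioTestResult}.
#' @export
permutationPvalue <- function(statFn, summary, nPerm = 10000L, seed = 1L,
                              method = "custom") {
  stopifnot(is(summary, "TransmissionSummary"), nPerm >= 1L)
  obs <- statFn(summary)
  n <- nrow(summary@X)
  set.seed(seed)
  flips <- .flipMatrix(n, nPerm)
  exceed <- 0L
  for (k in seq_len(nPerm)) {
    if (statFn(complementSwap(summary, flips[, k])) >= obs)
      exceed <- exceed + 1L
  }
  new("TrioTestResult", method = method, statistic = obs,
      pValue = (1 + exceed) / (1 + nPerm), nPerm = as.integer(nPerm),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Shared-flip fast paths.  All four tests are functions of the per-variant
## flip-weighted column sums S = t(F) %*% X, since V = sum_i X_i X_i' and
## every H_j are flip-invariant.  One stream of flip vectors is reused across
## the tests of a run; each marginal p-value remains exact.
## ---------------------------------------------------------------------------

## S: (nPerm+1) x L matrix of column sums, observed first; H: length L.
.statTs <- function(S, H) {
  pos <- H > 0
  if (!any(pos)) return(numeric(nrow(S)))
  M <- S[, pos, drop = FALSE]^2 / rep(H[pos], each = nrow(S))
  do.call(pmax, c(as.data.frame(M), list(0)))
}

.statCtdt <- function(S, H) {
  tot <- sum(H)
  if (tot == 0) return(numeric(nrow(S)))
  rowSums(S)^2 / tot
}

.statTmult <- function(S, Vinv) {
  rowSums((S %*% Vinv) * S)
}

#' Run the trio association tests with a shared permutation stream
#'
#' Computes any subset of the four region-level tests -- largest
#' single-variant TDT (\code{ts}), multivariable score test (\code{tmult}),
#' combined TDT (\code{ctdt}) and the random-effects likelihood-ratio test
#' (\code{lrt}) -- with permutation p-values from one shared stream of
#' within-family flips.  All four statistics depend on the data only through
#' flip-weighted transmission sums, so sharing the stream is statistically
#' valid and saves most of the permutation cost.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param methods character subset of \code{c("ts","tmult","ctdt","lrt")} or
#'   \code{"all"}.
#' @param gamma relative-risk upper bound for the LRT (default 5).
#' @param nPerm number of permutations.
#' @param seed integer RNG seed.
#' @return Named list of \linkS4class{TrioTestResult} /
#'   \linkS4class{TrioLrtResult} objects.
#' @export
trioTest <- function(cohort, methods = "all", gamma = 5, nPerm = 10000L,
                     seed = 1L) {
  all_m <- c("ts", "tmult", "ctdt", "lrt")
  if (identical(methods, "all")) methods <- all_m
  if (!all(methods %in% all_m))
    stop("unknown method(s): ", paste(setdiff(methods, all_m), collapse = ", "))
  summary <- summarizeTransmission(cohort)
  X <- summary@X
  H <- summary@H
  n <- nrow(X)
  set.seed(seed)
  flips <- .flipMatrix(n, nPerm)
  S <- rbind(colSums(X), crossprod(flips, X))
  out <- list()
  addResult <- function(name, statVec) {
    p <- (1 + sum(statVec[-1L] >= statVec[1L])) / (1 + nPerm)
    out[[name]] <<- new("TrioTestResult", method = name,
                        statistic = statVec[1L], pValue = p,
                        nPerm = as.integer(nPerm), seed = as.integer(seed))
  }
  if ("ts" %in% methods) addResult("ts", .statTs(S, H))
  if ("tmult" %in% methods) {
    Vinv <- .pinv(crossprod(X))
    addResult("tmult", .statTmult(S, Vinv))
  }
  if ("ctdt" %in% methods) addResult("ctdt", .statCtdt(S, H))
  if ("lrt" %in% methods) {
    spec <- randomEffectsSpec(cohort, gamma = gamma)
    Tmat <- round((S + rep(H, each = nrow(S))) / 2)
    fit <- .lambdaEngine(Tmat, H, spec@delta)
    lam <- fit$lambda
    p <- (1 + sum(lam[-1L] >= lam[1L])) / (1 + nPerm)
    out[["lrt"]] <- new("TrioLrtResult", method = "lrt",
                        statistic = lam[1L], pValue = p,
                        nPerm = as.integer(nPerm), seed = as.integer(seed),
                        piHat = fit$piHat[1L], gamma = gamma)
  }
  out[methods]
}
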
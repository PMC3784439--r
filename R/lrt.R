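#' Transmission probability of a mutant allele to an affected child
#'
#' Exact probability, under HWE and random mating, that a heterozygous
#' parent transmits the mutant allele given that the offspring is affected.
#' Computed by enumeration: conditioning on the focal parent being
#' heterozygous, iterate over the other parent's HWE genotype and its
#' transmitted allele, accumulate the penetrance-weighted probability of the
#' child's genotype for a transmitting and a non-transmitting focal parent,
#' and take the ratio.  The baseline penetrance cancels, so only the
#' genotype relative risk enters.  Equals 1/2 whenever \code{rr = 1}.
#'
#' @param q minor allele frequency in (0, 1) (vectorized).
#' @param rr genotype relative risk (> 0).
#' @param form penetrance form: one or two mutant alleles confer the same
#'   relative risk (\code{dominant}), risk compounds per allele
#'   (\code{multiplicative}), or only homozygotes are at risk
#'   (\code{recessive}).
#' @return Transmission probability in (0, 1).
#' @examples
#' transmissionProbability(0.2, 1, "dominant")       # 0.5 under the null
#' transmissionProbability(1e-6, 5, "dominant")      # -> 5/6 as q -> 0
#' @export
transmissionProbability <- function(q, rr,
                                    form = c("dominant", "multiplicative",
                                             "recessive")) {
  form <- match.arg(form)
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly inside (0, 1)")
  if (any(rr <= 0)) stop("rr must be positive")
  ## g is a scalar genotype code; rr may be a vector (rr^0 keeps shape)
  rfun <- switch(form,
    dominant       = function(g) if (g >= 1) rr else rr^0,
    multiplicative = function(g) rr^g,
    recessive      = function(g) if (g == 2) rr else rr^0)
  ## other parent: HWE genotype probabilities and transmitted allele
  pg <- list(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)
  ptrans <- list(`0` = c(`0` = 1, `1` = 0),
                 `1` = c(`0` = 0.5, `1` = 0.5),
                 `2` = c(`0` = 0, `1` = 1))
  b1 <- 0; b2 <- 0   # focal parent transmits mutant / normal allele
  for (go in c("0", "1", "2")) {
    for (bo in c("0", "1")) {
      w <- pg[[go]] * ptrans[[go]][[bo]]
      b1 <- b1 + 0.5 * w * rfun(1L + as.integer(bo))
      b2 <- b2 + 0.5 * w * rfun(0L + as.integer(bo))
    }
  }
  b1 / (b1 + b2)
}

#' Estimate per-variant minor allele frequencies from parental genotypes
#'
#' \eqn{\hat q_j = \sum_i (g_{f,ij} + g_{m,ij}) / (4 n)}, the allele
#' frequency among the 4n parental chromosomes, clamped to
#' \eqn{[1/(4n+2), 1 - 1/(4n+2)]} so that the transmission-probability bound
#' stays defined for variants monomorphic in the parents.  Parental counts
#' are untouched by the within-family permutation, so the estimates are
#' identical across permutation replicates.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @return Numeric vector of per-variant MAF estimates.
#' @export
estimateMaf <- function(cohort) {
  stopifnot(is(cohort, "TrioCohort"))
  n <- nFamilies(cohort)
  q <- rowSums(fatherGeno(cohort) + motherGeno(cohort)) / (4 * n)
  eps <- 1 / (4 * n + 2)
  pmin(pmax(q, eps), 1 - eps)
}

#' Upper bound on the transmission probability at a relative-risk ceiling
#'
#' \eqn{\delta_j = p(\hat q_j, \gamma)} under the dominant model: the
#' largest transmission probability consistent with relative risks at most
#' \code{gamma}.  Decreasing in \eqn{\hat q}, so rarer variants are allowed
#' larger random effects.
#'
#' @param qHat per-variant MAF estimate(s) in (0, 1).
#' @param gamma relative-risk upper bound (> 1).
#' @return Numeric vector of bounds in (0.5, 1).
#' @export
deltaBound <- function(qHat, gamma) {
  if (any(gamma <= 1)) stop("gamma must exceed 1")
  transmissionProbability(qHat, gamma, "dominant")
}

#' Build the random-effects model specification for a cohort
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param gamma relative-risk upper bound (default 5).
#' @return A \linkS4class{RandomEffectsSpec} with per-variant MAF estimates
#'   and transmission-probability bounds.
#' @export
randomEffectsSpec <- function(cohort, gamma = 5) {
  qHat <- estimateMaf(cohort)
  new("RandomEffectsSpec", gamma = gamma, qHat = qHat,
      delta = deltaBound(qHat, gamma), pi = NA_real_)
}

#' Log marginal probability of the transmitted count under the mixture model
#'
#' With probability \eqn{1 - \pi} the variant is nonfunctional and
#' \eqn{T \sim Binomial(H, 1/2)}; with probability \eqn{\pi} its
#' transmission probability is Uniform(1/2, \eqn{\delta}), giving the
#' marginal \eqn{C(H,t) B(t+1, H-t+1) [F_\delta - F_{1/2}] / (\delta - 1/2)}
#' where \eqn{F_x} is the Beta(t+1, H-t+1) cdf and \eqn{B} the beta
#' function.  Computed fully in log space (using
#' \eqn{C(H,t) B(t+1,H-t+1) = 1/(H+1)} and tail-selected log cdf
#' differences), stable for H up to at least 1e4.
#'
#' @param t transmitted-count (0..H), vectorized.
#' @param H heterozygous-parent total.
#' @param delta upper bound in (0.5, 1).
#' @param pi mixture weight in [0, 1].
#' @return Log probability mass.
#' @examples
#' mixtureLogPmf(1, 1, 0.8, 1)    # log(0.65): mean of Uniform(0.5, 0.8)
#' @export
mixtureLogPmf <- function(t, H, delta, pi) {
  if (any(delta <= 0.5) || any(delta >= 1))
    stop("delta must lie in (0.5, 1)")
  if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0, 1]")
  if (any(t < 0) || any(t > H)) stop("t must lie in 0..H")
  la <- stats::dbinom(t, H, 0.5, log = TRUE)
  lg <- .logUniformComponent(t, H, delta)
  ## log(0) = -Inf makes the boundary weights pi = 0 and pi = 1 exact
  .logAddExp(log1p(-pi) + la, log(pi) + lg)
}

## log of the functional-component mass:
## (F_delta - F_half) / ((H+1) (delta - 1/2)) for Beta(t+1, H-t+1).
## The cdf difference is taken on whichever tail keeps both terms small.
.logUniformComponent <- function(t, H, delta) {
  s1 <- t + 1
  s2 <- H - t + 1
  upper <- t > H / 2
  lo1 <- stats::pbeta(delta, s1, s2, log.p = TRUE)
  lo0 <- stats::pbeta(0.5, s1, s2, log.p = TRUE)
  up1 <- stats::pbeta(delta, s1, s2, lower.tail = FALSE, log.p = TRUE)
  up0 <- stats::pbeta(0.5, s1, s2, lower.tail = FALSE, log.p = TRUE)
  ldiff <- ifelse(upper, .logSubExp(lo1, lo0), .logSubExp(up0, up1))
  ldiff - log(H + 1) - log(delta - 0.5)
}

#' Pseudo-log-likelihood of the functional fraction
#'
#' Sum over variants of the mixture log pmf of the observed transmitted
#' counts; the product of per-variant marginals is treated as a likelihood
#' even though transmitted counts across variants may be dependent (validity
#' of the test is restored by the permutation null).  Variants with
#' \eqn{H_j = 0} contribute 0.
#'
#' @param pi mixture weight in [0, 1].
#' @param summary a \linkS4class{TransmissionSummary}.
#' @param spec a \linkS4class{RandomEffectsSpec} aligned with the summary's
#'   variants.
#' @return Log pseudo-likelihood.
#' @export
pseudoLogLik <- function(pi, summary, spec) {
  stopifnot(is(summary, "TransmissionSummary"), is(spec, "RandomEffectsSpec"))
  if (length(spec@delta) != length(summary@H))
    stop("spec is not aligned with the summary's variants")
  keep <- summary@H > 0
  if (!any(keep)) return(0)
  sum(mixtureLogPmf(summary@b[keep], summary@H[keep], spec@delta[keep], pi))
}

## ---------------------------------------------------------------------------
## Vectorized likelihood engine.
##
## Tmat: (nRows x L) transmitted counts (rows are the observed data set and
## permutation replicates); H, delta: length L.  The pseudo-log-likelihood is
## concave in pi (each term is the log of a function linear in pi), so a
## coarse grid (step `gridStep`) followed by golden-section refinement inside
## the winning cell converges; boundary maxima at pi in {0, 1} are admissible.
## Everything is evaluated against precomputed per-cell component masses so a
## likelihood pass costs one elementwise sweep of the matrix.
## ---------------------------------------------------------------------------
.lambdaEngine <- function(Tmat, H, delta, gridStep = 0.01, tol = 1e-6) {
  nr <- nrow(Tmat)
  keep <- H > 0
  if (!any(keep)) {
    return(list(lambda = numeric(nr), piHat = numeric(nr),
                ll = numeric(nr), ll0 = numeric(nr)))
  }
  Tm <- Tmat[, keep, drop = FALSE]
  Hm <- rep(H[keep], each = nr)
  dm <- rep(delta[keep], each = nr)
  la <- stats::dbinom(Tm, Hm, 0.5, log = TRUE)
  lg <- .logUniformComponent(Tm, Hm, dm)
  dim(la) <- dim(Tm); dim(lg) <- dim(Tm)
  base <- pmax(la, lg)
  ea <- exp(la - base)          # one of ea, eg is exactly 1 per cell
  eg <- exp(lg - base)
  D <- eg - ea
  C <- rowSums(base)
  llAt <- function(p) C + rowSums(log(ea + p * D))  # p scalar or length nr
  ll0 <- rowSums(la)
  grid <- seq(0, 1, by = gridStep)
  best <- ll0                   # grid point pi = 0
  bestPi <- numeric(nr)
  for (p in grid[-1L]) {
    v <- llAt(p)
    imp <- v > best
    best[imp] <- v[imp]
    bestPi[imp] <- p
  }
  ## golden-section refinement in [bestPi - step, bestPi + step]
  gr <- (sqrt(5) - 1) / 2
  a <- pmax(0, bestPi - gridStep)
  b <- pmin(1, bestPi + gridStep)
  while (max(b - a) > tol) {
    x1 <- b - gr * (b - a)
    x2 <- a + gr * (b - a)
    f1 <- llAt(x1)
    f2 <- llAt(x2)
    lower <- f1 < f2
    a <- ifelse(lower, x1, a)
    b <- ifelse(lower, b, x2)
  }
  piRef <- (a + b) / 2
  llRef <- llAt(piRef)
  useRef <- llRef > best
  piHat <- ifelse(useRef, piRef, bestPi)
  ll <- pmax(llRef, best)
  list(lambda = pmax(0, 2 * (ll - ll0)), piHat = piHat, ll = ll, ll0 = ll0)
}

#' Maximum pseudo-likelihood estimate of the functional fraction
#'
#' Maximizes the pseudo-log-likelihood over \eqn{\pi \in [0, 1]} by a coarse
#' grid (step 0.01) followed by golden-section refinement to tolerance 1e-6;
#' boundary values are admissible.  The profile is concave in \eqn{\pi}.
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @param spec a \linkS4class{RandomEffectsSpec}.
#' @return The estimate \eqn{\hat\pi}.
#' @export
fitPi <- function(summary, spec) {
  stopifnot(is(summary, "TransmissionSummary"), is(spec, "RandomEffectsSpec"))
  if (all(summary@H == 0))
    stop("all variants are uninformative (no heterozygous parents)")
  fit <- .lambdaEngine(matrix(summary@b, nrow = 1L), summary@H, spec@delta)
  fit$piHat[1L]
}

#' Likelihood-ratio statistic for the functional fraction
#'
#' \eqn{\Lambda = 2 \log L(\hat\pi) - 2 \log L(0) \ge 0}.
#'
#' @param summary a \linkS4class{TransmissionSummary}.
#' @param spec a \linkS4class{RandomEffectsSpec}.
#' @return Named list with \code{lambda} and \code{piHat}.
#' @export
lrtStatistic <- function(summary, spec) {
  stopifnot(is(summary, "TransmissionSummary"), is(spec, "RandomEffectsSpec"))
  fit <- .lambdaEngine(matrix(summary@b, nrow = 1L), summary@H, spec@delta)
  list(lambda = fit$lambda[1L], piHat = fit$piHat[1L])
}

#' Random-effects likelihood-ratio test with permutation p-value
#'
#' Estimates per-variant MAFs and transmission-probability bounds from the
#' parental genotypes once (they are invariant under the within-family
#' permutation, which changes children only), computes the observed
#' \eqn{\Lambda}, and obtains the p-value by recomputing \eqn{\Lambda} on
#' complement-swapped transmission summaries with the same bounds.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param gamma relative-risk upper bound (> 1; default 5).
#' @param nPerm number of permutations.
#' @param seed integer RNG seed.
#' @return A \linkS4class{TrioLrtResult}.
#' @export
lrtTest <- function(cohort, gamma = 5, nPerm = 10000L, seed = 1L) {
  if (gamma <= 1) stop("gamma must exceed 1")
  trioTest(cohort, methods = "lrt", gamma = gamma, nPerm = nPerm,
           seed = seed)[["lrt"]]
}
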
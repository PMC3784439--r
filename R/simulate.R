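#' Build a simulation design
#'
#' @param L total number of variants in the region.
#' @param nFunctional number of functional (risk-related) variants; the
#'   region is laid out functional-first.
#' @param rrMin,rrMax relative-risk range for rare functional variants.
#' @param mafLow,mafHigh rare-variant MAF range (defaults 0.001 and 0.01).
#' @param commonMaf optional fixed MAFs of common variants.
#' @param commonFunctional logical vector marking which common variants are
#'   functional.
#' @param commonRrMin,commonRrMax relative-risk range for common functional
#'   variants.
#' @param prevalence population disease probability (default 0.01).
#' @param nTrios target number of ascertained case-parents trios.
#' @param protectiveProb probability that a functional variant is protective
#'   (its RR is replaced by its inverse).
#' @param form per-variant penetrance form (default \code{dominant}); the
#'   joint model across variants is multiplicative.
#' @param strat optional two-subpopulation setting: a list with
#'   \code{prop2} (proportion of the second population),
#'   \code{prevalence2}, and \code{mafLow2}/\code{mafHigh2} (the second
#'   population's MAF range).
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(L = 5, nFunctional = 0, nTrios = 500)
#' @export
simulationConfig <- function(L, nFunctional = 0L, rrMin = 1, rrMax = 1,
                             mafLow = 0.001, mafHigh = 0.01,
                             commonMaf = numeric(0),
                             commonFunctional = logical(0),
                             commonRrMin = 1, commonRrMax = 1,
                             prevalence = 0.01, nTrios = 500L,
                             protectiveProb = 0, form = "dominant",
                             strat = list()) {
  new("SimulationConfig", L = as.integer(L),
      nFunctional = as.integer(nFunctional),
      rrMin = rrMin, rrMax = rrMax, mafLow = mafLow, mafHigh = mafHigh,
      commonMaf = as.numeric(commonMaf),
      commonFunctional = as.logical(commonFunctional),
      commonRrMin = commonRrMin, commonRrMax = commonRrMax,
      prevalence = prevalence, nTrios = as.integer(nTrios),
      protectiveProb = protectiveProb, form = form, strat = strat)
}

#' Assign relative risks to functional variants by allele frequency
#'
#' Linear interpolation between the RR range endpoints: the functional
#' variant with the smallest MAF receives \code{rrMax}, the one with the
#' largest receives \code{rrMin}, i.e.
#' \eqn{r_j = r_{max} - (r_{max} - r_{min}) (q_j - q_{min}) /
#' (q_{max} - q_{min})} with \eqn{q_{min}}/\eqn{q_{max}} the extreme
#' functional MAFs.  With a single functional variant (or all MAFs equal)
#' the midpoint \eqn{(r_{min} + r_{max})/2} is used.  Each functional
#' variant is then independently replaced by its protective inverse
#' \eqn{1/r_j} with probability \code{protectiveProb}.  Nonfunctional
#' variants keep RR 1.
#'
#' @param mafs per-variant minor allele frequencies.
#' @param functionalIdx indices of the functional variants.
#' @param rrMin,rrMax relative-risk range (\code{rrMin <= rrMax}).
#' @param protectiveProb probability of flipping a functional variant to
#'   protective.
#' @return Relative-risk vector of length \code{length(mafs)}.
#' @export
assignRelativeRisks <- function(mafs, functionalIdx, rrMin, rrMax,
                                protectiveProb = 0) {
  if (rrMin > rrMax) stop("rrMin must not exceed rrMax")
  rr <- rep(1, length(mafs))
  if (length(functionalIdx) == 0L) return(rr)
  q <- mafs[functionalIdx]
  qmin <- min(q); qmax <- max(q)
  if (length(q) == 1L || qmax == qmin) {
    r <- rep((rrMin + rrMax) / 2, length(q))
  } else {
    r <- rrMax - (rrMax - rrMin) * (q - qmin) / (qmax - qmin)
  }
  if (protectiveProb > 0) {
    flip <- stats::runif(length(r)) < protectiveProb
    r[flip] <- 1 / r[flip]
  }
  rr[functionalIdx] <- r
  rr
}

## Expected per-variant penetrance multiplier E[r^{code(g)}] under HWE.
.carrierExpectation <- function(q, rr, form) {
  switch(form,
    dominant       = 1 + (rr - 1) * (1 - (1 - q)^2),
    multiplicative = (1 - q + q * rr)^2,
    recessive      = 1 + (rr - 1) * q^2)
}

## Largest attainable per-variant multiplier (over genotypes with positive
## probability).
.maxRiskFactor <- function(rr, form) {
  switch(form,
    dominant       = pmax(rr, 1),
    multiplicative = pmax(rr^2, 1),
    recessive      = pmax(rr, 1))
}

## Upper bound on the probability mass of genotypes whose multiplicative
## penetrance would exceed 1.  Any violating genotype must carry risk alleles
## at >= k variants, where k is the smallest number of largest per-variant
## factors whose product with f0 exceeds 1; the carrier-count tail is
## Poisson-binomial, computed by DP.
.capViolationMass <- function(mafs, rr, form, f0) {
  fac <- .maxRiskFactor(rr, form)
  risky <- fac > 1
  if (f0 * prod(fac[risky]) <= 1) return(0)
  ord <- order(fac[risky], decreasing = TRUE)
  k <- min(which(f0 * cumprod(fac[risky][ord]) > 1))
  pcar <- switch(form,
    recessive = mafs[risky]^2,
    1 - (1 - mafs[risky])^2)
  dp <- c(1, numeric(length(pcar)))
  for (p in pcar)
    dp <- c(0, dp[-length(dp)]) * p + dp * (1 - p)
  sum(dp[(k + 1):length(dp)])
}

#' Calibrate the baseline penetrance to a target prevalence
#'
#' Under independent variant genotypes and a multiplicative joint model the
#' population prevalence is \eqn{f_0 \prod_j E[r_j^{code}]}, so
#' \eqn{f_0 = prevalence / \prod_j E[r_j^{code}]} makes it exact.  With
#' several deleterious variants in a region the multiplicative penetrance
#' can formally exceed 1 for children carrying mutants at most functional
#' sites simultaneously; such genotypes are vanishingly improbable for rare
#' variants (the samplers cap risk at 1) and calibration errors only when
#' their total probability mass exceeds \code{tol}.
#'
#' @param region a \linkS4class{RegionModel} (its \code{f0} slot is
#'   ignored).
#' @param prevalence target population disease probability.
#' @param tol largest tolerated probability mass of penetrance-capped
#'   genotypes.
#' @return The baseline penetrance \eqn{f_0}.
#' @export
calibrateBaselinePenetrance <- function(region, prevalence, tol = 1e-6) {
  stopifnot(is(region, "RegionModel"))
  denom <- prod(.carrierExpectation(region@mafs, region@rr, region@form))
  f0 <- prevalence / denom
  mass <- .capViolationMass(region@mafs, region@rr, region@form, f0)
  if (mass > tol)
    stop(sprintf(
      "genotypes with penetrance above 1 carry probability mass %.3g (> %g); reduce prevalence or relative risks",
      mass, tol))
  f0
}

## Truncated neutral site-frequency spectrum: density proportional to 1/q on
## [lo, hi], i.e. log-uniform.  This is what a coalescent haplotype pool
## restricted to a MAF window delivers, and it is what the parametric
## generator emulates.
.drawRareMafs <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Draw a realized regional disease model from a design
#'
#' Rare-variant MAFs are drawn from a truncated neutral site-frequency
#' spectrum (density proportional to \eqn{1/q}, i.e. log-uniform) on the
#' configured range, emulating a coalescent haplotype pool restricted to a
#' MAF window; common variants sit at their fixed MAFs.  Relative risks are assigned by
#' MAF-interpolation separately within the rare and common functional
#' groups (their RR ranges differ), nonfunctional variants get RR 1, and
#' the baseline penetrance is calibrated to the configured prevalence.
#' Region layout is functional-first: common functional, rare functional,
#' common nonfunctional, rare nonfunctional.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{RegionModel}.
#' @export
drawRegion <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  nCF <- sum(config@commonFunctional)
  nCN <- length(config@commonMaf) - nCF
  nRF <- config@nFunctional - nCF
  nRN <- config@L - config@nFunctional - nCN
  mafs <- c(config@commonMaf[config@commonFunctional],
            .drawRareMafs(nRF, config@mafLow, config@mafHigh),
            config@commonMaf[!config@commonFunctional],
            .drawRareMafs(nRN, config@mafLow, config@mafHigh))
  functional <- c(rep(TRUE, nCF + nRF), rep(FALSE, nCN + nRN))
  idxCF <- seq_len(nCF)
  idxRF <- nCF + seq_len(nRF)
  rr <- rep(1, config@L)
  rr[idxRF] <- assignRelativeRisks(mafs, idxRF, config@rrMin, config@rrMax,
                                   config@protectiveProb)[idxRF]
  if (nCF > 0L)
    rr[idxCF] <- assignRelativeRisks(mafs, idxCF, config@commonRrMin,
                                     config@commonRrMax,
                                     config@protectiveProb)[idxCF]
  region <- new("RegionModel", mafs = mafs, rr = rr, f0 = NA_real_,
                form = config@form, functional = functional)
  region@f0 <- calibrateBaselinePenetrance(region, config@prevalence)
  region
}

## P(child count = gc | father count, mother count), indices offset by 1.
.PTRANS <- local({
  pt <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))  # P(parent transmits mutant)
  arr <- array(0, c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) for (bf in 0:1) for (bm in 0:1)
    arr[gf + 1, gm + 1, bf + bm + 1] <-
      arr[gf + 1, gm + 1, bf + bm + 1] + pt[gf + 1, bf + 1] * pt[gm + 1, bm + 1]
  arr
})

.riskCode <- function(gc, rr, form) {
  switch(form,
    dominant       = ifelse(gc >= 1, rr, 1),
    multiplicative = rr^gc,
    recessive      = ifelse(gc == 2, rr, 1))
}

## Exact conditional sampler: under the multiplicative across-variant model
## the trio genotype distribution given an affected child factorizes over
## variants, each site tilted by r_j(g_child); the baseline penetrance
## cancels.  Samples n trios at one variant from the 27-cell table.
.sampleVariantTrios <- function(n, q, rr, form) {
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  w <- .riskCode(0:2, rr, form)
  cells <- expand.grid(gf = 0:2, gm = 0:2, gc = 0:2)
  p <- hwe[cells$gf + 1] * hwe[cells$gm + 1] *
    .PTRANS[cbind(cells$gf + 1, cells$gm + 1, cells$gc + 1)] * w[cells$gc + 1]
  idx <- sample.int(nrow(cells), n, replace = TRUE, prob = p)
  list(father = cells$gf[idx], mother = cells$gm[idx], child = cells$gc[idx])
}

.simulateConditional <- function(region, nTrios) {
  L <- length(region@mafs)
  fa <- matrix(0L, L, nTrios); mo <- matrix(0L, L, nTrios)
  ch <- matrix(0L, L, nTrios)
  for (j in seq_len(L)) {
    s <- .sampleVariantTrios(nTrios, region@mafs[j], region@rr[j], region@form)
    fa[j, ] <- s$father; mo[j, ] <- s$mother; ch[j, ] <- s$child
  }
  list(father = fa, mother = mo, child = ch)
}

.simulateRejection <- function(region, nTrios, maxDraws) {
  L <- length(region@mafs)
  prev <- region@f0 *
    prod(.carrierExpectation(region@mafs, region@rr, region@form))
  if (nTrios / prev > maxDraws)
    stop(sprintf(
      "expected number of candidate families (~%.3g) exceeds the cap %.3g; lower nTrios, raise prevalence, or use method = 'conditional'",
      nTrios / prev, maxDraws))
  fa <- matrix(0L, L, 0); mo <- matrix(0L, L, 0); ch <- matrix(0L, L, 0)
  drawn <- 0
  while (ncol(ch) < nTrios) {
    m <- min(ceiling((nTrios - ncol(ch)) / prev * 1.2) + 100, 5e5)
    drawn <- drawn + m
    if (drawn > 2 * maxDraws)
      stop("rejection sampling exceeded the candidate-family cap")
    gf <- matrix(stats::rbinom(L * m, 2, region@mafs), L, m)
    gm <- matrix(stats::rbinom(L * m, 2, region@mafs), L, m)
    bf <- (gf == 2) + (gf == 1) * stats::rbinom(L * m, 1, 0.5)
    bm <- (gm == 2) + (gm == 1) * stats::rbinom(L * m, 1, 0.5)
    gc <- bf + bm
    logRisk <- colSums(matrix(
      log(.riskCode(as.vector(gc), rep(region@rr, m), region@form)), L, m))
    pAff <- pmin(1, region@f0 * exp(logRisk))
    keep <- stats::runif(m) < pAff
    fa <- cbind(fa, gf[, keep, drop = FALSE])
    mo <- cbind(mo, gm[, keep, drop = FALSE])
    ch <- cbind(ch, gc[, keep, drop = FALSE])
  }
  keep <- seq_len(nTrios)
  list(father = fa[, keep, drop = FALSE], mother = mo[, keep, drop = FALSE],
       child = ch[, keep, drop = FALSE])
}

#' Simulate an ascertained case-parents trio cohort
#'
#' Parents are drawn from HWE at the region MAFs (independent sites), each
#' parent transmits one allele per variant, and cohorts are conditioned on
#' the child being affected under the multiplicative-across-variants
#' penetrance model.  Two samplers are provided: \code{"rejection"} draws
#' families and keeps those with an affected child (probability
#' \eqn{f_0 \prod_j r_j^{code}}), exactly the generative ascertainment;
#' \code{"conditional"} (the default) samples from the identical ascertained
#' distribution directly, using the fact that the conditional trio
#' distribution factorizes over variants with a per-site \eqn{r_j(g_c)}
#' tilt, and is feasible at low prevalence.
#'
#' A pre-built \linkS4class{RegionModel} can be supplied via \code{region}
#' to bypass \code{\link{drawRegion}} -- the hook for plugging in an
#' external haplotype pool's frequencies without changing downstream code.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed optional integer seed; if \code{NULL} the current RNG state
#'   is used.
#' @param region optional \linkS4class{RegionModel} overriding the drawn
#'   region.
#' @param method \code{"conditional"} or \code{"rejection"}.
#' @param maxDraws cap on expected candidate families for the rejection
#'   sampler.
#' @return A \linkS4class{TrioCohort}; the realized region model is kept in
#'   \code{metadata()}.
#' @export
simulateTrioCohort <- function(config, seed = NULL, region = NULL,
                               method = c("conditional", "rejection"),
                               maxDraws = 2e7) {
  stopifnot(is(config, "SimulationConfig"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region)) region <- drawRegion(config)
  g <- switch(method,
    conditional = .simulateConditional(region, config@nTrios),
    rejection   = .simulateRejection(region, config@nTrios, maxDraws))
  co <- TrioCohort(father = g$father, mother = g$mother, child = g$child)
  S4Vectors::metadata(co) <- list(region = region, config = config,
                                  sampler = method)
  co
}

#' Simulate a stratified null cohort from two subpopulations
#'
#' Families come from subpopulation 2 with population proportion
#' \code{strat$prop2}; mating is within-subpopulation and per-variant MAFs
#' are drawn independently for each subpopulation (subpopulation 1 from the
#' rare range, subpopulation 2 from its own configured range).  Because
#' cohorts are ascertained on an affected child and the subpopulations have
#' different prevalences, the share of trios from subpopulation 2 is
#' \eqn{prop_2 K_2 / (prop_1 K_1 + prop_2 K_2)} -- 1/2 for the default
#' 20\%/4\% versus 80\%/1\% setting.  Only null regions (no functional
#' variants) are supported; under the null, ascertainment leaves genotypes
#' at their HWE/Mendelian distribution within each subpopulation.
#'
#' @param config a \linkS4class{SimulationConfig} with a \code{strat}
#'   setting and \code{nFunctional = 0}.
#' @param seed optional integer seed.
#' @return A \linkS4class{TrioCohort} with per-family \code{population}
#'   labels in \code{colData()}.
#' @export
simulateStratifiedCohort <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(config@strat) == 0L) stop("config has no strat setting")
  if (config@nFunctional != 0L)
    stop("stratified simulation supports null regions only")
  if (!is.null(seed)) set.seed(seed)
  st <- config@strat
  n <- config@nTrios
  L <- config@L
  w2 <- st$prop2 * st$prevalence2 /
    ((1 - st$prop2) * config@prevalence + st$prop2 * st$prevalence2)
  pop <- 1L + as.integer(stats::runif(n) < w2)
  mafs1 <- .drawRareMafs(L, config@mafLow, config@mafHigh)
  mafs2 <- .drawRareMafs(L, st$mafLow2, st$mafHigh2)
  fa <- matrix(0L, L, n); mo <- matrix(0L, L, n); ch <- matrix(0L, L, n)
  for (k in 1:2) {
    idx <- which(pop == k)
    if (length(idx) == 0L) next
    mafs <- if (k == 1L) mafs1 else mafs2
    for (j in seq_len(L)) {
      s <- .sampleVariantTrios(length(idx), mafs[j], 1, config@form)
      fa[j, idx] <- s$father; mo[j, idx] <- s$mother; ch[j, idx] <- s$child
    }
  }
  co <- TrioCohort(father = fa, mother = mo, child = ch,
                   population = pop)
  S4Vectors::metadata(co) <- list(mafs1 = mafs1, mafs2 = mafs2,
                                  config = config, sampler = "conditional")
  co
}
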
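test_that("transmission probability is exact, null-centred and properly bounded", {
  for (form in c("dominant", "multiplicative", "recessive"))
    for (q in c(0.01, 0.2, 0.5, 0.9))
      expect_equal(transmissionProbability(q, 1, form), 0.5)

  # rare-variant limit: an affected child is r:1 evidence for transmission
  expect_equal(transmissionProbability(1e-6, 5, "dominant"), 5 / 6,
               tolerance = 1e-5)

  # strictly increasing in rr under the dominant model
  ps <- transmissionProbability(rep(0.05, 5), c(1, 1.5, 2, 3, 5), "dominant")
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  expect_error(transmissionProbability(0, 2), "inside")
  expect_error(transmissionProbability(0.1, -1), "positive")
})

test_that("enumeration agrees with a simulated ascertainment oracle", {
  # 1e6 candidate trios at q = 0.3, rr = 2 (dominant): accept affected
  # children with probability proportional to penetrance, then count mutant
  # transmissions from heterozygous parents
  set.seed(99)
  N <- 1e6
  q <- 0.3; rr <- 2
  gf <- rbinom(N, 2, q); gm <- rbinom(N, 2, q)
  bf <- (gf == 2) + (gf == 1) * rbinom(N, 1, 0.5)
  bm <- (gm == 2) + (gm == 1) * rbinom(N, 1, 0.5)
  gc <- bf + bm
  keep <- runif(N) < ifelse(gc >= 1, rr, 1) / rr
  hetF <- gf == 1 & keep; hetM <- gm == 1 & keep
  pHat <- (sum(bf[hetF]) + sum(bm[hetM])) / (sum(hetF) + sum(hetM))
  pAna <- transmissionProbability(q, rr, "dominant")
  expect_true(pAna > 0.5 & pAna < 2 / 3)
  se <- sqrt(pAna * (1 - pAna) / (sum(hetF) + sum(hetM)))
  expect_lt(abs(pHat - pAna), 3 * se)
})

test_that("MAF estimates count parental alleles with clamping", {
  co <- makeCohort(matrix(0L, 1, 100), matrix(0L, 1, 100), matrix(0L, 1, 100))
  expect_equal(unname(estimateMaf(co)), 1 / 402)  # lower clamp at 1/(4n+2)

  fa <- matrix(0L, 1, 100); fa[1, 1] <- 1L
  co2 <- makeCohort(fa, matrix(0L, 1, 100),
                    matrix(c(1L, rep(0L, 99)), 1, 100))
  expect_equal(unname(estimateMaf(co2)), 1 / 400)

  # binomial sampling oracle at q = 0.01 with 2000 families
  set.seed(12)
  n <- 2000L
  fa <- matrix(rbinom(n, 2, 0.01), 1); mo <- matrix(rbinom(n, 2, 0.01), 1)
  bf <- (fa == 2) + (fa == 1) * rbinom(n, 1, 0.5)
  bm <- (mo == 2) + (mo == 1) * rbinom(n, 1, 0.5)
  co3 <- makeCohort(fa, mo, matrix(bf + bm, 1))
  expect_lt(abs(estimateMaf(co3) - 0.01), 3 * sqrt(0.01 * 0.99 / (4 * n)))
})

test_that("delta bounds decrease with MAF and respect the null degenerate case", {
  expect_error(deltaBound(0.01, 1), "exceed 1")
  expect_equal(deltaBound(1e-8, 5), 5 / 6, tolerance = 1e-6)
  qs <- c(0.001, 0.005, 0.01, 0.05, 0.2)
  ds <- deltaBound(qs, 5)
  expect_true(all(diff(ds) < 0))
  expect_true(all(ds > 0.5 & ds < 1))
})

test_that("mixture pmf is a proper, stable distribution with known special cases", {
  # binomial degeneracy at pi = 0
  expect_equal(mixtureLogPmf(0:10, 10, 0.8, 0), dbinom(0:10, 10, 0.5, log = TRUE))
  # H = 1 closed form: mean of Uniform(0.5, 0.8)
  expect_equal(mixtureLogPmf(1, 1, 0.8, 1), log(0.65))
  expect_equal(mixtureLogPmf(0, 1, 0.8, 1), log(0.35))
  # normalization across H, delta, pi
  for (H in c(1, 5, 17, 50))
    for (delta in c(0.51, 0.8, 0.95))
      for (pi in c(0, 0.3, 1))
        expect_lt(abs(sum(exp(mixtureLogPmf(0:H, H, delta, pi))) - 1), 1e-12)
  # quadrature oracle for the uniform random-effects component
  unif <- integrate(function(p) dbinom(8, 10, p), 0.5, 0.8,
                    rel.tol = 1e-13)$value / 0.3
  oracle <- 0.5 * dbinom(8, 10, 0.5) + 0.5 * unif
  expect_lt(abs(exp(mixtureLogPmf(8, 10, 0.8, 0.5)) - oracle), 1e-10)
  # large-H stability
  big <- mixtureLogPmf(c(4900, 5200, 9000), 1e4, 0.7, 0.5)
  expect_true(all(is.finite(big)))
  expect_error(mixtureLogPmf(1, 2, 0.5, 0.5), "delta")
  expect_error(mixtureLogPmf(3, 2, 0.8, 0.5), "0..H")
})

test_that("aggregate mass above H/2 increases with the functional fraction", {
  H <- 20; delta <- 0.7
  mass <- vapply(seq(0, 1, by = 0.1), function(pi)
    sum(exp(mixtureLogPmf(11:20, H, delta, pi))), numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("pseudo-likelihood handles uninformative variants and reduces correctly", {
  s <- makeSummaryFromCounts(T = c(3, 0), H = c(5, 0))
  spec <- new("RandomEffectsSpec", gamma = 5, qHat = c(0.01, 0.01),
              delta = deltaBound(c(0.01, 0.01), 5), pi = NA_real_)
  expect_equal(pseudoLogLik(0, s, spec), dbinom(3, 5, 0.5, log = TRUE))
  expect_equal(pseudoLogLik(0.4, s, spec),
               mixtureLogPmf(3, 5, spec@delta[1], 0.4))
  z <- makeSummary(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(pseudoLogLik(0.7, z, spec), 0)
  expect_error(fitPi(z, spec), "uninformative")
  expect_error(pseudoLogLik(0, s, new("RandomEffectsSpec", gamma = 5,
                                      qHat = 0.01, delta = 0.8,
                                      pi = NA_real_)),
               "aligned")
})

test_that("the functional-fraction MLE sits where a dense grid puts it", {
  # deficit of transmissions everywhere: likelihood is maximized at pi = 0
  s <- makeSummaryFromCounts(T = c(2, 4, 1), H = c(6, 9, 4))
  spec <- new("RandomEffectsSpec", gamma = 5, qHat = rep(0.005, 3),
              delta = deltaBound(rep(0.005, 3), 5), pi = NA_real_)
  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, pseudoLogLik, numeric(1), summary = s, spec = spec)
  expect_equal(grid[which.max(ll)], 0)
  expect_equal(fitPi(s, spec), 0)
  expect_equal(lrtStatistic(s, spec)$lambda, 0)

  # strong excess at every variant with large H: pi-hat near 1
  s2 <- makeSummaryFromCounts(T = rep(400, 12), H = rep(500, 12))
  spec2 <- new("RandomEffectsSpec", gamma = 5, qHat = rep(0.005, 12),
               delta = deltaBound(rep(0.005, 12), 5), pi = NA_real_)
  expect_gt(fitPi(s2, spec2), 0.9)

  # interior case: grid+refine agrees with a dense direct scan
  s3 <- makeSummaryFromCounts(T = c(9, 3, 8, 5, 4), H = c(12, 8, 10, 10, 8))
  spec3 <- new("RandomEffectsSpec", gamma = 5, qHat = rep(0.005, 5),
               delta = deltaBound(rep(0.005, 5), 5), pi = NA_real_)
  ll3 <- vapply(grid, pseudoLogLik, numeric(1), summary = s3, spec = spec3)
  expect_equal(fitPi(s3, spec3), grid[which.max(ll3)], tolerance = 2e-3)
  lam <- lrtStatistic(s3, spec3)
  expect_equal(lam$lambda,
               2 * (max(ll3) - pseudoLogLik(0, s3, spec3)),
               tolerance = 1e-6)
})

test_that("the functional fraction is recovered on synthetic transmission data", {
  set.seed(314)
  L <- 100; H <- rep(200L, L); delta <- 0.75; pi0 <- 0.3
  spec <- new("RandomEffectsSpec", gamma = 5, qHat = rep(0.005, L),
              delta = rep(delta, L), pi = NA_real_)
  fits <- vapply(seq_len(30), function(i) {
    functional <- runif(L) < pi0
    p <- ifelse(functional, runif(L, 0.5, delta), 0.5)
    fitPi(makeSummaryFromCounts(rbinom(L, H, p), H), spec)
  }, numeric(1))
  expect_lt(abs(mean(fits) - pi0), 3 * sd(fits) / sqrt(30))
})

test_that("the LRT is non-negative, degenerate-safe and permutation-consistent", {
  # every X = 0: Lambda ties across permutations, p = 1
  co <- makeCohort(matrix(0L, 2, 10), matrix(2L, 2, 10), matrix(1L, 2, 10))
  res <- lrtTest(co, gamma = 5, nPerm = 60L, seed = 2L)
  expect_equal(pValue(res), 1)
  expect_equal(statistic(res), 0)
  expect_equal(piHat(res), 0)
  expect_error(lrtTest(co, gamma = 1), "exceed 1")

  # Lambda >= 0 on random cohorts; MAF estimates and delta bounds are
  # untouched by the within-family swap (parents only)
  for (seed in 1:6) {
    coR <- simulateTrioCohort(
      simulationConfig(L = 3, nFunctional = 1, rrMin = 2, rrMax = 2,
                       mafLow = 0.02, mafHigh = 0.1, nTrios = 40L),
      seed = seed)
    r <- lrtTest(coR, nPerm = 40L, seed = seed)
    expect_gte(statistic(r), 0)
    flips <- sample(c(-1, 1), nFamilies(coR), replace = TRUE)
    expect_equal(estimateMaf(swapCohort(coR, flips)), estimateMaf(coR),
                 ignore_attr = TRUE)
  }

  # the permutation engine reproduces a direct per-permutation recomputation
  co2 <- simulateTrioCohort(
    simulationConfig(L = 2, nFunctional = 2, rrMin = 3, rrMax = 3,
                     mafLow = 0.05, mafHigh = 0.1, nTrios = 50L), seed = 8L)
  spec2 <- randomEffectsSpec(co2, gamma = 5)
  s2 <- summarizeTransmission(co2)
  lamFn <- function(s) lrtStatistic(s, spec2)$lambda
  slow <- permutationPvalue(lamFn, s2, nPerm = 200L, seed = 5L)
  fast <- lrtTest(co2, gamma = 5, nPerm = 200L, seed = 5L)
  expect_equal(statistic(fast), statistic(slow))
  expect_equal(pValue(fast), pValue(slow))
})
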
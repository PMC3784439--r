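test_that("relative risks interpolate by MAF, with protective inversion", {
  mafs <- c(0.001, 0.004, 0.01, 0.5)
  rr <- assignRelativeRisks(mafs, 1:3, rrMin = 1.8, rrMax = 2.0)
  expect_equal(rr[1], 2.0)                      # smallest MAF, largest effect
  expect_equal(rr[3], 1.8)                      # largest MAF, smallest effect
  expect_equal(rr[2], 2.0 - 0.2 * 0.003 / 0.009)
  expect_equal(rr[4], 1)                        # nonfunctional untouched

  expect_equal(assignRelativeRisks(0.005, 1, 1.8, 2.0), 1.9)  # single: midpoint

  set.seed(1)
  rrP <- assignRelativeRisks(rep(0.005, 50), 1:50, 2, 2, protectiveProb = 1)
  expect_true(all(rrP == 0.5))
  rr0 <- assignRelativeRisks(runif(20, 0.001, 0.01), 1:20, 1.8, 2.0)
  expect_true(all(rr0 >= 1))
  # protective inverses land in the printed 0.50-0.56 window
  set.seed(2)
  rrMix <- assignRelativeRisks(runif(10, 0.001, 0.01), 1:10, 1.8, 2.0,
                               protectiveProb = 0.5)
  prot <- rrMix[rrMix < 1]
  expect_true(all(prot >= 1 / 2.0 & prot <= 1 / 1.8))
  expect_error(assignRelativeRisks(0.01, 1, 3, 2), "exceed")
})

test_that("baseline penetrance calibration matches closed forms and Monte Carlo", {
  nullReg <- fixedRegion(rep(0.005, 4), rep(1, 4))
  expect_equal(nullReg@f0, 0.01)

  oneVar <- fixedRegion(0.01, 2)
  expect_equal(oneVar@f0, 0.01 / (1 + (1 - 0.99^2)))

  # Monte-Carlo prevalence oracle: children drawn unconditionally
  reg <- fixedRegion(c(0.05, 0.02), c(2, 3), prevalence = 0.02)
  set.seed(55)
  N <- 1e6
  aff <- rep(1, N)
  for (j in 1:2) {
    gc <- rbinom(N, 2, reg@mafs[j])
    aff <- aff * ifelse(gc >= 1, reg@rr[j], 1)
  }
  prevHat <- mean(runif(N) < reg@f0 * aff)
  expect_lt(abs(prevHat - 0.02), 3 * sqrt(0.02 * 0.98 / N))

  # capped-penetrance mass beyond tolerance is an error
  expect_error(fixedRegion(rep(0.3, 5), rep(3, 5), prevalence = 0.5),
               "probability mass")
})

test_that("regions honour the design: ranges, roles, monotone effect sizes", {
  cfg <- simulationConfig(L = 4, nFunctional = 2, rrMin = 3.4, rrMax = 3.6,
                          nTrios = 100L)
  set.seed(77)
  reg <- drawRegion(cfg)
  expect_true(all(reg@mafs >= 0.001 & reg@mafs <= 0.01))
  expect_equal(reg@functional, c(TRUE, TRUE, FALSE, FALSE))
  fr <- reg@rr[1:2]
  expect_true(all(fr >= 3.4 & fr <= 3.6))
  expect_equal(which.max(fr), which.min(reg@mafs[1:2]))
  expect_true(all(reg@rr[3:4] == 1))

  cfg0 <- simulationConfig(L = 3, nFunctional = 0, nTrios = 100L)
  reg0 <- drawRegion(cfg0)
  expect_true(all(reg0@rr == 1))
  expect_equal(reg0@f0, 0.01)

  # common variants sit at fixed MAFs with their own RR range
  cfgC <- simulationConfig(L = 5, nFunctional = 5, rrMin = 2.4, rrMax = 2.6,
                           nTrios = 100L, commonMaf = 0.03,
                           commonFunctional = TRUE, commonRrMin = 1.1,
                           commonRrMax = 1.2)
  regC <- drawRegion(cfgC)
  expect_equal(regC@mafs[1], 0.03)
  expect_equal(regC@rr[1], 1.15)
  expect_true(all(regC@rr[2:5] >= 2.4 & regC@rr[2:5] <= 2.6))
})

test_that("ascertained cohorts transmit at the analytic rate", {
  # null: pooled transmitted fraction from heterozygous parents is 1/2
  cfg0 <- simulationConfig(L = 2, nFunctional = 0, mafLow = 0.1,
                           mafHigh = 0.3, nTrios = 4000L)
  s0 <- summarizeTransmission(simulateTrioCohort(cfg0, seed = 41L))
  frac0 <- sum(transmittedCounts(s0)) / sum(hetTotals(s0))
  expect_lt(abs(frac0 - 0.5), 3 * sqrt(0.25 / sum(hetTotals(s0))))

  # functional variant: empirical fraction matches transmissionProbability
  reg <- fixedRegion(c(0.005, 0.005), c(5, 1))
  cfg <- simulationConfig(L = 2, nFunctional = 1, rrMin = 5, rrMax = 5,
                          nTrios = 30000L)
  co <- simulateTrioCohort(cfg, seed = 43L, region = reg)
  s <- summarizeTransmission(co)
  pAna <- transmissionProbability(0.005, 5, "dominant")
  H1 <- hetTotals(s)[1]
  expect_lt(abs(transmittedCounts(s)[1] / H1 - pAna),
            3 * sqrt(pAna * (1 - pAna) / H1))
  # and the nonfunctional variant stays at 1/2
  H2 <- hetTotals(s)[2]
  expect_lt(abs(transmittedCounts(s)[2] / H2 - 0.5), 3 * sqrt(0.25 / H2))
})

test_that("conditional and rejection samplers draw the same trio distribution", {
  reg <- fixedRegion(0.3, 3, prevalence = 0.05)
  cfg <- simulationConfig(L = 1, nFunctional = 1, rrMin = 3, rrMax = 3,
                          mafLow = 0.29, mafHigh = 0.31, prevalence = 0.05,
                          nTrios = 4000L)
  key <- function(co) paste(fatherGeno(co), motherGeno(co), childGeno(co))
  a <- key(simulateTrioCohort(cfg, seed = 61L, region = reg,
                              method = "conditional"))
  b <- key(simulateTrioCohort(cfg, seed = 62L, region = reg,
                              method = "rejection"))
  lev <- union(unique(a), unique(b))
  tab <- rbind(table(factor(a, lev)), table(factor(b, lev)))
  keep <- colSums(tab) >= 10
  hom <- suppressWarnings(chisq.test(tab[, keep]))
  expect_gt(hom$p.value, 0.001)

  # a hopeless acceptance rate is refused with guidance
  cfgBad <- simulationConfig(L = 1, nFunctional = 0, prevalence = 0.001,
                             nTrios = 100000L)
  expect_error(simulateTrioCohort(cfgBad, seed = 1L, method = "rejection",
                                  maxDraws = 1e6),
               "cap")
})

test_that("stratified null cohorts mix subpopulations by ascertained prevalence", {
  cfg <- simulationConfig(L = 6, nFunctional = 0, nTrios = 6000L,
                          strat = list(prop2 = 0.2, prevalence2 = 0.04,
                                       mafLow2 = 0.001, mafHigh2 = 0.03))
  co <- simulateStratifiedCohort(cfg, seed = 71L)
  pop <- SummarizedExperiment::colData(co)$population
  # ascertained share of subpopulation 2: 0.2*0.04 / (0.8*0.01 + 0.2*0.04)
  expect_lt(abs(mean(pop == 2L) - 0.5), 3 * sqrt(0.25 / 6000))

  # cohort MAF is the ascertainment-weighted mixture of the two draws
  md <- S4Vectors::metadata(co)
  qmix <- 0.5 * md$mafs1 + 0.5 * md$mafs2
  qhat <- estimateMaf(co)
  se <- sqrt(qmix * (1 - qmix) / (4 * 6000))
  expect_true(all(abs(qhat - qmix) < 4 * se + 1e-4))

  # transmissions remain fair despite stratification
  s <- summarizeTransmission(co)
  frac <- sum(transmittedCounts(s)) / sum(hetTotals(s))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(hetTotals(s))))

  expect_error(simulateStratifiedCohort(
    simulationConfig(L = 2, nFunctional = 0, nTrios = 10L)), "strat")
  expect_error(simulateStratifiedCohort(
    simulationConfig(L = 2, nFunctional = 1, rrMin = 2, rrMax = 2,
                     nTrios = 10L,
                     strat = list(prop2 = 0.2, prevalence2 = 0.04,
                                  mafLow2 = 0.001, mafHigh2 = 0.03))),
    "null regions")
})

test_that("simulated cohorts always pass Mendelian validation", {
  for (seed in 1:4) {
    co <- simulateTrioCohort(
      simulationConfig(L = 3, nFunctional = 1, rrMin = 3, rrMax = 3,
                       mafLow = 0.005, mafHigh = 0.05, nTrios = 50L),
      seed = seed)
    expect_true(methods::validObject(co))
  }
})
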
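---
title: "Testing grouped rare variants with case-parents trios"
author: "trioRareVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing grouped rare variants with case-parents trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioRareVar)
```

# The problem

Groups of rare variants (minor allele frequency 0.001–0.01) in a gene
region may jointly influence disease risk, but population-based
case-control collapsing tests can be badly confounded by rare-variant
population stratification.  Family designs avoid this: conditional on a
heterozygous parent, the transmission of the mutant allele to an affected
child is a coin flip under the null of no association, *whatever* the
population structure.  This package implements four region-level
association tests for case-parents trios, all functions of the transmitted
minus non-transmitted mutant-allele counts, together with the within-family
permutation null that calibrates them and a simulation framework for
studying their operating characteristics.

# Data reduction

For family $i$ and variant $j$, with mutant-allele counts $g_{f}$, $g_{m}$,
$g_{c}$ for father, mother and affected child, the package works from

$$X_{ij} = 2 g_{c,ij} - g_{f,ij} - g_{m,ij},$$

the number of transmitted minus non-transmitted mutant alleles, and from
the per-family count of heterozygous parents.  Homozygous parents are
uninformative.  Per variant, $H_j$ is the total number of heterozygous
parents, $b_j = (H_j + \sum_i X_{ij})/2$ the mutant alleles they
transmitted, and $c_j = H_j - b_j$ the ones they did not.  The identity
$b_j + c_j = H_j$ and the bound $|X_{ij}| \le$ (heterozygous parents in
family $i$) are enforced as class validity.  Phase is never needed: a
doubly heterozygous family with a heterozygous child contributes
$b = c = 1$ automatically.

# The four tests

* **Largest single-variant TDT** ($T_s$): $\max_j (b_j - c_j)^2/(b_j + c_j)$.
* **Multivariable score test** ($T_{mult}$): $U^\top V^- U$ with
  $U_j = \sum_i X_{ij}$ and $V = \sum_i X_i X_i^\top$, $V^-$ a Moore–Penrose
  generalized inverse.  The scores have mean zero under the null, so $V$ is
  left uncentered.  The asymptotic $\chi^2_{rank(V)}$ reference is exposed
  as a diagnostic only; it is conservative for sparse data.
* **Combined TDT** (cTDT): pool across variants, $(B - C)^2/(B + C)$ with
  $B = \sum_j b_j$, $C = \sum_j c_j$.
* **Random-effects likelihood-ratio test** (LRT), described next.

Uninformative regions ($b + c = 0$) score 0 by convention.

## The random-effects mixture model

Conditional on $H_j$, the transmitted count $T_j = b_j$ is
$\mathrm{Binomial}(H_j, p_j)$; $p_j = 1/2$ under the null.  A functional
deleterious variant has $1/2 < p_j < 1$, and if relative risks are bounded
by a ceiling $\gamma$ (default 5), then $p_j \le \delta_j$, where
$\delta_j$ is the transmission probability at relative risk $\gamma$ for
the variant's estimated MAF under the dominant model.  $\delta_j$ decreases
with MAF, encoding the usual expectation that rarer variants may carry
larger effects.  Let $\pi$ be the fraction of functional variants in the
region.  The model treats each $p_j$ as a random effect,

$$p_j \sim (1 - \pi)\,\mathbb{1}\{p_j = 1/2\} +
  \pi\,\mathrm{Uniform}(1/2, \delta_j),$$

giving the marginal

$$P(T_j = t) = (1-\pi)\binom{H_j}{t}2^{-H_j} +
  \pi\,\frac{F_{\delta_j}(t+1, H_j-t+1) - F_{1/2}(t+1, H_j-t+1)}
            {(H_j + 1)(\delta_j - 1/2)},$$

where $F_x(a, b)$ is the regularized incomplete beta function (the
$\mathrm{Beta}(a,b)$ cdf at $x$); the identity
$\binom{H}{t} B(t+1, H-t+1) = 1/(H+1)$ collapses the combinatorial factor.
The product of these marginals over variants is a *pseudo*-likelihood —
transmitted counts may be dependent across variants — maximized over
$\pi \in [0,1]$ to give $\hat\pi$ and
$\Lambda = 2\log L(\hat\pi) - 2\log L(0) \ge 0$.  Association testing is
the boundary test $H_0: \pi = 0$, with inference by permutation rather than
asymptotics, which restores validity under arbitrary cross-variant
dependence.

## The permutation null

Within each family, the transmitted and non-transmitted genotype vectors
are exchangeable under the null, so a permutation replicate multiplies each
family's whole row $X_i$ by an independent $\pm 1$ flip — equivalently,
replaces the child genotype vector by its complement
$g_f + g_m - g_c$.  The flip is applied at the family level to the entire
cross-variant vector: this requires genotypes only (no phase) and preserves
cross-variant dependence; flipping parents separately is not computable
from genotypes when both parents are heterozygous.  Heterozygous-parent
counts, and hence every $H_j$, MAF estimate and $\delta_j$, are invariant
under the swap.  P-values use the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, which is a valid
p-value, handles ties, and is never exactly zero.  All four statistics
depend on a replicate only through the flip-weighted column sums
$S = F^\top X$ (and the flip-invariant $V$ and $H$), so one shared stream
of flips serves all tests of a run; each marginal p-value remains exact.

# Tunable parameters

* `gamma` (unitless relative-risk ceiling, default 5): the largest
  genotype relative risk entertained by the random-effects bound.  A
  smaller, better-informed ceiling sharpens the alternative and can add
  power; 5 is a safe general-purpose default.
* `nPerm` (default 10000): permutation resolution; p-values are granular at
  $1/(n_{perm}+1)$.
* `mutantRule` (`minor`/`alt`): which allele is counted.  The minor allele
  is determined from parental chromosomes only, so ascertained children
  cannot flip the label.
* MAF estimates $\hat q_j$ use the parental allele frequency
  ($4n$ chromosomes), clamped to $[1/(4n+2), 1 - 1/(4n+2)]$.  The parental
  estimator is consistent under HWE, unbiased by ascertainment of the
  child, and permutation-invariant; the clamp keeps $\delta_j$ defined at
  variants monomorphic in the parents (such variants have $H_j = 0$ and
  cannot influence $\Lambda$).

# The simulator

`simulateTrioCohort()` generates ascertained case-parents cohorts from a
`SimulationConfig`: parents in HWE at per-variant MAFs, Mendelian
transmission, and an affected child under penetrance
$f_0 \prod_j r_j^{code(g_{c,j})}$ (joint model multiplicative across
variants; per-variant form dominant by default, multiplicative and
recessive available).  $f_0$ is calibrated so the population prevalence is
exact under independent sites (default 1%).

Design choices worth recording:

* **Conditional sampling.**  Because the joint penetrance is multiplicative
  across variants and sites are independent, the trio genotype distribution
  *given an affected child* factorizes per variant, each site tilted by
  $r_j(g_c)$ with $f_0$ cancelling.  The default sampler draws from this
  exact conditional distribution site by site, which makes ascertainment at
  1% prevalence cheap.  A literal rejection sampler (draw families, keep
  affected children, with a configurable cap on candidate draws) is kept
  both as the generative reference — the two are checked against each other
  and against the analytic transmission probability in the test suite — and
  for users who want disease-status draws.
* **MAF spectrum.**  Rare-variant MAFs are drawn from a truncated neutral
  site-frequency spectrum (density $\propto 1/q$, i.e. log-uniform) on the
  configured window, the spectrum a coalescent haplotype pool delivers when
  restricted to a MAF range.  A uniform draw would over-represent the most
  informative top of the window and systematically inflate power relative
  to sequence-derived data.  A pre-built `RegionModel` can be passed via
  the `region` argument to plug in frequencies from an external haplotype
  pool without touching downstream code.
* **Effect sizes.**  Functional relative risks interpolate linearly between
  `rrMax` at the smallest functional MAF and `rrMin` at the largest
  (midpoint when there is a single functional variant); common functional
  variants form their own group with their own RR range.  Protective
  variants arise by inverting the assigned RR with probability
  `protectiveProb`.
* **Penetrance cap.**  With several deleterious variants the multiplicative
  penetrance formally exceeds 1 for children mutant at most functional
  sites at once.  Such genotypes are astronomically improbable for rare
  variants; the samplers cap the Bernoulli risk at 1 and calibration
  refuses only configurations where the capped mass exceeds $10^{-6}$
  (bounded by a Poisson-binomial tail).  Erroring on any formal violation
  would reject the standard rare-variant designs this simulator exists for.
* **Stratification.**  The two-subpopulation null draws each family's
  subpopulation with probability proportional to
  $\mathrm{proportion} \times \mathrm{prevalence}$ — ascertainment on an
  affected child re-weights subpopulations, so with 20% of the population
  at 4% prevalence versus 80% at 1%, half of the ascertained trios come
  from the minority population.  Mating is within-subpopulation and each
  subpopulation has its own MAF draw.

## What the generator does and does not emulate

The generator reproduces the marginal ingredients that drive these tests:
HWE parents at a controlled MAF spectrum, Mendelian transmission,
ascertainment, per-variant effect sizes tied to frequency.  It treats sites
as independent, so it carries **no linkage disequilibrium**.  For rare
variants the statistics condition on per-family vectors and LD enters only
at second order — but where a common variant sits on haplotypes that also
carry rare risk alleles, hitchhiking can give the common site transmission
distortion far beyond its marginal relative risk.  Power results involving
common variants embedded in sequence data should therefore be read as
conservative: passing tests here demonstrate correct behaviour under the
independent-sites model, not under strong haplotype structure.  De novo
mutations, genotyping error and missingness are likewise out of scope.

# Numerical choices

* The mixture pmf is evaluated fully in log space; the beta-cdf difference
  is taken on whichever tail keeps both terms small
  ($t \gtrless H/2$), so the pmf is stable to $H \ge 10^4$.
* The pseudo-log-likelihood is concave in $\pi$ (each term is the log of a
  linear function), so the optimizer — a 0.01-step grid followed by
  golden-section refinement to $10^{-6}$, boundary values admissible — is
  exact for the profile; a derivative-free scheme is used because the
  profile can be nearly flat near 0 for small regions.
* Generalized inverses zero singular values below
  $\max(\mathrm{dim}) \cdot \epsilon \cdot \sigma_{max}$; rank-deficient
  $V$ is the norm with rare variants (duplicated or monomorphic columns).
* Degenerate inputs: regions with all $H_j = 0$ give every statistic 0 and
  permutation p-value 1; `fitPi()` on a fully uninformative summary is an
  error.
* Replicates of a Monte-Carlo experiment are seeded by a fixed integer mix
  of (master seed, replicate index), so experiments are reproducible and
  schedule-independent.

# Scale of the shipped checks

The test suite and the acceptance script rerun the evaluation designs at
reduced replication (typically 150–500 simulated cohorts with 400–1000
permutations each, against the reference analyses' 5000 × 10000), with
comparison bands widened to three Monte-Carlo standard errors at the scaled
replicate count plus a 0.03 allowance on power comparisons for the
haplotype-pool substitution.  These sizes keep the whole suite in the
minutes range on a single core while leaving the bands narrow enough to be
informative.

# Known limitations

* No missing-parent designs (1-TDT style), no sibling controls, no general
  pedigrees: complete case-parents trios only, and families with any
  missing genotype are dropped whole.
* The recessive form is implemented in the simulator and the transmission
  enumeration, but rare homozygotes are so unlikely that all four tests
  have little power there; no operating characteristics are claimed.
* Confidence intervals for $\pi$ and per-variant effect estimation are out
  of scope; $\hat\pi$ is reported as a descriptive by-product.
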
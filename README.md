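# trioRareVar

Association tests for **groups of rare (and common) variants** in a gene
region using **case-parents trios** (father, mother, affected child).
Population-based collapsing tests can be confounded by rare-variant
population stratification; trio tests are not, because under the null a
heterozygous parent transmits the mutant allele to the affected child with
probability 1/2 regardless of population structure.

The package is for statistical geneticists analysing sequenced trio data
at the gene/region level, and for methodologists studying the operating
characteristics of region-level family-based tests.

## The statistics

All tests reduce each family x variant cell to
`X_ij = 2*g_child - g_father - g_mother`, the transmitted minus
non-transmitted mutant-allele count, and per variant to `H_j` (heterozygous
parents), `b_j` (mutant alleles they transmitted) and `c_j = H_j - b_j`:

* `ts` — largest single-variant TDT: `max_j (b_j - c_j)^2 / (b_j + c_j)`;
* `tmult` — multivariable score test: `U' V^- U` with `U = colSums(X)`,
  `V = X'X` and `V^-` a Moore–Penrose generalized inverse;
* `ctdt` — combined TDT: `(B - C)^2 / (B + C)` after pooling counts across
  variants;
* `lrt` — a likelihood-ratio test under a random-effects mixture: each
  variant's transmission probability is either exactly 1/2 (nonfunctional,
  probability `1 - pi`) or Uniform(1/2, `delta_j`) (functional), where
  `delta_j` is the largest transmission probability consistent with a
  relative-risk ceiling `gamma` (default 5) at the variant's estimated
  MAF.  The marginal of the transmitted count mixes a Binomial(H, 1/2)
  with a beta-function term; `Lambda = 2 log L(pi-hat) - 2 log L(0)` tests
  `pi = 0`.

All p-values come from the within-family permutation null: each family's
transmitted genotype vector is swapped with its complement
`g_f + g_m - g_c` under independent ±1 flips, preserving `H_j` and
cross-variant dependence.  The simulation framework reproduces regional
architectures — functional fraction, MAF-dependent effect sizes,
protective variants, common/rare mixtures, two-population stratification —
with ascertainment on an affected child.

## Worked example

Simulate 500 ascertained trios over a 10-variant region in which all ten
rare variants are deleterious (relative risks 1.8–2.0, rarer variants
getting larger effects), then run all four tests with a shared permutation
stream:

```r
library(trioRareVar)

cfg <- simulationConfig(L = 10, nFunctional = 10, rrMin = 1.8, rrMax = 2.0,
                        nTrios = 500)
cohort <- simulateTrioCohort(cfg, seed = 1)
res <- trioTest(cohort, methods = "all", gamma = 5, nPerm = 10000, seed = 2)
for (r in res) show(r)
```

```
ts: statistic = 7, permutation p = 0.05969 (10000 permutations, seed 2)
tmult: statistic = 21.97, permutation p = 0.008099 (10000 permutations, seed 2)
ctdt: statistic = 15.45, permutation p = 9.999e-05 (10000 permutations, seed 2)
lrt: lambda = 13.7, pi-hat = 1, permutation p = 0.0002 (gamma 5, 10000 permutations, seed 2)
```

The random-effects test estimates that essentially all of the region's
variants are functional and rejects the null decisively (`p = 2e-4`), as
does the pooled combined TDT; the max-single-variant test, which cannot
aggregate ten weak signals, misses 0.05 here.  On
real data, start from files instead:

```r
cohort <- readTrioVcf("region.vcf", "families.ped", mutantRule = "minor")
res <- trioTest(cohort, methods = "all")
writeResults(res, "results.tsv", format = "tsv")
```

A thin command-line front end with `simulate`, `test`, `type1` and `power`
subcommands is installed at
`system.file("scripts", "trio-rarevar.R", package = "trioRareVar")`.

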
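# pleioscan

Shared genetic architecture analysis and pleiotropic gene discovery from
GWAS summary statistics.

## The problem

Related complex traits — autoimmune diseases are the canonical example —
overlap clinically and mechanistically, and genome-wide association
studies suggest they overlap genetically as well.  Quantifying that
overlap from summary statistics alone (no individual-level genotypes)
requires three complementary views:

- **How heritable is each trait, and how correlated are their genetic
  effects?**  LD score regression: regressing per-SNP chi-square
  statistics on LD scores separates polygenic signal (slope) from
  confounding (intercept), and its bivariate form estimates the genetic
  correlation `rg = gcov / sqrt(h2_1 h2_2)`.  The stratified form
  partitions heritability across functional annotations and tests
  category enrichment.
- **How many causal variants do two traits share?**  A four-component
  causal mixture: each SNP is null for both traits (probability `pi0`),
  causal for one (`pi1`, `pi2`), or causal for both (`pi12`, with effect
  correlation `rho12`).  Fitted by a characteristic-function likelihood,
  it yields Venn-diagram quantities — unique and shared effective
  variants explaining 90% of each trait's heritability — and the
  mixture-implied `rg = pi12 rho12 s1 s2 / sqrt((pi1+pi12)s1^2 (pi2+pi12)s2^2)`,
  making explicit that extensive variant sharing can coexist with modest
  effect correlation.
- **Which genes drive the sharing?**  Adaptive sum-of-powered-score
  tests.  For a gene's traits-by-SNPs z-matrix,
  `SPUs(g1; z) = (sum_j |z_j|^g1)^(1/g1)` aggregates SNPs and
  `MTSPUsSet(g1, g2; Z) = sum_h SPUs(g1; Z_h)^g2` aggregates traits; the
  adaptive versions (aSPUs, MTaSPUsSet) take the minimum Monte-Carlo
  p-value over the power grid `{1, 2, 4, 8}`, with matrix-normal nulls
  (among-SNP covariance from panel LD, among-trait covariance estimated
  from pruned null SNPs) and staged replicate escalation up to 10^6
  draws.  A gene significant in the multi-trait test *and* in at least
  one single-trait test at the `alpha/G` threshold is flagged
  pleiotropic.

The package implements all three layers plus the plumbing around them
(summary-statistics ingestion with allele harmonization, LD computation
and pruning, SNP-to-gene mapping, conditional Q-Q diagnostics,
hypergeometric gene-set enrichment) and a synthetic-data generator with
recorded ground truth that makes every stage testable.

## Worked example

Simulate two diseases with a partially shared sparse architecture
(0.4% of 20,000 SNPs causal per trait, half of them shared with effect
correlation 0.8, so the generative genetic correlation is 0.4), then
recover the architecture:

```r
library(pleioscan)

ld <- ld_block_structure(20000, 10, rho_levels = c(0.25, 0.45, 0.65, 0.85),
                         seed = 42)
arch <- mixture_params(pi0 = 0.994, pi1 = 0.002, pi2 = 0.002, pi12 = 0.002,
                       sigma1_sq = 0.3 / (0.004 * 20000),
                       sigma2_sq = 0.3 / (0.004 * 20000), rho12 = 0.8)
truth <- draw_effects(arch, 20000, seed = 1)
ss <- simulate_zscores(truth, ld, n = 50000, seed = 2,
                       trait_ids = c("diseaseA", "diseaseB"))

fit_h2(ss$diseaseA, ld)
#> LD score regression (observed scale), 20000 SNPs, 200 blocks
#>   h2        = 0.2109 (se 0.0663)
#>   intercept = 0.7661 (se 0.3697)
#>   mean chi2 = 2.8753

fit_rg(ss$diseaseA, ss$diseaseB, ld)
#> bivariate LD score regression, 20000 SNPs
#>   rg = 0.4254 (se 0.1407), p = 0.0025
#>   genetic covariance = 0.09009, cross-intercept = -0.1884

uA <- fit_univariate(ss$diseaseA, ld, seed = 3)
uB <- fit_univariate(ss$diseaseB, ld, seed = 4)
bv <- fit_bivariate(ss$diseaseA, ss$diseaseB, ld, uA, uB, seed = 5,
                    n_boot = 4)
overlap_summary(bv)
#> polygenic overlap (variants explaining 90% of h2):
#>   unique trait 1: 0.01K   shared: 0.02K (se 0.00K)   unique trait 2: 0.02K
#>   mixture-implied rg = 0.321
```

Reading the output: the heritability estimate (0.21, SE 0.07) brackets
the simulated truth within sampling error on this single 20,000-SNP
replicate; the genetic correlation (0.43, SE 0.14) recovers the
generative 0.4 and is significant at the pairwise Bonferroni level; and
the overlap summary reports effective-variant counts on the thousands
("K") scale — the truth here is about 0.02K shared of 0.04K per margin.
Gene-level scanning continues with `map_snps_to_genes()` and
`gene_scan()`, whose table carries per-gene multi-trait and per-trait
p-values plus pleiotropic/novel flags; `hypergeometric_enrichment()`
tests the flagged gene list against user-supplied gene sets.

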
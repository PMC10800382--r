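---
title: "Models and methods for shared genetic architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for shared genetic architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## Scope

`pleioscan` dissects the genetic architecture shared by a set of related
complex traits — the motivating application is groups of immune-mediated
diseases — using nothing but per-SNP GWAS summary statistics (z-scores,
alleles, sample sizes) and a reference genotype panel for linkage
disequilibrium (LD).  Three layers of analysis build on one another:

1. **LD score regression** for SNP heritability, confounding-robust
   intercepts, genetic correlations, and annotation-stratified enrichment.
2. **A four-component bivariate causal mixture** quantifying *polygenic
   overlap*: how many causal variants two traits share, as opposed to how
   correlated their effects are.
3. **Adaptive gene-based tests** (SPUs / aSPUs / MTSPUsSet / MTaSPUsSet)
   that aggregate association evidence over the SNPs of a gene and over
   traits, with matrix-normal Monte-Carlo null distributions, and a genome
   scan that classifies genes as pleiotropic.

Every layer is exercised against a synthetic-data generator whose ground
truth is recorded, so calibration and recovery are testable end to end.

## The generative model

Genotypes are standardized to unit variance, so per-SNP effect sizes
\(\beta\) live on the standardized scale and the SNP heritability is
\(h^2 = \sum_j \beta_j^2\).  For a pair of traits the causal architecture
is the four-component mixture

\[(\beta_{1j}, \beta_{2j}) \sim \pi_0\, \delta_0
  + \pi_1\, N(0, \Sigma_1) + \pi_2\, N(0, \Sigma_2)
  + \pi_{12}\, N(0, \Sigma_{12}),\]

where \(\pi_0\) is the fraction of SNPs null for both traits, \(\pi_1,
\pi_2\) the fractions causal for one trait only (diagonal \(\Sigma\)s with
variances \(\sigma_1^2, \sigma_2^2\)), and \(\pi_{12}\) the fraction causal
for both, with effect correlation \(\rho_{12}\) inside the shared
component.  The mixture-implied genetic correlation is

\[r_g = \frac{\pi_{12}\rho_{12}\sigma_1\sigma_2}
  {\sqrt{(\pi_1+\pi_{12})\sigma_1^2\,(\pi_2+\pi_{12})\sigma_2^2}},\]

which is why traits can share many causal variants yet show a modest
\(r_g\): the shared-component correlation is diluted by unique variants
and by \(|\rho_{12}| < 1\).

Observed z-scores follow the standard summary-statistics model
\(z_t = \sqrt{N_t}\, R\, \beta_t + \eta_t\) with noise
\(\eta_t \sim N(0, (1 + N_t a_t) R)\): effects are smeared by the LD
matrix \(R\), the noise is LD-correlated, \(a_t\) is a per-trait
confounding inflation (so the LD score regression intercept targets
\(1 + N_t a_t\)), and a cross-trait noise correlation \(r_0\) models
sample overlap.  The generative form is stated explicitly here because it
is the assumption every estimator below relies on.

### What the generator emulates — and what it does not

`ld_block_structure()` builds block-equicorrelated LD: contiguous blocks
of SNPs share a correlation \(\rho_b\), zero between blocks.  Per-block
correlations can be constant, drawn from a continuous range (giving the
LD-score spread that a regression on LD scores needs), or from a small
discrete set (keeping the number of distinct per-SNP LD profiles small,
which the mixture likelihood exploits).  Real LD is banded and decaying
rather than blocky, has allele-frequency structure, and varies along the
genome; none of that is represented, and effect sizes carry no
MAF-dependence.  Passing tests therefore demonstrate correctness of the
estimators *under their stated model*, not robustness to every feature of
real data.  Case/control traits are treated on the observed scale
throughout; no liability-scale conversion is attempted, and reported
heritabilities are labelled accordingly.

Default study conditions used by the test-suite simulations: `M` = 50,000
SNPs in blocks of 10 for regression-layer checks (20,000 for the mixture
layer, where the likelihood is the bottleneck), sample sizes 20,000 to
50,000, \(h^2\) around 0.3, causal fractions 0.003 to 0.01.  These are
desk-scale versions of a realistic GWAS: large enough for the asymptotics
that the methods rely on, small enough that the entire suite runs in
minutes on one CPU.

## LD score regression

With LD score \(\ell_j = 1 + \sum_{k \ne j} r_{jk}^2\), the univariate
model is \(E[z_j^2] = \text{intercept} + N_j (h^2 / M)\, \ell_j\) and the
bivariate model is \(E[z_{1j} z_{2j}] = \text{cross-intercept} +
\sqrt{N_1 N_2}\,(\text{gcov}/M)\, \ell_j\).  Fitting is two-step weighted
least squares: inverse-LD-score weights first, then weights proportional
to the inverse squared fitted mean (a fixed two-iteration scheme keeps the
estimator deterministic).  Standard errors come from a delete-one block
jackknife over contiguous equal-count SNP blocks (default 200); the
genetic correlation `rg = gcov / sqrt(h2_1 h2_2)` is jackknifed as a full
ratio, re-estimating numerator and denominators on every leave-one-out
subset, and its p-value is two-sided normal on `rg / rg_se`.  No
chi-square cap is applied by default at desk scale (`max_chisq` exists as
an option).  The stratified extension regresses \(z^2\) on per-category LD
scores \(\ell(j, c) = \sum_k r_{jk}^2 a_{kc}\), always appends an all-SNPs
baseline, and reports \(\tau_c\), per-category heritability, enrichment
`(h2_c / h2) / (M_c / M)` and a one-sided coefficient p-value; collinear
category sets fall back to a small documented ridge with a warning.

## The causal-mixture likelihood

The density of a z-score (pair) under the mixture has no closed form once
LD is involved, but its characteristic function is a product of simple
Gaussian factors over LD neighbors, which enter only through their
\(r^2\).  The package therefore summarises each SNP's LD environment as a
binned histogram of neighbor \(r^2\) values (plus the self term), computes

\[\log \varphi(t_1, t_2) = \text{noise term} + \sum_b c_b
  \log\!\big(\pi_0 + \pi_1 g_1 + \pi_2 g_2 + \pi_{12} g_{12}\big),\]

with \(g\)s the component Gaussian factors at bin value \(r^2_b\), and
inverts by 2-D FFT on a symmetric grid (default 128 points per axis,
half-width 15 on the z scale; 256 points univariate).  Negative inversion
ripple is clipped at zero with the clipped mass reported, and an estimated
aliasing mass above \(10^{-3}\) at the grid edge raises an error advising
a wider grid — wide-variance parameter points genuinely need one.  The
inverted density integrates to 1 within \(10^{-3}\) across tested
parameter points and matches a \(10^6\)-draw direct simulation of the same
generative sum to total-variation distance below 0.02.

Fitting is sequential, mirroring common practice and shrinking the search
space: each trait's univariate margin \((\pi_u, \sigma_u^2, \sigma_0^2)\)
is maximised first (Nelder–Mead on log/logistic-transformed coordinates
from a three-point multistart over \(\pi_u \in \{10^{-4}, 10^{-3},
10^{-2}\}\), effect variance initialised from a method-of-moments
heritability), then held fixed while the bivariate stage estimates only
\((\pi_{12}, \rho_{12}, \rho_0)\) with \(\pi_{12} \le \min(\pi_{u1},
\pi_{u2})\) enforced by the parameterisation.  A profile check at the
\(\pi_{12} = 0\) boundary is run after optimisation; boundary solutions
are reported with a flag, not an error, because the boundary breaks
Hessian-based normality — which is also why uncertainty comes from a
parametric bootstrap (default 20 refits on draws from the fitted density)
rather than from second derivatives.  If the optimiser exhausts its
iteration budget it is restarted once from the incumbent; the convergence
code is carried in the result rather than escalated to an error, so long
simulation studies are not aborted by one sluggish replicate.

**Effective variants.** "Number of causal variants" is ill-defined for a
Gaussian effect distribution, so overlap summaries use the effective count
explaining 90% of heritability: with squared effects distributed as
\(\sigma^2 \chi^2_1\), the threshold \(t\) with
\(E[X \mathbf{1}(X>t)]/E[X] = 0.9\) is found by root-finding and
`n90 = pi_c M P(X > t)` (about \(0.445\, \pi_c M\); independent of
\(\sigma^2\)).  The raw count \(\pi_{12} M\) is reported alongside, since
conventions differ between tools; the 90% convention is the headline.
A point-mass alternative (`model = "point"`) gives the \(0.9\,\pi_c M\)
limit.  Overlap counts print on the thousands ("0.21K") scale.

## Conditional Q-Q diagnostics

`conditional_qq()` stratifies one trait's p-values by significance in a
second trait (default thresholds 1, 0.1, 0.01, 0.001) and plots each
stratum against uniform quantiles.  Progressive leftward separation of
stricter strata is the model-free signature of polygenic overlap.  The
scalar shift statistic — median \(-\log_{10} p\) in the strictest
nonempty stratum minus the all-SNPs stratum — is near zero for
independent traits and grows with \(\pi_{12}\); conditioning a trait on
itself bounds it from above.

## Adaptive gene-based tests

For a gene with \(d\) SNPs and \(m\) traits, the statistics are the
powered norms \(\mathrm{SPUs}(\gamma_1; z) = (\sum_j
|z_j|^{\gamma_1})^{1/\gamma_1}\) and
\(\mathrm{MTSPUsSet}(\gamma_1, \gamma_2; Z) = \sum_h
\mathrm{SPUs}(\gamma_1; Z_h)^{\gamma_2}\), over the default grid
\(\Gamma = \{1, 2, 4, 8\}\) for both powers.  Absolute values are taken
inside the norm: odd powers of signed z-scores raise negative bases to
fractional powers, so the powered-norm reading is the only well-defined
default; a signed power-sum compatibility mode exists on `spus()`.  Small
powers aggregate dense diffuse signals, large powers approach the max
statistic and favor sparse strong signals; \(\gamma = \infty\) is
available but off by default.

The null distribution is matrix-normal: \(Z_0 = L_V X L_R^\top\) with
among-SNP covariance \(R\) (panel LD of the gene's SNPs,
eigenvalue-floored at \(10^{-8}\)) and among-trait covariance \(V\),
estimated genome-wide from LD-pruned SNPs with all \(|z| < 2\) (signal
exclusion).  The truncation attenuates correlations by the truncated
second moment of the standard normal, and the estimate is de-attenuated
by that factor — exact as the true correlation goes to zero, adequate for
the moderate correlations the null model needs.

The adaptive combination uses one null bank per gene: each candidate
power's p-value is its \(\ge\)-rank in the bank with the \(+1\)
correction, each draw's own minimum-p over the grid is ranked against the
others, and the adaptive p-value is the rank of the observed minimum —
guaranteeing \(p \in [1/(B+1), 1]\).  Per-trait aSPUs statistics are
ranked against a single shared SPUs null stream (the pre-mixing rows of
the bank, each marginally \(N(0, R)\)), which makes single-trait results
exactly invariant to trait order and costs no extra random numbers.
Replicates escalate in stages (default schedule \(10^3\) to \(10^6\)),
continuing while the smallest p-value is within a factor 5 of the
attainable floor; each stage draws a fresh bank with a stage-offset seed.
Per-gene seeds are a hash of the gene id combined with the master seed,
so scan results are independent of gene order.

A gene is flagged **pleiotropic** when its multi-trait p-value and at
least one single-trait p-value clear the per-test Bonferroni threshold
\(\alpha/G\), and **novel** when additionally absent from a user-supplied
known-association table.

## Numerical and design choices

- Coordinates are 1-based inclusive; a reader flag converts 0-based
  half-open BED.
- Palindromic (A/T, C/G) SNPs are dropped during harmonization rather
  than frequency-resolved: frequency columns cannot be assumed present in
  all inputs, and silent strand errors are worse than lost SNPs.
- Pruning windows are counted in SNPs with the conventional
  `(window step r2)` semantics; on a violating pair the later-position
  SNP is dropped (deterministic tie-break).  Pairs separated by more than
  `window - step` SNPs may never share a scanning window; the pruning
  guarantee is local by construction.
- Missing panel dosages are mean-imputed per SNP before correlation;
  monomorphic panel SNPs are rejected.
- The LD \(r^2\) bias correction `r2 - (1 - r2)/(n - 2)` (floored at 0)
  is off by default and available as a flag for regression use.
- The intersect-then-prune order is prune-the-panel-first, then intersect
  with traits; a config flag could swap this, and at desk scale the
  difference is immaterial.
- Monte-Carlo p-values use \(\ge\) comparisons and \(+1\) corrections
  throughout, so ties and discreteness can never produce an invalid
  (anti-conservative beyond \(1/(B+1)\)) p-value.
- The gene-test SNP count is capped (default 500) with an audit entry;
  pruning to \(r^2 < 0.1\) makes the cap rarely bind.
- Benjamini–Hochberg is the default gene-set adjustment; Bonferroni is
  available.  Display thresholds round to significant figures, not
  decimal places.

## Known limitations

- Observed-scale heritability only; no liability transformation for
  case/control traits.
- More than two traits are handled pairwise in the mixture layer; a full
  \(2^T\)-component model is out of scope.
- The block-LD generator cannot represent long-range decaying LD; the
  mixture likelihood inherits whatever coarseness the r-squared binning
  imposes (per-bin mean r-squared values keep block structures exact).
- Bootstrap standard errors for the bivariate mixture cover only the
  overlap parameters; the fixed univariate margins contribute no spread.
- With a non-exchangeable trait correlation matrix, exchanging traits
  permutes per-trait results exactly but re-orders the Cholesky factor of
  `V`, so multi-trait Monte-Carlo p-values are invariant in distribution
  rather than realization.

## Problem sizes used by the automated checks

The packaged tests simulate at `M` between 1,500 (gene-scan end-to-end,
30 genes, 3 traits) and 50,000 SNPs (regression recovery, 50 replicates),
with Monte-Carlo banks of \(10^3\)–\(10^5\) draws and one \(10^6\)-draw
density oracle; these sizes were chosen so the statistical claims are
sharp (binomial 99% bands, 2-standard-error coverage) while the whole
suite completes in a few minutes on a single core.
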
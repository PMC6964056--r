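---
title: "Dissecting additive, dominance, epistatic and maternal variance with genomic kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting additive, dominance, epistatic and maternal variance with genomic kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvcomp)
```

## The problem

In a population of full- and half-sib families with SNP genotypes, the
phenotypic variance of a trait can be split into additive genetic,
dominance, additive-by-additive epistatic, maternal-environment and
residual components by fitting a multi-kernel GBLUP mixed model:

$$\mathbf{y} = \mathbf{X}\boldsymbol{\beta} + \mathbf{h}b +
  \mathbf{Z}_1\mathbf{a} + \mathbf{Z}_2\mathbf{d} +
  \mathbf{Z}_3\mathbf{e}_{aa} + \mathbf{Z}_4\mathbf{m} + \mathbf{e},$$

with $\mathbf{a} \sim N(0, \mathbf{G}\sigma^2_A)$,
$\mathbf{d} \sim N(0, \mathbf{D}\sigma^2_D)$,
$\mathbf{e}_{aa} \sim N(0, k(\mathbf{G}\#\mathbf{G})\sigma^2_{E_{aa}})$,
$\mathbf{m} \sim N(0, \mathbf{I}\sigma^2_M)$ (one level per dam) and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_E)$. The covariate $\mathbf{h}$ is
each individual's genomic homozygosity (fraction of homozygous loci); its
regression coefficient $b$ measures directional dominance, i.e. inbreeding
depression. This vignette explains the modelling choices in `gvcomp`, the
parameters that matter, and what the synthetic-data generator does and does
not emulate.

## Kernels: HWE versus NOIA parameterization

Both parameterizations use the same additive contrast
$h_a[i,j] = x_{ij} - 2p_j$ (dosage centred at twice the allele frequency).
They differ in the dominance contrasts and in the scaling:

* **HWE** (VanRaden method 1): dominance contrasts
  $(-2p^2,\, 2pq,\, -2q^2)$ for dosage $0/1/2$;
  $\mathbf{G} = \mathbf{H}_a\mathbf{H}_a'/2\sum_j p_j q_j$,
  $\mathbf{D} = \mathbf{H}_d\mathbf{H}_d'/4\sum_j p_j^2 q_j^2$, epistatic
  kernel $\mathbf{G}\#\mathbf{G}$ with $k = 1$. Orthogonality of the
  additive and dominance contrasts holds only if the sample is in
  Hardy-Weinberg equilibrium.
* **NOIA**: dominance contrasts
  $(-2p_1p_2,\, 4p_0p_2,\, -2p_0p_1)/(p_0 + p_2 - (p_0 - p_2)^2)$ built
  from the observed genotype frequencies, which makes them orthogonal to
  the additive contrasts in the analysed sample itself; every kernel is
  divided by its own trace mean, so `mean(diag(K)) == 1` exactly.

A crossbred population — two divergent parent groups mated reciprocally —
has an excess of heterozygotes relative to Hardy-Weinberg proportions, so
the two approaches genuinely differ there. Because the additive contrasts
are shared, any model *without* a dominance term differs between the
approaches only by scalar kernel rescaling, which the variance component
absorbs: the REML log-likelihoods are identical (`gvcomp` tests this to
1e-4). With sample-frequency NOIA kernels the reference-population
(Legarra) factor `mean(diag(V)) - mean(V)` is exactly 1 for the
contrast-built kernels `G` and `D` (the contrast columns sum to zero, so
the grand mean vanishes) and within a few percent of 1 for the Hadamard
epistatic kernels (their grand mean averages squared relationships, so it
is small but strictly positive), so NOIA estimates need essentially no
rescaling; HWE estimates are multiplied by their kernel's factor at
reporting time (`variance_ratios(..., apply_legarra = TRUE)`), never baked
into the stored kernels. For identity-covariance terms (maternal,
residual) the factor is taken as exactly 1. We apply the per-kernel factor
to every fitted kernel, including the epistatic ones — the natural reading
of correcting "each variance component's relationship matrix" — even
though only the additive and dominance cases are usually discussed.

Monomorphic or zero-contrast loci are kept as all-zero columns (with a
warning) instead of being dropped, so the divisors stay consistent with
the declared locus panel. Allele and genotype frequencies always come from
the analysis sample after imputation, pooled over both reciprocal crosses;
injecting external reference frequencies is deliberately not a default.
The frequency-before-or-after-imputation question is unobservable in
practice at a 0.4% missing rate (imputation draws from the observed
genotype frequencies, leaving them essentially unchanged); `gvcomp`
computes them after imputation, once, and uses them everywhere.

## REML engine

`reml_fit()` maximizes the restricted likelihood
$\log L = -\tfrac12(\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| +
\mathbf{y}'\mathbf{P}\mathbf{y})$ (the $n\log 2\pi$ constant is omitted
consistently, so only differences matter) by average-information updates:

* start from an equal split of the phenotypic variance across terms —
  robust for small samples with several competing kernels;
* take the AI step; if it would decrease the likelihood or leave the
  non-negative orthant, halve the step until it does not (30 halvings);
* pin a component to the floor `1e-10 * var(y)` when its update goes
  negative while its gradient points outward (an active-set boundary);
* declare convergence at `|dlogL| < 1e-8` and maximum relative component
  change `< 1e-6`.

Dense algebra throughout: the target is $n \approx 10^3$ individuals,
where a Cholesky factorization costs tens of milliseconds, so no sparse
path is warranted. A `1e-8` diagonal jitter is applied inside the solver
only if a Cholesky fails; stored kernels are never modified. Fixed effects
use full-rank treatment coding with the first level as reference;
rank-deficient designs raise an error naming the confounded columns, and
single-level factors are dropped with a warning. Individuals with missing
response, covariate or fixed-effect values are dropped per trait with a
message.

Standard errors for variance-component ratios use the first-order delta
method with the inverse AI matrix as the component covariance; components
on the zero boundary are treated as fixed, contributing neither variance
nor covariance. The exact standard errors a given REML implementation
reports depend on its internals, so cross-package agreement is expected
only approximately; `gvcomp`'s values are validated against hand-evaluated
gradients instead.

## Model family, testing and selection

`fit_suite()` fits the eight models A, AD, AE, AM, ADE, ADM, AME, ADME
(letters = fitted random terms; residual always present; the homozygosity
covariate is included unless switched off) and compares each sub-model to
the full ADME model. Because the null hypotheses put variance components
on the boundary of the parameter space, the LRT null distribution is the
binomially weighted chi-square mixture
$\sum_k \binom{q}{k} 2^{-q}\, \chi^2_k$ for $q$ omitted components;
`mixture_critical_value()` root-finds the critical value (e.g. 2.71 at
$q = 1, \alpha = 0.05$) and `mixture_pvalue()` gives tail probabilities.
The degrees of freedom are derived programmatically as the number of
variance components the sub-model omits relative to ADME.

Model selection is formalized as *backward elimination from the full
model*: D, E and M are each retained exactly when dropping that term alone
from ADME is rejected at $\alpha = 0.05$ on the one-component mixture.
Publications often describe this choice only through significance stars; a
reproducible pipeline needs an explicit rule. We considered the obvious
alternative — the most parsimonious model whose joint LRT against ADME is
not rejected — but it is less powerful for individual terms and fails to
reproduce typical star-table choices: a sub-model lacking a moderately
significant term can escape rejection on a 2-d.f. joint test even when the
1-d.f. single-term drop is clearly significant. Backward elimination
reproduces the star-table logic term by term.
Additive-by-dominance and dominance-by-dominance kernels are available as
optional model-code suffixes (`"ADME+ad+dd"`) but excluded from the
standard suite and from selection. `fullsib_excess_variance()` gives the
expected within-full-sib-family variance excess
$\tfrac14\sigma^2_D + \tfrac18\sigma^2_{E_{aa}} + \tfrac18\sigma^2_{E_{ad}}
+ \tfrac18\sigma^2_{E_{dd}}$ for interpreting non-additive estimates.

## Inbreeding depression

`depression_summary()` reports the regression coefficient $b$ (trait units
per unit homozygosity), the relative depression $b_R = -b/\bar{y}$ with
$\bar{y}$ the raw phenotypic mean (before fixed-effect adjustment, which
matches how the per-trait population averages are usually tabulated), the
5th and 95th empirical homozygosity percentiles, and the tail-to-tail
performance difference $|b| \cdot (q_{95} - q_{05})$. Quantiles use linear
interpolation between order statistics (R's default type 7) — a
convention choice the summary makes explicit, since the source analyses
do not state one.

## The synthetic-data generator

No real genotype data are distributed, so `simulate_dataset()` generates
populations with the statistical structure the analysis assumes:

* **Founders** — two groups, per-locus allele frequencies drawn
  independently per group from Beta(3, 3). Independent draws make the
  groups divergent, so the crossbred offspring show a heterozygote excess
  and genuinely depart from HWE — the condition separating NOIA from HWE
  kernels. Configurable per-group Beta laws allow stronger divergence.
* **Design** — reciprocal partial factorial: group-A sires x group-B dams
  and vice versa, each sire mated to 2 dams in a chain so every parent
  appears in at least two full-sib families (offspring have both full- and
  half-sibs). Defaults: 20 sires + 20 dams per group, 80 families, family
  sizes from a negative binomial (mean 15, size 2) truncated at 1 to mimic
  a realistically unbalanced hatchery design, about 1150 phenotyped
  offspring.
* **Genotypes** — gene-dropped from founder haplotypes (Mendelian sampling
  per locus), 2000 independent loci, 0.4% of calls masked as missing.
  Independent loci are a stand-in: no linkage map is modelled, so LD
  structure of real data is *not* emulated.
* **Trait** — additive, dominance and epistatic effect vectors are built
  in the NOIA contrast basis of the offspring sample (per-locus effects;
  500 locus pairs for epistasis) and rescaled so realized variances hit
  the configured components exactly; one maternal effect per dam; normal
  residual; fixed effects for reciprocal cross (2 levels), batch (3), day
  (8) and filleter (3). Directional dominance is a mean decline of
  $\delta$ trait units per unit homozygosity — equivalently a common
  positive dominance effect across heterozygous loci — giving inbreeding
  depression while dominance *variance* stays at its small configured
  value: the "infinitesimal dominance" regime in which depression exists
  without detectable $\sigma^2_D$.

Default true components $(\sigma^2_A, \sigma^2_D, \sigma^2_{E_{aa}},
\sigma^2_M, \sigma^2_E) = (0.10, 0.01, 0.15, 0.09, 0.65)$ put the ratios
at $h^2 = 0.10$, $m^2 = 0.09$, $e^2_{aa} = 0.15$, and $\delta = 6.5$ with
intercept 10 makes $b_R \approx 1$. All randomness flows from a single
seed recorded in the run manifest.

Passing recovery tests on these data show that the estimator is consistent
with its own model assumptions at desk scale; they cannot show robustness
to LD, genotyping artefacts, selection, or non-normal residuals, none of
which the generator produces.

## Numerical and scale choices

* Problem sizes in the test suite: unit tests run on ~200 offspring and
  300 loci; the end-to-end recovery experiment uses the default design
  (~1150 offspring, 2000 loci) with 20 replicates — enough for stable
  empirical 95% bands while keeping a full run in minutes on one core.
* Mixture root-finding brackets $[0, 200]$ with `uniroot` at `tol = 1e-10`,
  well beyond the two decimals typically printed.
* The GCTA binary GRM writer stores the lower triangle in single
  precision; round-trips are therefore exact only to ~1e-7 relative.
* Pedigree relationship matrices use the tabular method with non-inbred
  founders; they are provided for comparison against genomic estimates,
  not as a fitting default.

## Limitations

* Single-trait models only; no genotype-by-environment terms, no
  marker-effect (SNP-BLUP) models, no pedigree-genomic blending.
* The AI-REML solver is dense ($O(n^3)$ per iteration); it is not intended
  for tens of thousands of individuals.
* Standard errors are asymptotic (delta method on the AI matrix) and known
  to be optimistic near boundaries.
* The simulator's independent-locus gene dropping omits LD and selection.
* Power at desk scale is limited: with ~80 families, ~1150 offspring and
  2000 SNPs, the one-component drop test detects a maternal ratio of 0.09
  in roughly half of replicates and an epistatic ratio of 0.15 in roughly a
  third — the Hadamard-square kernel carries little information at this
  panel size, and that remains true even when the simulated architecture
  matches the fitted kernels exactly. Estimates are unbiased (recovery
  bands cover the truth); individual-term *detection* at these effect sizes
  simply needs more data than a desk-scale design provides.

## A short tour

```{r tour, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)

g <- impute_missing(sim$genotypes, seed = 1)
g_off <- genotype_matrix(unclass(g)[sim$phenotypes$id, ])
kernels <- suite_kernels(g_off, approach = "noia")

pheno <- sim$phenotypes
pheno$homozygosity <- individual_homozygosity(g_off)

suite <- fit_suite(pheno, kernels,
                   fixed = c("cross", "batch", "day", "filleter"))
tidy(suite)                         # logL, LRT, mixture p-values, stars
variance_ratios(suite$fits$ADME)    # corrected components and ratios
depression_summary(suite$fits$ADME, pheno$homozygosity, pheno$trait)
autoplot(suite)                     # stacked variance decomposition
```
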
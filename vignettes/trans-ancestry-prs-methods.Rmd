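---
title: "Methods: trans-ancestry PRS evaluation and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-ancestry PRS evaluation and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`transprs` evaluates a polygenic risk score (PRS) for a binary disease across
ancestrally diverse cohorts and calibrates it so that a single risk cutoff is
meaningful for every individual, regardless of genetic ancestry. The package
covers six analysis stages — scoring, ancestry inference, post hoc score
adjustment, performance metrics, meta-analysis, and effect-size concordance —
plus a synthetic multi-ancestry data generator that gives every stage a
testable ground truth. It does not construct PRS weights: any weight table
(e.g. a PGS Catalog scoring file produced by Bayesian shrinkage methods)
is consumed as input.

# The synthetic-data generator

## Allele-frequency divergence

Populations diverge from a common ancestral frequency pool under the
Balding–Nichols model: for a variant with ancestral frequency $p$ and
divergence $F$ (the FST parameter), the population-specific frequency is drawn
from $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, and
genotypes are $\mathrm{Binomial}(2, p_{pop})$. This is the standard
FST-parameterized divergence model; it produces populations that are separable
by principal components, which is all the downstream machinery requires.
$F = 0$ and $F = 1$ are rejected (the Beta degenerates). Ancestral frequencies
are uniform on 0.05–0.5 by default so that a 1% MAF filter rarely binds;
the range is configurable.

Admixed individuals are modeled at the allele-frequency level: each variant's
frequency is the mixture $\sum_k w_k\,p_k$ of the parental population
frequencies. This places admixed samples between the parental centroids in PC
space — sufficient for testing projection and adjustment — but does not
produce local-ancestry tracts; analyses that depend on tract structure are
out of scope.

Linkage disequilibrium is emulated only by an optional variant-copying knob
(`n_ld_copies`, `ld_copy_r`): a copy shares each of its two alleles with the
source variant with probability $r$, giving dosage correlation $\approx r$
and squared correlation $\approx r^2$. That is enough to exercise LD pruning
and tag-variant search; there is no coalescent or haplotype structure, so
passing tests say nothing about performance under realistic fine-scale LD.

## Disease model

Disease arises from a liability-threshold model. The genetic score
$g_i = \sum_j w_j d_{ij}$ (weights $w_j \sim N(0,1)$ on `n_causal` variants)
is standardized *within each population*, scaled to variance $h^2$
(`liability_h2`), and combined with independent Gaussian noise of variance
$1-h^2$. A sample is a case iff its liability exceeds $\Phi^{-1}(1-K)$, with
$K$ the population-specific prevalence. Standardizing within population makes
the realized prevalence match the configured $K$ in every population while
the *raw* PRS (weights acting on unstandardized dosages) still shifts across
populations when $F > 0$ — exactly the phenomenon the post hoc adjustment is
designed to remove. The shipped prevalence registry carries diagnosed-T2D
values from the literature: European 10.0%, African 12.5%, Hispanic 13.1%,
Asian 13.7%.

Covariates (age, sex, site) are generated independent of genotype by default;
`confound_site = TRUE` ties site to population to let users probe covariate
adjustment. GWAS summary statistics add per-variant Gaussian noise with
$SE = 1/\sqrt{2Np(1-p)}$ to the true effects; a `effect_correlation`
parameter ($\rho$) draws each population's true effects as
$\rho w + \sqrt{1-\rho^2}\,\varepsilon$, because cross-population effect-size
architecture is an empirical unknown that the generator should expose rather
than assert.

# Scoring

Scores are $\sum_j w_j d_{ij}$ over variants matched on
(chromosome, position, unordered allele pair); positions are 1-based
throughout. A swapped effect/other orientation is scored on the reversed
dosage $2-d$, so the counted allele is always the weight's effect allele and
`(A,B,w)` versus `(B,A,-w)` give identical scores up to a constant offset
(rank-invariant). Strand-ambiguous pairs (A/T, C/G) are dropped by default —
without strand metadata their orientation is unresolvable — and can be kept
by flag. Missing dosages are imputed as twice the effect-allele frequency,
matching the default of the standard scoring tools; `impute_missing = FALSE`
makes them contribute zero instead. Multi-allelic records are dropped with a
count.

# Ancestry inference

LD pruning is greedy and windowed (defaults 500/50/0.05, in variant counts):
within each window, while any pair exceeds the $r^2$ ceiling, the lower-MAF
member of the worst pair is removed (tie: later position). PCA standardizes
each variant by mean $2p$ and scale $\sqrt{2p(1-p)}$ and stores loadings plus
the standardization constants, so targets are projected with reference-panel
constants; absent or missing variants contribute the standardized mean
(zero), with a configurable 50% minimum variant overlap. Component signs are
fixed deterministically (largest-magnitude loading positive) so downstream
regression coefficients are reproducible across runs.

Population assignment uses a class-conditional probabilistic classifier over
the top PCs (default 6) with an abstention threshold (default 0.8). The
density is a multivariate Student-t with 4 degrees of freedom rather than a
Gaussian, a deliberate design choice: with Gaussian tails, a sample far from
*every* class — an admixed individual, say — still receives a posterior near
1 for whichever class is marginally closer, because the log likelihood ratio
grows with the squared distance difference. Heavy tails make that ratio
polynomial, so far-from-everything samples keep intermediate posteriors and
abstain, while samples inside a cluster are still assigned with posterior
$\approx 1$. Means, covariances (ridge-regularized) and class-frequency
priors are estimated from the labeled reference scores.

# Post hoc ancestry adjustment

The raw score's mean and variance are modeled as linear functions of the top
5 reference-panel PCs:
$$PRS \sim \alpha_0 + \textstyle\sum_{k=1}^{5} \alpha_k PC_k,
\qquad \delta \sim \beta_0 + \textstyle\sum_{k=1}^{5} \beta_k PC_k,$$
where $\delta$ is the squared residual of the first regression — the natural
operationalization of "residual variance" as a per-sample quantity; a
log-link variant would guarantee positivity but changes the functional form,
so the linear form is the default and negative fitted variances are floored
at $10^{-6}\,\mathrm{Var}(\text{reference scores})$ with a logged count.
Any individual projected into the same PC space is then standardized:
$$PRS_{adj} = \frac{PRS_{raw} - (\hat\alpha_0 + \sum_k \hat\alpha_k PC_k)}
{\sqrt{\hat\beta_0 + \sum_k \hat\beta_k PC_k}}.$$
The model is fitted on the full reference panel (not per-population subsets)
on raw, uncentered scores; the convention and a fingerprint of the PC space
are stored in the saved model, and adjustment refuses to run against PCs from
a different model. Within fixed PC coordinates the transform is affine, so
ranks are preserved.

# Evaluation metrics

* **Liability-scale $R^2$**: incremental $R^2$ of a linear model of 0/1
  status on covariates + score over covariates alone, multiplied by
  $C = K^2(1-K)^2 / (z^2 P(1-P))$ with $z$ the normal density at
  $\Phi^{-1}(1-K)$ and $P$ the sample case fraction. The linear
  (observed-scale) incremental $R^2$ is the conventional pairing with this
  ascertainment correction. At $K = P = 0.5$ the factor is exactly $\pi/2$.
* **AUCs**: the rank (Mann–Whitney) statistic, ties counted one half. The
  "PRS adjusting for covariates" AUC is computed on the score residualized
  on the covariates by least squares — the most common reading; the
  computation is isolated so an alternative covariate-specific-threshold ROC
  could be swapped in.
* **OR/SD**: covariate-adjusted logistic regression on the within-sample
  standardized score; Wald 95% CIs throughout (matching the symmetric
  intervals conventionally printed), with a separation heuristic flagging
  unreliable CIs.
* **Tail metrics**: top 2/5/10% indicators at the empirical percentile (ties
  enter the top group; realized group size reported), covariate-adjusted OR,
  sensitivity/specificity from the raw cross-tabulation, and
  prevalence-adjusted predictive values
  $PPV = \frac{sens \cdot prev}{sens \cdot prev + (1-spec)(1-prev)}$,
  $NPV = \frac{spec\,(1-prev)}{spec\,(1-prev) + (1-sens)\,prev}$
  evaluated at the registry prevalence rather than the ascertained sample
  case fraction.
* **Decile calibration**: samples ranked by the score, split into 10 groups
  whose sizes differ by at most one; per decile the mean predicted
  probability and observed case fraction.

# Meta-analysis and concordance

Study estimates combine by inverse-variance weighting
($w_i = 1/se_i^2$; combined SE $= 1/\sqrt{\sum w_i}$), the scheme stated for
the cohort-level OR meta-analysis and assumed for the variant-level
fixed-effect meta-analysis (the weighting scheme at variant level is not
specified by convention; IVW is the default in standard tools). Cochran's Q
and $I^2$ are reported but never used for filtering. Lead variants are
extracted greedily by minimum p-value with a 500 kb exclusion window on each
side — "locus" has no universal definition, so the window is prominently
configurable. When a lead is absent from a population's summary table, the
best LD proxy with $r^2 \ge 0.6$ within the locus window substitutes for it;
tag substitution attenuates the measured concordance, so reported
correlations of $|\beta|$ are conservative.

# Numerical choices and degenerate inputs

Monomorphic variants are dropped from GWAS simulation (undefined SE) and
from PCA (zero variance), always with counts. Frequencies from the
Balding–Nichols draw are clamped to $[10^{-4}, 1-10^{-4}]$ to avoid exactly
monomorphic panels. `ppv_npv` raises a defined error on zero denominators
rather than returning NaN. Percentile ties are resolved by including all tied
samples in the top group. The adjustment refuses constant scores (degenerate
variance regression) and rank-deficient PC matrices.

# Problem sizes and what the tests show

The test suite and the demo pipeline run at deliberately modest scale —
2,000–10,000 variants, cohorts of 650–20,000 samples, three populations with
$F$ around 0.1 — chosen so the whole suite completes in a few minutes while
keeping every statistical check well-powered at its stated tolerance
(binomial/Wald standard errors at each $n$ were the sizing criterion).
Synthetic cohorts have no realistic LD, no genotyping error, no missingness
beyond what tests inject, and population structure far cleaner than real
biobanks; green tests therefore demonstrate correctness of the statistical
machinery, not real-data performance of any particular score.

# Known limitations

Incident-case (survival) evaluation is out of scope, as are local-ancestry
resolved adjustment, recalibration of absolute risk probabilities, BGEN /
PLINK-binary readers, and uncertainty quantification for extreme-percentile
cutoffs. The classifier contract is "probabilistic classifier with
abstention"; the shipped default is chosen for determinism and robustness,
not as the only valid choice.
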
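---
title: "Detecting variance QTLs: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variance QTLs: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlscan)
```

## Why test variances

A regression that omits an interaction term does not just lose power for
the interaction — it leaves a fingerprint in the *variance* of the trait.
If a trait obeys

$$Y_j = \beta_1 g_{1j} + \beta_2 g_{2j} + \beta_{INT}\, g_{1j} g_{2j} + \varepsilon_j$$

and the partner $g_2$ (another locus, or an environmental exposure) is
unobserved, then conditional on the observed locus $g_1$ the trait
variance is

$$\mathrm{Var}(Y \mid g_1) = (\beta_2 + \beta_{INT}\, g_1)^2\,
\mathrm{Var}(g_2) + \sigma^2_\varepsilon,$$

which changes with $g_1$ whenever $\beta_{INT} \neq 0$.  A locus with
this signature is a variance QTL (vQTL).  Screening a genome for vQTLs
first, then running explicit product-term regressions only on the hits,
collapses millions of candidate interaction tests into a few hundred.

Note the converse is not exact: variance heterogeneity can also arise
from scale artefacts, mean-variance coupling in skewed traits, or
epistatic architectures more complex than a single product term.  The
direct GxE/GxG confirmation step exists precisely because the screen is
a necessary-but-not-sufficient signal.

## The common preprocessing step

All five tests consume the same preprocessed quantities.  For each
variant, `residualize()` regresses the trait on an intercept, two
genotype-group indicator variables (so the variant's own mean effect is
removed without assuming additivity) and all covariates, by OLS.  A
large main effect would otherwise masquerade as variance heterogeneity;
removing it, and the covariates, in one projection means every
downstream test sees mean-centred residuals $e_{ij}$ ($i$ = genotype
group, $j$ = individual).  Missing data are removed listwise first.
Only hard calls 0/1/2 are accepted: the group medians that the
deviation-based tests need are undefined for fractional dosages, so
dosage input is rejected rather than silently rounded.

`group_median_deviations()` then forms
$D_{ij} = |e_{ij} - \tilde e_i|$, the absolute deviation from the
genotype-group median.  The median (not the mean) makes the measure
resistant to outliers; the absolute value makes location tests applied
to $D$ respond to spread.  Signed deviations would have median zero in
every group by construction and would test location, not dispersion —
this is why the absolute value is part of the definition here, matching
the Levene/Brown-Forsythe tradition and the deviation-regression
literature.

## The five tests

* **KW** — Kruskal-Wallis on the $D_{ij}$: ranks are taken jointly
  across all samples (average ranks on ties; the tie correction is
  implicit in computing the rank variance from realised ranks), and
  the between-group rank dispersion is referred to $\chi^2_{M-1}$.
  Fully non-parametric in the deviations.
* **BF** — Brown-Forsythe: the one-way ANOVA F statistic on the
  $D_{ij}$ with genotype treated as a 3-level factor, on
  $(M-1, N-M)$ df.
* **DRM** — deviation regression: OLS of $D_{ij}$ on the allele count
  $0/1/2$ treated as continuous, two-sided t test on the slope.  Using
  one continuous predictor instead of group contrasts avoids the
  small-group sparsity that destabilises BF at low MAF.
* **DGLM** — a double GLM: mean submodel
  $e_j = \alpha + \beta x_j + \varepsilon_j$ with observation variances
  $\sigma^2_j$, dispersion submodel
  $\log \sigma^2_j = \gamma_0 + \gamma_1 x_j$.  Fitting alternates
  weighted least squares for the mean (weights $1/\hat\sigma^2_j$) with
  a gamma log-link GLM on the squared residuals (prior weight $1/2$,
  because $e^2 \sim \sigma^2 \chi^2_1$ is gamma with shape $1/2$).  The
  report is a Wald z test of $\gamma_1 = 0$.  The `DGLM_INT` variant
  first maps the residuals through the rank-based inverse-normal
  transformation.
* **QUAIL** — quantile-integral model: the estimand is
  $\beta_{QI} = \int_0^{0.5} (\beta_{1-\tau} - \beta_\tau)\, d\tau$, the
  integrated gap between upper- and lower-quantile regression slopes,
  estimated by a midpoint rectangle rule on $K$ equal bins of $(0,0.5)$
  ($\tau_k = k/2K - 1/4K$, width $1/2K$).

### Decisions that were genuinely open

**DGLM inference.**  Wald z on $\gamma_1$ rather than a likelihood-ratio
test: it matches the summary convention of standard double-GLM software,
costs nothing extra, and is asymptotically equivalent under the null at
the sample sizes where DGLM is trustworthy anyway.  Squared residuals
are floored at $10^{-10}\,\mathrm{Var}(e)$ before the log-link fit
(exact zeros would break the link), and convergence is declared at
relative dispersion-deviance change below $10^{-8}$ (at most 50
sweeps).  The Wald covariance is $2\,(Z^{\top}Z)^{-1}$ — the gamma-GLM
information with shape $1/2$, equivalently dispersion 1 with prior
weight $1/2$ — which reproduces the classical
$\mathrm{Var}(\log s^2) \approx 2/n$ per group and is verified by null
calibration and parameter-recovery tests.

**QUAIL inference.**  Fitting $2K$ quantile regressions per variant is
what makes the estimator expensive; genome-wide that cost is
prohibitive.  The p-value therefore comes from an integrated rank-score
construction: each sample gets the score
$\eta_j = K^{-1}\sum_k [\psi_{1-\tau_k}(e_j) - \psi_{\tau_k}(e_j)]$ with
$\psi_\tau(e) = \tau - 1\{e \le \hat Q_\tau\}$ and $\hat Q_\tau$ the
lower (type-1) marginal sample quantile — a sample sits high on $\eta$
when it falls outside the central quantile band — and the OLS slope of
$\eta$ on allele count is t-tested.  The per-quantile regressions are
kept only for the $\hat\beta_{QI}$ point estimate and can be switched
off (`estimate_effect = FALSE`) in scans and simulation loops.
Covariates are not re-fitted inside the quantile models: the
preprocessing projection already removed them.  Because this two-step
inference is not identical to the original implementation's machinery,
power comparisons involving QUAIL should be read as properties of this
construction; in our desk-scale experiments it is well calibrated under
all three error laws and competitive in power, and it is excluded from
default benchmark suites on cost grounds, not validity.

**INT convention.**  The rank-based inverse-normal transformation uses
the Blom offset, $\Phi^{-1}((r - 3/8)/(N + 1/4))$ with average ranks on
ties — the convention prevalent in GWAS phenotype preparation.

**Median convention.**  The sample median is the midpoint of the two
central order statistics for even group sizes.  A numerical
consequence: the two central observations of an even group are
mathematically equidistant from that median, but floating point can
leave their deviations one ulp apart, so rank-based statistics can be
perturbed in the 4th significant digit relative to an implementation
that rounds first.  This is far below any decision threshold and is
left untreated.

## The simulation design

`sim_scenario()` + `simulate_trait()` generate the two-locus model
above.  Both loci are independent Binomial(2, MAF) draws
(Hardy-Weinberg), and the error is drawn from one of three laws —
standard normal, Student t with 3 df (kurtotic), chi-square with 6 df
(right-skewed, the shape of lipid-like traits) — then z-scored to
sample mean 0 and SD 1 (with the $n-1$ SD) per replicate, so the
variance fraction explained by the genetic terms is constant across
error laws.  The reference conditions mirror the published design this
harness emulates: main effects $\beta_1 = \beta_2 = 0.3$ (or both 0),
interaction $\beta_{INT} = 0.3$ for power and $0$ for null calibration,
SNP1 MAF on the grid $\{0.1, 0.2, 0.3, 0.4\}$.

What the generator does **not** emulate: linkage disequilibrium between
the two loci, real allele-frequency spectra for the partner locus
(a single configurable MAF stands in for a panel of real variants),
relatedness, population structure, genotyping error, and missingness.
Passing calibration and power checks on this generator therefore
demonstrates correctness of the statistics under the stated sampling
model, not robustness to cohort pathologies that upstream QC is
supposed to remove.

Problem sizes are deliberately desk-scale: cohorts of 2,000 (null
calibration) and 5,000 (power) with 1,000–8,000 replicates, and a
power threshold of $10^{-3}$ standing in for genome-wide
$5\times10^{-8}$ at biobank cohort sizes.  These are the package's
default study conditions; the full-scale settings remain plain
function arguments.

## What the calibration experiments show

With normal errors every method holds the nominal false-positive rate.
With t(3 df) errors, DGLM's gamma model for squared residuals is
grossly anti-conservative already at $\alpha = 0.05$; the INT variant
repairs it.  BF's miscalibration under kurtosis is a *tail*
phenomenon — at $\alpha = 0.05$ it looks fine, while at
$\alpha = 10^{-2}$–$10^{-3}$ (the region that matters for genome-wide
thresholds) its false-positive rate runs several-fold above nominal at
MAF 0.1, where the minor-homozygote group is sparse.  KW and DRM stay
calibrated in the tail.  With chi-square(6 df) errors both DGLM
variants are invalid — INT normalises margins, not the mean-variance
coupling of a skewed law — and KW shows the slight liberality expected
of rank tests under skew.  For power: DGLM is the strongest test when
errors really are normal; KW is the strongest validly-calibrated test
in the default suite under heavy tails; power rises with the tested
locus' MAF (the interaction's variance share grows with
$\mathrm{Var}(g_1)$) and is no worse with main effects present than
absent.  These statements are exactly what the package's acceptance
tests assert, and `scripts/acceptance.R` recomputes the underlying
numbers from scratch.

## Follow-up interaction regressions

`clump()` reduces correlated hits to lead variants by greedy selection
in ascending-p order (ties broken lexicographically by id), keeping a
variant only if its allele-count $r^2$ with every kept lead is below
the threshold (default 0.01).  No physical window or secondary
threshold is applied — vQTL hit lists are short enough that marginal
$r^2$ suffices.

`gxe_scan()` and `gxg_scan()` fit the explicit product-term OLS models
on the *raw* trait (covariates inside the model, preserving the
main/interaction hierarchy): every environmental factor enters each
model as a main effect, one partner at a time carries the product term,
and ancestry PCs ride along as plain covariates.  Outputs carry raw
two-sided p-values — with 30 vQTLs and 7 environments that is exactly
$30 \times 7 = 210$ GxE and $\binom{30}{2} = 435$ GxG fits, and the
user applies whatever multiplicity correction fits their design.  The
signed display value is $\mathrm{sign}(\hat\beta_{INT}\,\hat\beta_g)
\cdot (-\log_{10} p)$: positive when the partner pushes the genetic
effect further from zero (exacerbation), negative when it attenuates —
a formulation that extends the usual "red = exacerbates" heat-map
convention to negative main effects.  The same-model $\hat\beta_g$ is
used for the sign; a marginal GWAS effect would be an equally
defensible choice, but the same-model coefficient keeps the product and
main effect on one scale.

## Known limitations

* Hard calls only; no dosage or BGEN/VCF input.
* No mixed-model adjustment for relatedness; the package assumes
  unrelated samples (kinship pruning is upstream QC).
* Rare variants (MAF below the scan filter, default 0.05) are excluded
  rather than specially handled; interaction findings at low MAF rarely
  replicate and the group-based tests are exactly where sparsity hurts.
* The QUAIL p-value machinery is the integrated rank-score
  construction described above, not a re-implementation of the original
  two-stage code path; its $\hat\beta_{QI}$ estimand is identical.
* `estimate_fpr()`/`estimate_power()` run serially; replicate seeds are
  pre-drawn from the scenario seed, so a parallel driver that respects
  the seed-per-replicate contract will reproduce the serial results.

## A minimal worked example

```{r example, eval = FALSE}
sc <- sim_scenario(n_samples = 2000, maf1 = 0.3, beta_int = 0.3, seed = 1)
set.seed(1)
g1 <- simulate_genotypes(2000, 0.3)
g2 <- simulate_genotypes(2000, 0.3)
y  <- simulate_trait(g1, g2, sc)

res <- residualize(y, g1)
dev <- group_median_deviations(res)
kw_test(dev)
dglm_test(res)
```
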
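# vqtlscan

Variance-QTL detection for quantitative traits: five dispersion test
statistics on covariate-adjusted residuals, a Monte Carlo
calibration/power harness, and the follow-up direct GxE / GxG
interaction regressions.

## The problem

A variant whose genotype groups differ in phenotypic **variance** (a
variance QTL, vQTL) is a fingerprint of an interaction whose partner was
never measured: if

    Y = b1*g1 + b2*g2 + bINT*g1*g2 + e

and `g2` (a second locus, or an exposure) is unobserved, then
`Var(Y | g1) = (b2 + bINT*g1)^2 * Var(g2) + Var(e)` varies with `g1`
whenever `bINT != 0`.  Screening for vQTLs first and then running
explicit product-term regressions only on the hits reduces millions of
candidate interaction tests to a few hundred.  The intended users are
statistical-genetics analysts with genotype hard calls (PLINK
`.bed/.bim/.fam` or a 0/1/2 text matrix) and a quantitative phenotype.

## Methods

Every test operates on residuals from regressing the trait on two
genotype-indicator variables and the covariates (`residualize()`), and
most on the absolute deviations from genotype-group medians
`D_ij = |e_ij - median_i|` (`group_median_deviations()`):

| tag | statistic |
|-----|-----------|
| `KW` | Kruskal-Wallis chi-square on jointly ranked `D_ij` (df `M-1`) |
| `BF` | Brown-Forsythe one-way F on `D_ij`, genotype categorical (df `M-1, N-M`) |
| `DRM` | t test of the OLS slope of `D_ij` on allele count 0/1/2 |
| `DGLM` | double GLM: mean model + gamma log-link dispersion model `log sigma^2 = g0 + g1*count`; Wald z on `g1` |
| `DGLM_INT` | DGLM after rank-based inverse-normal transformation |
| `QUAIL` | quantile-integral effect `beta_QI = integral over (0,0.5) of (beta_{1-tau} - beta_tau) d tau`, midpoint rule on K bins; integrated rank-score p-value |

`estimate_fpr()` / `estimate_power()` replay the full
simulate-residualize-test pipeline under a configurable two-locus design
(`sim_scenario()`) with normal, t(3 df) or chi-square(6 df) errors,
z-scored per replicate.  `clump()` performs greedy r² lead selection,
and `gxe_scan()` / `gxg_scan()` fit the confirmatory product-term
regressions with signed `-log10(p)` matrices
(`interaction_matrix()`).  See the vignette
(`vignettes/vqtl-methods.Rmd`) for the models, assumptions and design
decisions.

## Worked example

A cohort of 5,000 with a hidden interaction partner
(`b1 = b2 = 0.3`, `bINT = 0.5`, both MAFs 0.3):

```r
library(vqtlscan)
sc <- sim_scenario(n_samples = 5000, maf1 = 0.3, beta1 = 0.3, beta2 = 0.3,
                   beta_int = 0.5, seed = 1)
set.seed(1)
g1 <- simulate_genotypes(5000, 0.3)
g2 <- simulate_genotypes(5000, 0.3)
y  <- simulate_trait(g1, g2, sc)            # g2 is now "forgotten"

res <- residualize(y, g1)
dev <- group_median_deviations(res)
kw_test(dev)
#> vQTL test: KW
#>   statistic = 15.3207 on df = 2
#>   p-value   = 0.0004712
#>   group n   = n0=2506 n1=2011 n2=483
dglm_test(res)
#> vQTL test: DGLM
#>   statistic = 6.0526 on df = 1
#>   effect    = 0.183729 (se 0.03036)
#>   p-value   = 1.425e-09
#>   group n   = n0=2506 n1=2011 n2=483
round(tapply(res$values, res$group, var), 3)
#>     0     1     2
#> 1.056 1.246 1.562
```

Both tests flag the locus even though the partner `g2` never enters the
model: the residual variance climbs from 1.06 (zero minor alleles) to
1.56 (two), and the DGLM `effect` of 0.18 estimates the per-allele slope
of the log residual variance.  File-based scans run through
`scan_config()` + `run_scan()`, or the CLI:

```sh
inst/cli/vqtlscan scan --genotype cohort --phenotype pheno.tsv \
    --covariates covar.tsv --method KW --out myscan
```

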
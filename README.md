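# mixwas

Phenotype subtype discovery and genetic heterogeneity testing for
multi-trait cohort studies.

## The problem

Many complex diseases and traits hide biologically distinct subtypes —
groups of people in whom different genes, pathways, or treatments matter.
Off-the-shelf clustering (k-means, Gaussian mixtures) finds *descriptive*
subgroups in any dataset, but those subgroups are routinely confounded by
covariates and population structure, and naive downstream tests of
"subtype-specific effects" are badly miscalibrated. `mixwas` is for
statistical geneticists and epidemiologists who want subtypes that survive
formal validation: it (1) learns subtypes with a model that adjusts for
covariates while clustering, and (2) tests whether SNPs, polygenic signal,
or interventions truly act differently across the learned subtypes, with
calibrated p-values.

## The model

**Step 1** fits a multi-trait finite mixture of regressions (MFMR) by
Expectation Conditional-Maximization. For sample *i* with latent subtype
*z<sub>i</sub>* ~ Categorical(*p*), quantitative trait *p*:

&nbsp;&nbsp;&nbsp;&nbsp;*y<sub>ip</sub>* = *X<sub>i</sub>* α<sub>p</sub> + *G<sub>i</sub>* β<sub>z<sub>i</sub>,p</sub> + ε<sub>ip</sub>,&nbsp;&nbsp;ε<sub>ip</sub> ~ N(0, σ²<sub>z<sub>i</sub>,p</sub>)

Covariates in *X* have effects shared across subtypes; covariates in *G*
(whose intercept column carries the subtype main effects γ) have per-subtype
effects. Binary traits use probit links, conditionally independent given the
subtype.

**Step 2** regresses each trait on a focal covariate *g* and its interaction
with the membership probabilities,

&nbsp;&nbsp;&nbsp;&nbsp;*y* ~ *X̃*α + *z*γ + *g*δ + (*g·z*)β + ε,

and tests homogeneity (δ, 1 df), heterogeneity (β, K−1 df), or both
(global, K df). Genome-wide scans report genomic-control λ. A polygenic
analog fits V = σ²<sub>hom</sub>K + σ²<sub>het</sub>(K∘ZZᵀ) + σ²<sub>e</sub>I
by AI-REML, partitioning heritability into homogeneous and subtype-specific
parts with a Wald test for total genetic variance and a boundary-aware LRT
for the subtype-specific component.

The package also includes comparator subtype estimators (GMM, CCA and PC
scores), MVN and low-rank phenotype imputation, PLINK/TSV readers and
writers, and a simulator reproducing the full battery of calibration worlds
(correlated and t₅ noise, non-linear SNP effects, continuous subtypes,
case/control ascertainment, gene–environment correlation, Balding–Nichols
population structure).

## Worked example

```r
library(mixwas)

## one baseline world: 2,000 samples, 2 true subtypes, 27 quantitative +
## 3 binary traits, 12 SNPs (4 null / 4 homogeneous / 4 heterogeneous)
ds  <- make_scenario("baseline_k2", overrides = list(n_samples = 2000), seed = 7)
fit <- fit_mfmr(ds$traits, ds$covariates, opts = mfmr_opts(K = 2, seed = 1))
fit
#> mfmr_fit: K=2, loglik=-73448.83, converged
#> mixing proportions: 0.500 0.500

adjusted_rand_index(fit$labels, ds$z_true)
#> [1] 0.98009

## step 2: test a heterogeneous-by-construction SNP across all 27
## quantitative traits (one QR shared across traits)
het_snp <- which(ds$snp_roles == "het")[1]
res <- interaction_test_multi(ds$traits$quant, ds$genotypes[, het_snp], fit$Z,
                              background = ds$covariates$homogeneous[, -het_snp],
                              mode = "heterogeneity")
head(res[order(res$p), ], 3)
#>    trait stat df       p
#> 10   q10 9.92  1 0.00164
#> 15   q15 7.25  1 0.00710
#> 23   q23 6.77  1 0.00928

it <- interaction_test(ds$traits$quant[, "q10"], ds$genotypes[, het_snp], fit$Z,
                       background = ds$covariates$homogeneous[, -het_snp],
                       mode = "heterogeneity")
subtype_specific_effects(it)
#>   subtype estimate     se   lower  upper
#> 1       1   -0.119 0.0677 -0.2540 0.0169
#> 2       2    0.176 0.0644  0.0472 0.3050
```

The adjusted Rand index of 0.98 says the learned subtypes nearly coincide
with the simulated truth. The heterogeneity test flags trait q10 for a SNP
simulated with per-subtype effects (heterogeneous SNPs jointly explain only
0.4% of each trait's variance, so single SNP-trait p-values are modest at
N=2,000), and the per-subtype estimates (±2 s.e. bounds) recover the
opposite signs the simulation planted. On null and homogeneous-effect SNPs
the same test is calibrated — that is the content of the acceptance suite.

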
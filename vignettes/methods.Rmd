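---
title: "Models and methods in mixwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mixwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`mixwas` implements a two-step strategy for finding and validating
phenotypic subtypes in multi-trait cohort data. Step one learns latent
subtypes from the traits themselves with a covariate-aware finite mixture of
multi-trait regressions (MFMR). Step two treats the inferred membership
probabilities as data and asks whether genetic or non-genetic covariates have
*different* effects across subtypes — with fixed-effect SNP-by-subtype
interaction tests, genome-wide interaction scans with genomic-control
diagnostics, and a polygenic variance-component model that partitions
heritability into homogeneous and subtype-specific parts. The package ships
a complete synthetic-cohort simulator so every calibration and power claim in
the test suite is reproducible from code alone.

# Step 1: the mixture of multi-trait regressions

Each sample $i$ carries a latent subtype $z_i \in \{1,\dots,K\}$ with
$P(z_i = k) = p_k$. For quantitative trait $p$,

$$ y_{ip} = X_i \alpha_p + G_i \beta_{kp} + \epsilon_{ip}, \qquad
   \epsilon_{ip} \sim N(0, \sigma^2_{kp}), $$

where $X$ (N×Q) holds *homogeneous* covariates whose effects $\alpha$ are
shared by all subtypes (genetic PCs, age, known interventions), and $G$
(N×L) holds *heterogeneous* covariates with per-subtype effects $\beta_k$.
The first column of $G$ is the intercept, so its per-subtype coefficients are
the subtype main effects on each trait. Binary traits use the same linear
predictor through a probit link, with a conditional-independence assumption:
given $z_i$, all traits (quantitative and binary) are independent. This keeps
the multi-trait binary likelihood tractable; cross-trait residual correlation
is deliberately *not* modeled (see "Numerical and design choices").

## Fitting

The model is fit by Expectation Conditional-Maximization:

* **E-step** — posterior responsibilities $Z_{ik} \propto p_k
  \prod_p N(y_{ip};\cdot,\sigma^2_{kp}) \prod_b \Phi(\cdot)^{y}(1-\Phi)^{1-y}$,
  computed in log space.
* **CM (quantitative)** — for each trait, a single weighted least-squares
  solve that is *joint* in $\alpha$ (shared) and all $\beta_k$, with weights
  $Z_{ik}/\sigma^2_{kp}$; then $\sigma^2_{kp}$ updates as the weighted
  residual mean square.
* **CM (binary)** — per trait, responsibility-weighted probit regression on
  the expanded design $[X, G \otimes \text{subtype}]$ by Fisher scoring with
  step halving; candidate steps are projected into a $\pm 15$ coefficient box
  (separation guard) *before* the ascent check, so no step can decrease the
  objective and the observed-data log-likelihood is non-decreasing across
  ECM iterations — an invariant asserted in the test suite on 250 fits.

Quantitative traits and covariates are standardized internally; all reported
coefficients and likelihoods are transformed back to the original scale (the
$K{=}1$ model reproduces `lm()`/`glm(probit)` coefficients to machine
precision, a tested oracle identity). Subtypes are relabeled after fitting so
the largest mixing proportion comes first, making label order deterministic.

Default optimizer effort is 10 random responsibility restarts plus one
initialization derived from a Gaussian-mixture fit on covariate-residualized
traits, relative tolerance $10^{-8}$, 1000 iterations. Large simulation
studies in the acceptance material reduce this to the single deterministic
GMM-derived start and $10^{-6}$; this changes runtime, not the simulated
world, and spot checks show identical test behavior.

If any subtype's responsibility mass falls below `max(K, 5)`
samples-equivalent the restart is marked degenerate; the best non-degenerate
restart wins, and a persistent degeneracy is returned flagged rather than
hidden.

## Choosing K and measuring stability

`cv_select_K()` reports held-out log-likelihood per fold relative to the
$K{=}1$ baseline — on pure noise the $K{>}1$ values hover at or below zero
(no out-of-sample reward for spurious structure), while real subtype
structure pushes them up. `coclustering_stability()` refits the model on
training folds, assigns held-out samples with frozen parameters, and reports
the fraction of originally co-clustered pairs that stay together.

# Step 2: heterogeneity testing

With membership probabilities $z$ (soft, never hard-assigned — hard labels
discard information), the single-covariate interaction model is

$$ y \sim \tilde X \alpha + z\gamma + g\delta + (g \ast z)\beta + \epsilon. $$

Three tests: **homogeneity** ($\delta \ne 0$ with $\beta \equiv 0$, 1 df),
**heterogeneity** ($\beta \ne 0$ with $\delta$ free, $K-1$ df), and
**global** ($\delta, \beta \ne 0$, $K$ df). One membership column (the
largest subtype) is dropped for identifiability; per-subtype effects are
reported as $\delta + \beta_k$ with delta-method standard errors.
Quantitative traits use linear regression with Wald chi-squared statistics;
binary traits use logistic regression with likelihood-ratio statistics. A
continuous subtype score (a CCA or PC estimate) can be passed in place of the
simplex matrix, giving 1-df heterogeneity and 2-df global tests.

How a *focal* covariate is handled in step 1 matters. Ignoring it entirely
is safe only for small effects (SNPs in a genome scan); including it with a
homogeneous effect is the default for large-effect covariates (its mean
effect is adjusted but the subtypes are not tuned to it); including it with
subtype-specific effects overfits and inflates the false-positive rate — a
directional property reproduced in the test suite. `genome_scan()` freezes
$Z$ from a fit that excluded the SNPs, streams per-SNP results, marks
monomorphic SNPs, and attaches the genomic-control factor
$\lambda_{GC} = \mathrm{median}(\chi^2_1)/0.4549$, flagging scans above a
configurable ceiling (default 1.5).

# Polygenic validation

`fit_iid_gxemm()` aggregates SNP-level heterogeneity genome-wide:

$$ V = \sigma^2_{hom} K + \sigma^2_{het} (K \circ ZZ^\top) + \sigma^2_e I, $$

with $K$ the genetic relationship matrix from standardized genotypes and
$K \circ ZZ^\top$ the kernel of genetic effects shared only within subtype
(soft memberships propagate step-1 uncertainty; with hard labels it is block
diagonal). Estimation is average-information REML with step halving and
projection onto the nonnegative orthant, with an EM-style fallback step when
the AI matrix is singular. Heritability fractions are computed on the
fixed-effect-residualized scale, weighting each kernel by its mean diagonal;
the constrained $\sigma^2_{het} = 0$ fit is ordinary GREML (verified against
a direct likelihood grid), and the fixed-effects-only null has a closed
form. Total genetic variance is tested with a one-sided Wald test; the
subtype-specific component with an LRT against the boundary-aware
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ null (the variance sits on the
boundary under $H_0$; the paper-style reference does not state its null, so
the standard mixture is used). A SNP with exactly opposite effects in two
equal subtypes contributes nothing homogeneous: the fit returns
$h^2_{hom} \approx 0$ with $h^2_{het}$ carrying the signal, and ignoring
heterogeneity (GREML) understates total heritability — both tested.
Binary-trait estimates are reported on the observed scale without p-values
(no accepted liability-scale transform exists for heterogeneous components).

# The simulated world

The generator's defaults state one concrete world: N samples; 27
quantitative and 3 binary traits (prevalences 0.5 / 0.3 / 0.2, the last one
available for 20%-prevalence ascertainment studies); 12 SNPs split 4 null /
4 homogeneous / 4 heterogeneous; homogeneous SNP effects explaining 4% of
every trait's variance, heterogeneous effects 0.4% (per-subtype effects
centered so they are purely heterogeneous), subtype main effects 20%
(constants the source material leaves to its supplement are fixed here and
exposed in `sim_config()`); the remainder is noise that is correlated across
traits through the square root of a scaled-Wishart random correlation matrix
(df = P + 2, substantial but well-conditioned correlations). Genotypes are
independent SNPs — no linkage disequilibrium, by design. Each variance
component is rescaled to hit its target *exactly* in sample, so variance
bookkeeping in tests is exact rather than within Monte-Carlo error.
Binary traits threshold a unit-variance latent trait at the empirical
quantile of the configured prevalence, which is exactly the probit
construction the mixture assumes.

Scenario variants: Student-$t_5$ noise (excess kurtosis 6 before
correlation mixing); squared or exponentiated SNP effects (analysis uses the
raw additive coding, so the model is misspecified on purpose — the squared
transform is uncorrelated with the raw SNP); a continuous Gaussian subtype
score replacing discrete labels (and a variant with heterogeneous SNP effect
sizes doubled, i.e. h2_het ×4 — subtype mains are left unchanged, since
doubling them too would mostly make the problem easier); 50/50 case/control
ascertainment of the 20%-prevalence trait from an oversampled population
draw; gene-environment correlation $\rho_{GE} \in [0,1]$ implemented as
probabilistic label copying from a genotype-burden threshold rule over the
*whole* SNP panel (so $\rho_{GE}=1$ makes subtype status a deterministic
function of genotype and even null SNPs correlate with it — without this,
the documented FPR inflation for null/hom SNPs could not arise); and a
two-population Balding–Nichols world (ancestral frequency uniform on
(0.05, 0.95), per-population frequencies
$\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with $F_{ST}=0.1$, 10,000 SNPs,
population main effects on traits defaulting to 5% of variance).

What the generator does *not* emulate: linkage disequilibrium, rare
variants, non-random missingness, relatedness/kinship, batch structure, and
trait-specific subtype membership. A green calibration test therefore
establishes calibration under exchangeable, LD-free genotypes and
single-membership subtypes — not under every failure mode of real cohorts.

# Numerical and design choices

* **Diagonal residuals in the mixture.** Robustness to correlated noise is a
  *tested property* (the baseline world has correlated noise and the
  heterogeneity test stays calibrated), not a modeled feature. A side effect:
  on easy draws a full-covariance Gaussian mixture can match or slightly
  exceed MFMR's clustering accuracy; MFMR's advantage concentrates where
  homogeneous covariate effects are strong, and the tests compare mean
  accuracy over draws in that regime.
* **Weir–Cockerham estimator.** The multi-locus ratio-of-sums form is the
  default; the mean of per-SNP ratios is visibly downward biased
  (≈0.084 for a true 0.1 at 2×1000 samples) and is available only via
  `per_snp = TRUE`.
* **Binary imputation threshold.** Imputed binary entries are cut at 0.5
  (the source material states thresholding without a cutpoint).
* **MVN imputation** runs EM to a $10^{-6}$ relative tolerance, cap 200
  iterations, with ridge repair of non-PD covariances; `lowrank_impute()`
  soft-thresholds singular values at the $(r{+}1)$-th value (or an explicit
  penalty) and restores observed entries exactly.
* **Seeds.** One master seed is fanned out deterministically per stage;
  identical config + seed gives bit-identical datasets and result tables.
* **Configuration files are JSON**, not YAML: no YAML parser is available in
  the supported dependency set, and the configuration contract is unchanged.

# Known limitations

Step-1 uncertainty enters step 2 only through the soft memberships, not as
sampling error in the fitted parameters. The heterogeneity test is not
ascertainment-corrected: on 50/50 case/control samples of a 20%-prevalence
trait a modest inflation is expected and accepted, as in the source
methodology. The variance-component model assumes equal heritability and
noise within every subtype, and estimates for ascertained binary traits are
reported without significance tests. Interaction tests on covariates with
strongly non-linear effects, or continuous large-effect subtype structure in
very large cohorts, can inflate beyond the tested regimes.
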
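---
title: "POM-SKAT: kernel association testing for ordinal phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{POM-SKAT: kernel association testing for ordinal phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomskat)
```

## The testing problem

Many clinically meaningful phenotypes are ordered categories rather than
continuous or binary traits: graded liver steatosis, antibody titer risk
bands such as anti-CCP levels for rheumatoid arthritis, tumor stage.
Set-based kernel association tests (the SKAT family) are the standard tool
for testing a group of SNPs jointly against a phenotype, but their classical
forms assume a continuous or binary outcome.  `pomskat` implements a
variance-component score test for an ordinal phenotype under the
proportional odds model (POM), together with the comparator tests and the
simulation harness needed to study its operating characteristics.

## Model and statistic

For subject $i$ let $y_i \in \{0, \dots, J-1\}$ be the ordinal phenotype,
$x_i$ a vector of covariates and $g_i \in \{0,1,2\}^M$ minor-allele dosages
for the SNP set.  The POM is the cumulative-logit model

$$\mathrm{logit}\, P(y_i \le j) = \zeta_j - g_i^\top\beta - x_i^\top\gamma,
\qquad \zeta_0 < \dots < \zeta_{J-2}.$$

Testing $H_0 : \beta = 0$ coefficient-by-coefficient loses power when $M$ is
large.  The variance-component formulation instead treats $\beta$ as random
with mean zero and variance $D(\theta)$, reducing the problem to the scalar
hypothesis $H_0 : \theta = 0$.  The quasi-likelihood score statistic is

$$T = \tfrac12 (y - \hat\mu)^\top \tilde G \, W \, \tilde G^\top (y - \hat\mu),$$

where

* $\hat\mu$ holds the fitted means of $y_i$ under the **null** POM
  (covariates only), $\hat\mu_i = \sum_{j=0}^{J-2} P(y_i > j)$;
* $\tilde G$ is the dosage matrix residualized on $[1, X]$ by least squares,
  which removes genotype–covariate confounding and centers the columns;
* $W = \mathrm{diag}(w_1, \dots, w_M)$ with
  $w_m = \{\mathrm{Beta}(f_m; \tfrac12, \tfrac12)\}^2$, the squared
  Beta-density weight at the sample minor allele frequency $f_m$, the
  realized derivative $D'(\theta)$ of the variance function.  This
  up-weights rarer common variants smoothly; the test's p-value is invariant
  to any positive rescaling of $W$.

Under $H_0$, $T$ is distributed as a mixture
$\sum_m \lambda_m \chi^2_1$ with $\lambda$ the eigenvalues of
$\tfrac12 V^{1/2} \tilde G W \tilde G^\top V^{1/2}$, where $V$ is the
diagonal matrix of null response variances
$\mathrm{Var}(y_i) = \hat\mu_i - \hat\mu_i^2 + 2\sum_{j\ge1} j P(y_i > j)$.
We compute the spectrum from the $M \times M$ form
$\tfrac12 W^{1/2}\tilde G^\top V \tilde G W^{1/2}$, which shares all nonzero
eigenvalues with the $n \times n$ form at a fraction of the cost (this
equality is asserted by a test on small fixtures).

### Pearson Type III p-value

The mixture tail is approximated by a Pearson Type III (shifted gamma)
distribution matched to the first three standardized moments.  With
$E(T) = \sum\lambda_m$, $\mathrm{Var}(T) = 2\sum\lambda_m^2$,
$E[(T-ET)^3] = 8\sum\lambda_m^3$ and skewness
$\xi = E[(T-ET)^3]/\mathrm{Var}(T)^{3/2}$, the standardized statistic
$T^* = (T - E(T))/\sqrt{\mathrm{Var}(T)}$ is referred to the shifted gamma
with

$$\text{shape } b = 4/\xi^2, \quad \text{scale } a = \xi/2, \quad
\text{location } c = -2/\xi,$$

the unique member of the family with mean 0, variance 1 and skewness $\xi$
(so $b a^2 = 1$ and $c + ab = 0$).  The p-value is the upper tail
$P(\Gamma(b, 1) > (T^* - c)/a)$, computed with `pgamma`.  For a single
eigenvalue the approximation is *exact* — it collapses to the
$\lambda\chi^2_1$ tail — which the test suite verifies to $10^{-9}$ across
tail probabilities from $10^{-6}$ to 0.99.  For $\xi \to 0$ the matched
distribution tends to the standard normal.

### Null model fitting

`fit_null()`/`pom_fit()` maximize the multinomial likelihood directly: a
damped Newton iteration on the raw $(\zeta, \gamma)$ vector with the
analytic gradient and Hessian, guarded by step halving (a proposal that
disorders the cutpoints collapses a category probability and is rejected by
the line search), with a quasi-Newton fallback on
$(\zeta_0, \log \Delta\zeta, \gamma)$ — a scale on which the ordering
constraint holds unconditionally — for the rare stall.  Convergence demands
a gradient max-norm below $10^{-8}$.  The fit is validated against
`MASS::polr` (for $J \ge 3$) and `glm(..., binomial)` (for $J = 2$, which
`polr` does not accept) in the test suite; the two moment formulas are
cross-checked against the definitional sums $\sum_j j P(y=j)$ and
$\sum_j j^2 P(y=j) - \mu^2$ to $10^{-12}$.

Two printed-formula subtleties in the source literature for this model
family are worth documenting.  First, exceedance sums for the mean and
variance of a $0..J-1$ score necessarily stop at $j = J-2$ (the last
cutpoint); running them to $J-1$ would reference a cutpoint that does not
exist and fails the $J=2$ sanity check $E(y) = P(y=1)$.  Second, sign
conventions for cutpoints differ across writeups; we adopt the ascending
`polr` convention $\mathrm{logit}\,P(y \le j) = \zeta_j - \eta$, to which
the test statistic is invariant.

## Comparators

* **PCA-LRT** — PCA on the SNP correlation matrix; the smallest $L$ leading
  components capturing 80% of the variance enter the POM, and the
  likelihood ratio against the covariates-only model is referred to
  $\chi^2_L$.
* **Single-SNP + Bonferroni** — each SNP fitted separately in the POM, Wald
  p-values against the standard normal (the asymptotic reference for the
  POM coefficient; at the sample sizes involved the difference from a $t$
  reference is negligible), then $\min(1, M \cdot \min_m p_m)$.
* **MinP** — the same per-SNP p-values, with the minimum referred to its
  permutation distribution over phenotype shuffles, add-one estimator
  $(1 + \#\{\min p^*_r \le \min p\})/(R+1)$.
* **QT** — the joint likelihood-ratio test of all $M$ dosage coefficients
  with $\chi^2_M$ reference.  The reference distribution is the only thing
  the source literature fixes for this comparator; we implement it as the
  joint LRT (score or Wald forms would be interchangeable) and it fails
  explicitly, as it should, when the joint design is collinear.

## The synthetic-data generator

`sim_dataset()` reproduces the study design the operating characteristics
are evaluated under:

* **Genotypes** — a Gaussian copula: latent rows are $N(0, \Sigma)$ with
  AR(1) correlation $\Sigma_{jk} = \rho^{|j-k|}$, thresholded per SNP at the
  standard-normal quantiles of $(1-f)^2$ and $1-f^2$, so marginals are the
  Hardy–Weinberg proportions $((1-f)^2,\, 2f(1-f),\, f^2)$ and adjacent
  SNPs are in LD controlled by $\rho$.  Default MAFs are equally spaced on
  $[0.1, 0.45]$.
* **Covariates** — i.i.d. bivariate normal with unit variances and
  covariance 0.5 (interpreting the compact $0.5^{|i-j|}$ notation as the
  $2\times2$ AR-type matrix), effects $\gamma = (0.5, 0.8)$.
* **Phenotype** — latent $y_i^{\mathrm{lat}} = x_i^\top\gamma +
  g_i^\top\beta + \phi\, g_{i1} g_{i2} + \epsilon_i$ with standard logistic
  errors, cut at the *empirical* quantiles of the realized latent vector at
  probabilities $D$ (linear-interpolation order-statistic quantiles, the
  standard `quantile()` default; any convention differing by $O(1/n)$ would
  be equally valid).  Truncating the realized vector pins the category
  proportions at `diff(c(0, D, 1))` in every replicate, exactly as in the
  original design.  The interaction product $g_{i1}g_{i2}$ is deliberately
  uncentered.
* **Seeding** — a master seed plus replicate index map through an affine
  function modulo the prime $2^{31}-1$ to a per-replicate seed, so every
  replicate is a pure function of `(master, r)` and bit-reproducible in
  isolation.

What the generator does **not** emulate: real LD blocks (AR(1) decay is a
smooth caricature), allele-frequency spectra of real gene regions, missing
genotypes, or population stratification.  Power studies of this design are
sometimes anchored to real gene-region genotypes from access-restricted
consortium data; absolute power values depend on that LD structure, so the
synthetic AR(1) generator supports *trend* and *ordering* conclusions, not
exact power reproduction (a genotype-file hook, `read_genotypes()`, lets a
user with access to real dosages rerun the power study on them).

## Simulation studies the package runs

* **Type I error** (`type1_experiment`) — 18 null scenarios:
  $J = 3, n = 2000, D = (0.16, 0.84)$ and
  $J = 5, n = 3000, D = (0.2, 0.4, 0.6, 0.8)$, crossed with
  $M \in \{50, 100, 200\}$ and $\rho \in \{0.2, 0.5, 0.8\}$, 500 replicates
  each at $\alpha = 0.05$.  The acceptance suite checks every empirical
  rate against the nominal level and the published grid within two binomial
  standard errors ($\pm 0.0195$ at 500 replicates) and the pooled p-values
  for uniformity (Kolmogorov–Smirnov at level 0.01, Q–Q deviation within
  the 99.9% KS band).
* **Power and trends** (`power_experiment`) — the package's trend checks
  run at a deliberately reduced grid sized for a desktop run:
  $J = 3$, $n = 1000$, $M \in \{8, 16\}$, $B \in \{0, 2, 4\}$ causal SNPs
  with $\beta_b = 0.2$, $\rho = 0.5$, 500 replicates per cell.  Checked
  properties: power nondecreasing in $B$ at fixed $M$, decreasing in $M$ at
  fixed $B$, and the aggregate ordering POM-SKAT $\ge$ PCA $\ge$ Bonferroni
  judged by paired per-replicate comparisons pooled over the alternative
  cells.
* **Permutation reference** (`permutation_pvalue`) — the re-sampling
  p-value refits the null model per shuffled phenotype and recomputes $T$
  ($\tilde G$ depends only on genotypes and covariates and is unchanged by
  the shuffle).  Phenotype-only permutation is an *exact* null reference
  only when the phenotype is exchangeable, i.e. when it carries no
  covariate dependence; with strong covariate effects the permutation
  distribution differs from the model-based null by design (it destroys the
  $y$–$X$ coupling and its heteroscedastic $V$).  The oracle-agreement
  checks therefore use exchangeable fixtures ($\gamma = 0$, covariates
  still in the model), where Pearson III and 5000-permutation p-values
  agree within 0.02 and a $10^6$-draw Monte-Carlo of the eigenvalue mixture
  agrees within 0.005 for mid-range p-values.

## Numerical choices and edge cases

* Eigenvalues below $10^{-10}\lambda_{\max}$ are treated as numerical rank
  deficiency and dropped before the moment sums.
* Sample MAF (folded to $\le 0.5$) feeds the weights; monomorphic SNPs
  (infinite weight) and SNPs collinear with covariates (zero residual) are
  dropped with an accounting warning, never silently.
* The phenotype must arrive as consecutive integers $0..J-1$ with every
  category observed; `remap_ordinal()` converts labeled categories with an
  explicit level order.  Missing-category and rank-deficiency errors name
  the offending level or column.
* $T^*$ below the gamma's support boundary (possible for tiny spectra)
  returns $p = 1$.
* Q–Q plotting positions are $i/(n+1)$; the source design does not state a
  convention and any standard choice differs by $O(1/n)$.

## A worked example

```{r example}
cfg <- sim_config(n = 500, M = 20, J = 3, rho = 0.5,
                  beta = rep(0.25, 4), seed = 42)
d <- sim_dataset(cfg)
res <- pom_skat_test(d$y, d$X, d$genotypes)
res
# comparators on the same data
c(pca = as.numeric(pca_lrt_test(d$y, d$X, d$genotypes)),
  bonferroni = bonferroni_test(single_snp_pvalues(d$y, d$X, d$genotypes)),
  qt = as.numeric(qt_test(d$y, d$X, d$genotypes)))
```

## Known limitations

* Only the weighted linear kernel is provided; IBS or Gaussian kernels, and
  rare-variant collapsing strategies, are out of scope.
* The Pearson III approximation targets common-variant spectra; with very
  few effective eigenvalues it remains exact-to-excellent, but no
  Davies-type exact inversion is included (the permutation routine is the
  in-package reference).
* The QT comparator is only estimable for $n \gg M$; this mirrors the known
  failure of joint classical tests for large SNP sets rather than working
  around it.
* p-values from permutation have granularity $1/(H+1)$; calibration
  statements at small $\alpha$ need correspondingly large $H$.
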
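---
title: "Mean-variance QTL mapping: models, permutations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-variance QTL mapping: models, permutations, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvqtlmap)
```

## The model

Traditional interval mapping fits, at each locus in turn, a standard linear
model (SLM): the phenotype of individual $i$ is
$y_i \sim N(m_i, \sigma^2)$ with a single residual variance shared by all
individuals, and

$$m_i = \mu + sex_i\,\beta_{sex} + a_i\,\beta_a + d_i\,\beta_d,$$

where $a_i$ is the count (0, 1, 2) of one parental allele and $d_i$
indicates heterozygosity (0 or 1). When the genotype at an evaluation
position is not observed directly, $a_i$ and $d_i$ are replaced by their
posterior expectations given all marker data on the chromosome (see
"Genotype probabilities" below).

Mean-variance QTL mapping replaces the single $\sigma^2$ with a double
generalized linear model (DGLM): each individual gets its own residual
variance, linked to a second linear predictor,

$$y_i \sim N(m_i, \sigma_i^2), \qquad \sigma_i = \exp(v_i), \qquad
v_i = \mu_v + sex_i\,\gamma_{sex} + a_i\,\gamma_a + d_i\,\gamma_d.$$

Evidence for a QTL comes from three nested likelihood-ratio comparisons of
the full model against:

* the null omitting the locus effects on the mean
  ($\beta_a = \beta_d = 0$) — the **mQTL** test (2 df);
* the null omitting the locus effects on the variance
  ($\gamma_a = \gamma_d = 0$) — the **vQTL** test (2 df);
* the null omitting both — the **mvQTL** test (4 df);

alongside the traditional SLM LOD score
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$. Because every fit is full
maximum likelihood (the SLM variance estimate is $RSS/n$, not
$RSS/(n-p)$), the statistics are mutually coherent: with an intercept-only
variance model the mQTL LR equals $2\ln(10)\,\mathrm{LOD}$ exactly, and
the mvQTL LR always dominates the mQTL and vQTL LRs. Both identities are
enforced by tests.

Why this matters scientifically: when one genotype group has smaller
residual variance, the SLM's pooled $\hat\sigma$ over-weights noisy groups
and under-weights precise ones, costing power to detect a mean effect; the
DGLM recovers that power by weighting each individual by its own fitted
precision. And a pure variance signal (a vQTL) is invisible to the SLM at
any sample size.

## Fitting

`fit_dglm()` maximizes the likelihood by block coordinate ascent:

1. **Mean block** — weighted least squares for $\beta$ with weights
   $1/\hat\sigma_i^2$;
2. **Variance block** — the score equations of a gamma GLM with log link
   and dispersion 2, response $(y_i-\hat m_i)^2$, solved to convergence
   (damped Newton on the observed information; the objective is concave in
   the variance coefficients, so the step always has a valid direction and
   backtracking guarantees ascent).

Each block solves its score system exactly, so the joint log-likelihood is
non-decreasing across iterations (a property the tests check). Iteration
stops when the log-likelihood changes by less than `tol` (default `1e-8`)
or after `maxit = 50` outer iterations; non-convergence returns the fit
flagged rather than erroring. Dispersion estimation is plain ML — no
leverage or REML-type adjustment — because the LR statistics compare
maximized likelihoods and a REML-style dispersion would break the
SLM reduction identity above.

Numerical choices worth knowing:

* Initialization: $v_i$ starts at the log SD of the SLM residuals (one
  cheap pass, stable).
* Internally the variance predictor is parameterized as
  $\log\sigma^2$; reported coefficients and standard errors are halved to
  the $\log\sigma$ convention of the model statement above.
* Degenerate fits (fitted $\sigma_i^2 < 10^{-12}$, e.g. an exact
  interpolation) are floored and flagged; flagged loci are excluded from
  permutation maxima rather than contributing infinite statistics.
* Constant or collinear locus codings are dropped from the locus terms, so
  a completely uninformative locus yields all four statistics equal to 0.
* Standard errors come from the block-diagonal expected information:
  $(X^\top W X)^{-1}$ for the mean and $2(Z^\top Z)^{-1}$ for the
  log-variance coefficients.

A Poisson DGLM (`fit_dglm_poisson()`) is provided for count phenotypes:
Poisson mean submodel with log link and prior weights $1/\phi_i$, a
log-linear dispersion submodel fitted to squared Pearson residuals, and
model comparison through the extended quasi-likelihood with
$V(\tilde y_i)$ evaluated at $\tilde y_i = \max(y_i, 1/6)$ so zero counts
contribute a finite constant.

## Genotype probabilities

`calc_genoprob()` runs the standard three-state hidden Markov
forward–backward pass for an F2 intercross: prior $(1/4, 1/2, 1/4)$ at the
first locus, transition probabilities for two independent meioses with the
Haldane map function $r = (1 - e^{-2d/100})/2$ (no interference; the
source analyses do not state a map function, so we adopt the intercross
convention), and emissions that allow a genotyping error rate
(default $10^{-4}$; a wrong code is observed with probability
`error_prob`, split evenly between the two wrong genotypes). Pseudomarkers
can be inserted on a `step`-cM grid; the default evaluates at genotyped
markers only, matching how the case-study scans report their peaks. The X
chromosome is treated as an autosome with a warning — a proper X model
(dosage, cross direction) is out of scope. Posteriors on chromosomes with
up to four markers are checked against brute-force enumeration of all
hidden sequences to $10^{-9}$.

The locus coding used by every scan model is the posterior expectation
$a = 2\,p_{BB} + p_{AB}$, $d = p_{AB}$, which reduces to exact
$\{0,1,2\}$ / $\{0,1\}$ coding at typed markers.

## Genome-wide significance

Raw LR statistics are converted to family-wise-error-rate (FWER) adjusted
p-values by permutation. Let $G_i$ be individual $i$'s whole-genome
genotype information. One permutation draws a single random relabeling of
individuals and applies it to the $G_i$ — never to phenotypes or
covariates — preserving each individual's multilocus genotype vector and
hence linkage among loci. The relabeling is *structured* by test:

* **SLM** and **mvQTL**: all genotype terms are relabeled;
* **mQTL**: only the locus terms in the full model's *mean* submodel; the
  variance-submodel locus terms stay unpermuted in full and null models
  alike, so the null fit is literally constant across permutations (the
  implementation computes it once per locus);
* **vQTL**: the converse.

This targets each test's null hypothesis while leaving the nuisance
signal (e.g. a true variance effect when testing the mean) intact. For
each permutation the genome-wide maximum of the test's statistic is
recorded; a three-parameter generalized extreme value (GEV) distribution
is fitted to the maxima by maximum likelihood (Gumbel moment
initialization; Gumbel fallback with a flag if the full fit fails), and
the adjusted p-value of a locus is the fitted upper-tail probability of
its statistic, clamped to $[10^{-12}, 1]$. Fitting a parametric tail is
what lets the procedure report p-values beyond the resolution of the
permutation count. Empirically the procedure is calibrated: on null
crosses (n = 150, 33 markers, 300 permutations) the family-wise error at
nominal 0.05 lies in $[0.02, 0.09]$ for all four tests (checked over 300
outer replicates in the test suite).

QTL localization uses a nonparametric bootstrap: resample individuals
with replacement, rescan the peak chromosome, record the position of the
maximal statistic, and take the central percentile interval of the
recorded positions (default 1,000 resamples, 90% coverage, using the test
that identified the QTL).

## Phenotype transformations

Variance effects are scale-sensitive: a monotone transformation can
manufacture or remove variance heterogeneity, so vQTL findings should be
examined across scales. The package provides the rank-based inverse
normal transform $\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties
(deterministic in the ranks, hence invariant to monotone re-expression of
the data), log, square root, and Box-Cox power transforms. Box-Cox
selection profiles the Gaussian likelihood (with Jacobian, via
`MASS::boxcox`) over a lambda grid (default $[-2, 2]$ in steps of 0.05)
against a covariates-only mean model — deliberately excluding QTL terms so
the choice of scale cannot peek at genotype effects. The exponent is
always data-selected or user-supplied, never assumed. For count
phenotypes with zeros a shift (default 1) is applied before log or power
transforms and recorded in the spec. One boundary convention: a full-tie
pair of length 2 maps to $(0, 0)$ by the average-rank rule, while longer
constant vectors error, since every rank is then tied and the transform
carries no information.

## The simulator and what passing tests mean

`simulate_f2()` draws each chromosome's genotypes from the F2 Markov
chain (first marker $(1/4, 1/2, 1/4)$, Haldane transitions for the marker
spacing), sex as Bernoulli(1/2), and the phenotype from the DGLM
generative model. Its defaults describe the kind of cross the method
targets — 244 individuals, the size of the circadian reduced-complexity
intercross, across 3 chromosomes of 11 markers at 10 cM — and all effects
default to zero so the default object is a global-null cross.
`power_compare()` works at a single locus with exact 1:2:1 genotype draws
and a fixed pointwise $\chi^2_2$ rejection threshold (the relevant regime
for a genome-wide cutoff like $\alpha = 5\times10^{-4}$); per-replicate
permutation thresholds would answer a different question.
`sample_size_equivalent()` converts the DGLM's power advantage at a locus
into the number of extra individuals the SLM would need, by grid search
(step 10 by default) until the SLM's power matches the DGLM's reference
power within Monte-Carlo error.

The simulator intentionally omits features of real crosses: genotyping
errors in the generated data (error handling is exercised through the HMM
instead), segregation distortion, missing genotypes beyond what the user
introduces, polygenic background, epistasis, and X-chromosome dosage.
Passing the suite therefore demonstrates that the estimator, tests,
permutation scheme, and intervals behave correctly *under the stated
model*; it does not certify robustness to model misspecification beyond
the transform-robustness tools described above.

Problem sizes used by the test suite and the acceptance script — chosen to
estimate each property with useful precision: 50 datasets of n = 120 for
the reduction identity; 2,000 null simulations at n = 200 for $\chi^2$
calibration; 5,000 single-locus replicates for power; 300 null crosses
(n = 150, 33 markers) with 300 permutations each for FWER calibration;
10,000 draws for GEV recovery; 200 fits at n = 800 for coefficient
coverage.

## Known limitations

* Autosomal F2 intercrosses only; no backcross/RIL designs, no kinship or
  polygenic correction, one locus per model (no epistasis scans).
* Genetic (cM) coordinates only; no physical-map conversion.
* The asymptotic $\chi^2$ references used in `power_compare()` are
  pointwise; genome-wide inference should always go through the
  permutation path. Like most likelihood-ratio tests, the DGLM tests are
  mildly anti-conservative in finite samples (at $n = 244$ the null
  rejection rate at nominal 0.05 is about 0.056 — the usual upward bias
  that a Bartlett correction would absorb); the permutation procedure is
  unaffected because it calibrates against the statistic's own null
  distribution.
* GEV tail extrapolation far beyond the permutation support inherits the
  usual caveats of parametric tail fitting; p-values are clamped at
  $10^{-12}$.

## A minimal session

```{r example, eval = FALSE}
cr <- simulate_f2(sim_config(
  n = 244, qtl = list(chr = "2", pos = 50, beta_a = 0.4, gamma_a = -0.4),
  seed = 1))
pr <- calc_genoprob(cr, error_prob = 1e-4)
sc <- scan_genome(pr, cr$pheno$y, covariates = cr$pheno["sex"])
nulls <- lapply(c("slm", "mqtl", "vqtl", "mvqtl"), function(tst) {
  permute_scan(pr, cr$pheno$y, covariates = cr$pheno["sex"],
               test = tst, n_perm = 1000, seed = 2)
})
sc <- fwer_adjust(sc, nulls)
top_marker(sc, "mqtl")
bootstrap_interval(pr, cr$pheno$y, covariates = cr$pheno["sex"],
                   chromosome = "2", test = "mqtl", seed = 3)
autoplot(sc)
```
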
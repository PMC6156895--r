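---
title: "Annotation-based DMR detection: model, assumptions and design choices"
author: "globalp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-based DMR detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globalp)
```

## The problem and the model

Methylation arrays report, per CpG probe, a beta value $\beta \in [0,1]$ —
the fraction of methylated DNA strands at that site. Because beta values are
heteroskedastic near the boundaries, association analysis works on M-values,
$M = \log_2(\beta/(1-\beta))$ (`beta_to_m()`; betas of exactly 0 or 1, which
occur on real arrays, are clamped into $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ by default, or rejected with `clamp = FALSE`).

**EWAS stage.** Each probe is regressed as
$M = \alpha + \beta\,y + \gamma^\top c + \epsilon$, with $y$ the quantitative
phenotype and $c$ the covariates. For family samples the residual covariance
is $\sigma^2_g \cdot 2\varphi + \sigma^2_e I$, with $\varphi$ the pedigree
kinship matrix ($2\varphi$ is the additive relationship matrix, the standard
quantitative-genetics convention). The fit is restricted maximum likelihood:
$2\varphi$ is eigendecomposed once, the data rotated into its eigenbasis,
and the criterion profiled down to the single variance ratio
$\delta = \sigma^2_g/\sigma^2_e$, minimized by a bounded Brent-type search on
$\log\delta \in [-10, 10]$ (`stats::optimize`, tolerance $10^{-8}$). When
many probes share one kinship matrix, `run_ewas()` rotates all probes with a
single matrix product; `kinship_eigen()` exposes the precomputed
decomposition for repeated fits.

Each probe yields $z = \hat\beta / \mathrm{SE}(\hat\beta)$ and a two-sided
p-value from the **normal (Wald) reference**, not a t reference: the region
statistic consumes $z$ directly and assumes standard-normal margins, so the
per-probe p-values are kept on the same reference for coherence. At the
sample sizes the method targets (hundreds of samples) the difference is
small; at small $n$ the normal reference is mildly anticonservative, which
is a known property of Wald mixed-model EWAS inference and is left
uncorrected here.

**Region stage.** Probes are grouped by fixed biological annotation — one
region per distinct (gene, functional category) pair across the six
categories TSS1500, TSS200, 5′UTR, 1stExon, Body, 3′UTR (paired
positionally from the manifest's parallel semicolon lists, the Illumina
manifest convention), and one region per (CpG island, relation) pair across
Island, N\_Shore, S\_Shore, N\_Shelf, S\_Shelf. Under the null the region's
z-vector is $z_m \sim \mathcal N(0, \Sigma)$ with $\Sigma$ the partial
correlation matrix of the probes' M-values given the covariates; hence

$$ z_m^\top \Sigma^{-1} z_m \sim \chi^2_m . $$

$\Sigma$ is estimated per region by residualizing each probe's M-values on
an intercept plus the covariates and correlating the residuals. Kinship is
deliberately **not** used in this residualization: the partial-correlation
definition is covariate-only, and a kinship-aware $\Sigma$ would be an
extension; `partial_correlation()` is the hook where such an extension would
plug in.

## Numerical choices

* **Ill-conditioned $\Sigma$** (duplicate or near-collinear probes):
  eigenvalues below $\tau \lambda_{max}$ ($\tau = 10^{-8}$, flag `eig_tol`)
  are clipped to zero, the statistic uses the corresponding pseudo-inverse,
  and the degrees of freedom equal the retained rank. Clipping $k$
  eigenvalues reduces df by exactly $k$, preserving the $\chi^2$ reference
  on the retained subspace rather than letting a near-singular inverse blow
  the statistic up.
* **Boundary REML optima.** Under a null variance component the REML optimum
  legitimately sits at the lower $\delta$ boundary ($\delta \to 0$ is
  exactly the OLS model). Boundary hits are therefore reported in a separate
  `boundary` flag with `converged = TRUE`; `converged = FALSE` is reserved
  for genuine numerical failure, so downstream region assembly does not
  discard half of all probes in unstructured data.
* **Missing data.** Per-probe complete cases in the EWAS (with `n_used`
  recorded); per-region complete cases for $\Sigma$. The z-scores entering a
  region may thus use slightly different samples than $\Sigma$ — the price
  of the summary-statistics input contract, documented rather than hidden.
* **Determinism.** Categorical covariates are expanded with sorted levels
  (first level as reference), sample alignment sorts ids, and region
  assembly orders by position with radix sort, so every stage is a pure
  function of its inputs; the pipeline re-run on the same study directory is
  byte-identical.
* **Multiplicity.** Benjamini–Hochberg step-up across the *pooled* family
  of gene and island regions (one FDR family, default $\alpha = 0.05$).
  Adjusting the two annotation classes separately would also be defensible;
  pooling is the default because the discoveries are reported as one list.
  The step-up is implemented directly (sort + reverse cumulative minimum)
  so its arithmetic is bit-reproducible against a brute-force oracle; the
  unit tests also cross-check it against `stats::p.adjust`.
* **Region size.** Default `min_probes = 2` (configurable to 1): a
  single-probe region is identical to the probe's own EWAS test, which the
  m = 1 reduction test confirms exactly.

## What the simulator emulates — and what it does not

`simulate_study()` generates family-structured studies: a phenotype built
from age/sex/center/smoking covariate effects, a polygenic family effect
with covariance $h^2 \cdot 2\varphi$ and unit total variance, and per-region
probe M-values drawn multivariate normal with exchangeable or AR(1)
correlation $\rho$, with planted effects added as `effect × phenotype` on
causal probes. M-values are generated directly and transformed to betas, so
the generative correlation lives on the scale the statistic uses. Family
structures are unrelated singletons, parent–parent–child trios, or sibships
(kinship blocks written analytically and cross-checked against the pedigree
recursion).

Defaults describe the reference calibration regime used throughout the
tests: 200 unrelated samples, regions of 5 probes with exchangeable
$\rho = 0.6$, no heritability, no causal regions. Replicate seeds are
spawned deterministically from a master seed.

The simulator intentionally omits: probe-type (Infinium I/II) chemistry and
its normalization artifacts, batch effects, cell-type composition,
genome-scale annotation complexity (each synthetic region is one gene-Body
annotation), and phenotype models beyond a Gaussian trait. Passing
calibration and power tests on these studies therefore demonstrates the
statistical machinery is correct under its own assumptions — not that real
450K data meet those assumptions; on real data the upstream normalization
and the adequacy of the covariate set remain the analyst's responsibility.
Probe-exclusion criteria (polymorphic and cross-reactive probes) are
consumed as precomputed id lists rather than recomputed from genome
resources, with the reasons preserved in the filter audit.

## Experiment sizing

The shipped experiments are sized for useful Monte-Carlo precision at
interactive runtimes: 2000 replicate studies for null calibration (binomial
95% half-width ≈ 0.01 at the region level), 500 replicates per power-grid
point (half-width ≤ 0.05), 500 replicates for fixed-effect recovery
(SEM ≈ 0.002 on $\hat b$), and $10^4$ draws for the null-uniformity
Kolmogorov–Smirnov check. The acceptance script uses 1000/300/200-replicate
variants of the same experiments.

## Known limitations

* $\Sigma$ estimated from the analysis sample itself adds sampling noise to
  the statistic; with $m = 5$ and $n = 200$ the measured region-level
  type-I error is close to nominal (the calibration test band is
  0.040–0.060), but very small $n$ with large $m$ will inflate it.
  Precomputed external correlation panels are a natural extension and can be
  supplied through `region_chi2()` directly.
* Two-time-point designs are analyzed as two independent runs; no
  cross-visit combination is attempted.
* The kinship LMM assumes a single polygenic variance component; household
  or batch random effects are out of scope.
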
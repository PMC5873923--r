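---
title: "Kernel models for multi-environment genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel models for multi-environment genomic prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernGE)
```

## The problem

Plant breeding programs evaluate sets of lines (or hybrids) in several
environments and must predict the performance of line-environment
combinations that were never grown: untested lines (sparse-testing designs)
or tested lines in unobserved environments. Genomic prediction does this by
borrowing information through a marker-derived relationship kernel between
lines, while genotype-by-environment interaction (G×E) determines how much
of a line's merit transfers from one environment to another.

`kernGE` implements two families of Bayesian multi-environment models over a
common data surface (a long-format table of line-by-environment adjusted
means plus a marker dosage matrix):

* the **Hadamard family** — MM, MMl, MDs, MDsl, MDe, MDel — in which all
  covariance structures are elementwise (Hadamard) products of the expanded
  line kernel with environment-incidence patterns, and
* the **Kronecker family** — MUC, MUCf — in which the genetic covariance is
  the Kronecker product of an unstructured m×m between-environment covariance
  with the line kernel.

Each model can use a linear kernel (GB; genomic BLUP) or a Gaussian kernel
(GK), giving the full grid of model-method combinations.

## Kernels

Markers pass a standard QC: markers with minor allele frequency below 0.05
or missing rate above the threshold are removed, remaining missing dosages
are mean-imputed, and columns are centred and scaled to unit sample variance
(n−1 denominator; zero-variance columns are dropped, never divided by zero).

The linear kernel is $K = XX'/p$ with $X$ the standardized $n \times p$
marker matrix. The Gaussian kernel is

$$K(x_i, x_{i'}) = \exp\!\left(-h\, d_{ii'}^2 \big/ \mathrm{median}(d^2)\right),$$

with $d_{ii'}^2$ the squared Euclidean marker distance, bandwidth $h = 1$,
and the median taken over the strictly off-diagonal distances — including
the zero self-distances would deflate the scale, so they are excluded. The
pair at the median distance always maps to $e^{-h}$; the diagonal is exactly
one. The Gaussian kernel is a nonlinear function of marker distance and
captures non-additive (epistatic) signal the linear kernel cannot.

## The Hadamard family

With records ordered environment-major, the models share the fixed part
$\mu\mathbf{1} + Z_E\beta_E$ (environments as fixed effects; the package
reports $\mu$ and $\beta_E$ under a sum-to-zero constraint for
identifiability, fitted with a flat prior) and combine the random terms

| model | random terms | covariances |
|-------|--------------|-------------|
| MM    | $Z_g g$ | $\sigma_g^2 K$ |
| MMl   | $Z_g g + Z_g l$ | $\sigma_g^2 K$, $\sigma_l^2 I$ |
| MDs   | $Z_g g + ge$ | plus $\sigma_{ge}^2$, one variance for all environments |
| MDsl  | $Z_g g + ge + Z_g l$ | |
| MDe   | $Z_g g + gE$ | per-environment variances $\sigma_{gE_j}^2$ |
| MDel  | $Z_g g + gE + Z_g l$ | |

all with homogeneous residual variance $\sigma^2$. The main effect's
expanded covariance $Z_g K Z_g'$ has between-environment blocks that
exchange information across environments; its single multiplier
$\sigma_g^2 \ge 0$ is why this family cannot represent negative
between-environment genetic covariances. The G×E deviations are confined to
the within-environment diagonal blocks — the Hadamard product of
$Z_g K Z_g'$ with $Z_E Z_E'$. The iid intercept $l$ captures line-level
genetic variation the marker kernel does not explain; under an l-model the
covariance of one line's records across environments becomes
$\sigma_g^2 K_{ii} + \sigma_l^2$.

### Gibbs sampling on the complete grid

The sampler operates on the complete $n \times m$ line-by-environment grid.
Cells that are structurally unobserved (trial unbalance) or masked for
cross-validation are latent and re-imputed from the current model state every
iteration (data augmentation). On the complete grid every full conditional
becomes diagonal after rotating lines into the eigenbasis of $K$
($K = UDU'$, effects sampled as $Ub$ with independent prior variances
$\sigma^2_k D$), so one iteration costs a handful of $n \times m$ matrix
products. Two consequences the tests rely on:

* masked phenotypes never enter any likelihood term — perturbing them leaves
  the chains bit-identical under a fixed seed; and
* posterior means are exactly invariant to the input record order, because
  the internal representation is the canonically ordered grid.

Variance components get scaled-inverse-chi-square priors with conjugate
full conditionals; eigenvalues below $10^{-10}\lambda_{\max}$ are truncated.
Predictions are posterior means of $\mu + Z_E\beta_E + \sum \text{random
effects}$ (residual excluded): Pearson accuracy is unaffected in expectation
by the zero-mean residual draw, matching standard practice.

### Priors

The defaults are weakly informative and data-scaled, in the Bayesian-GBLUP
tradition: $\nu = 5$ for each model-wide component, with the scale set so
the prior mode equals $\mathrm{var}(y) R^2 / k$ ($R^2 = 0.5$ split equally
over the $k$ non-residual terms) and $\mathrm{var}(y)(1 - R^2)$ for the
residual. One exception, adopted after a bias analysis: the
environment-specific G×E variances of MDe/MDel are informed by a single
environment's records each, and a $\nu = 5$ prior carrying the full term
mode measurably inflates their posterior means when the truth is small. They
therefore get $\nu = 3$ with the deviation-term mode split across the $m$
environments. All priors are overridable, and are always computed from
training records only so cross-validation masks cannot leak through prior
scales. `prior_sanity()` checks the sampled prior moments against the
closed-form mean $S\nu/(\nu-2)$.

Default chain settings are 12,000 iterations, 2,000 burn-in, thinning 5;
tests and the acceptance script use shorter chains (stated with each call)
because the eigen-rotated sampler mixes quickly — fixed-variance runs agree
with the direct mixed-model-equation solve to about 0.01 at 20,000 kept
samples.

## The Kronecker family

MUC models the stacked genetic values as $u \sim N(0, U_E \otimes K)$ with
$U_E$ an unstructured m×m between-environment covariance, heterogeneous
diagonal residual covariance $\Sigma \otimes I$, and (MUCf) an additional
intercept-level term $f \sim N(0, F_E \otimes I)$. Because the off-diagonals
of $U_E$ are free parameters, this family can represent negative genetic
correlations between environments — the regime where the Hadamard family's
$\sigma_g^2$ collapses to its boundary at zero.

The sampler again rotates lines into the kernel eigenbasis, where rows
decouple; the row-specific m×m full conditionals are vectorized by whitening
with $\Sigma^{-1/2}$ and diagonalizing the resulting m×m pencil once per
iteration. $U_E$ and $F_E$ get inverse-Wishart priors (df $= m + 2$, scale
$0.5\,\mathrm{diag}(\text{per-environment phenotypic variance})$); each
$\Sigma_{jj}$ a scaled-inverse-chi-square. Inverse-Wishart draws are
positive definite by construction; a jitter counter (`n_jitter`) records the
rare numerically singular case. Unbalanced and masked cells are
data-augmented so the Kronecker algebra stays balanced.

One identifiability fact worth knowing: within an environment, $F_{E,jj}$
and $\Sigma_{jj}$ are confounded (both iid over lines). The data identify
the off-diagonals of $F_E$, the off-diagonals of $U_E$, and per-environment
totals; the package's tests assert exactly those quantities.

## Cross-validation

`make_partitions()` implements the two standard schemes: CV1 draws whole
lines into the test set (untested lines — the iid intercept cannot help
here, since it carries no between-line information), CV2 draws individual
records (sparse testing — the intercept transfers a tested line's residual
genetic value across environments). Default: repeated random 80/20 splits;
disjoint k-fold splits are available behind a flag, as is
environment-stratified CV2 sampling (the default samples uniformly over
records). Partitions are deterministic under a seed and serializable to
JSON so different engines can reuse identical masks. `evaluate_cv()` fits
every model on identical masks and reports the per-environment mean and SD
(across partitions) of the Pearson correlation between observed and
predicted test values; environment-partition cells with fewer than two
usable test records are skipped and counted. A precondition enforces at
least two test and one training record per environment per partition
(resampling, with a counter).

## The synthetic trial generator

`simulate_trial()` draws every random component from its stated normal law.
True kernel-structured effects are drawn in the kernel eigenbasis, so
$\mathrm{Var}(g) = \sigma_g^2 K$ holds by construction rather than only in
expectation over marker sampling. Design choices that matter:

* **Family structure.** `simulate_markers()` can group lines into families
  with Balding–Nichols per-family allele frequencies (default differentiation
  0.15 in the recovery scenarios). This is not decoration: with independent
  markers and no families the realized $K$ is numerically close to $I$, and
  the kernel main effect $g$ becomes statistically indistinguishable from
  the iid intercept $l$ — no sampler could recover their split. Breeding
  populations are structured into families, so the structured default is
  also the realistic one.
* **Genetic residual via rank deficiency.** The intercept $l$ stands for
  genetic variance the markers do not capture. In scenarios meant to show
  the intercept's predictive value under CV2, the generator uses fewer
  markers than lines ($p < n$), so part of the iid signal lies outside the
  kernel's column space; with $p \gg n$ a full-rank kernel absorbs an iid
  intercept almost entirely and the intercept models show no advantage.
* **Epistasis.** An `epistasis_fraction` reallocates that share of each
  kernel-structured variance to a component with covariance proportional to
  the elementwise square $K \circ K$ (normalized to unit mean diagonal) —
  the covariance of pairwise marker-product effects, which the Gaussian
  kernel can exploit and the linear kernel cannot.
* **Unbalance** is applied by deleting cells to per-environment target
  counts after the balanced grid is drawn.
* **Presets** (`HEL_like`, `USP_like`, `WHE1_like`, `WHE5_like`) reproduce
  published trial geometries — 452 maize hybrids over 5 unbalanced sites
  (counts 247/330/452/367/330), 739 hybrids over 4 environments
  (731/732/731/737), 599 and 807 wheat lines over 4 and 5 balanced
  environments — with variance magnitudes borrowed from published estimates
  (e.g. the maize MDs-GK scales σ² ≈ 0.278, σ²g ≈ 0.938, σ²ge ≈ 0.525,
  and a wheat-like regime where one environment correlates negatively with
  the rest). These are scenario calibrations, not reproduction targets.

What the generator does **not** emulate: linkage disequilibrium and genetic
maps, selection, environment-specific kernels, non-normal residuals, and
stage-1 experimental-design error structure (inputs are assumed to be
adjusted means). Passing recovery tests therefore demonstrates correctness
of the samplers and identifiability under the stated covariance structures,
not robustness to everything field data can do.

## Numerical choices and degenerate inputs

* Kernel validation: symmetry within 1e-10; eigenvalues at or above
  −1e-8·λmax, otherwise the kernel is rejected rather than clipped; GK
  entries must lie in (0, 1] with unit diagonal.
* Eigen truncation in both engines: eigenvalues below 1e-10·λmax are
  dropped; the corresponding coordinates are pinned at zero.
* All lines genetically identical → the Gaussian kernel's median distance is
  zero → an error naming the degeneracy.
* Monomorphic or all-missing markers are removed by QC; if nothing survives,
  an explicit error.
* A single environment makes the unstructured model undefined → refused.
* Divergence (non-finite state) aborts with the iteration index; in
  practice the conjugate updates keep every draw finite and positive.
* Deterministic replay: the fit seeds R's RNG once and draws in a fixed
  order whose count does not depend on data values, so identical seed and
  configuration reproduce bit-identical chains.

## Scale of the shipped experiments

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a few minutes: oracle comparisons at
n = 30 lines with 20,000 kept samples; parameter recovery at n = 400 lines,
m = 4 environments, chains of 1,200 (shortened but verified against longer
chains); accuracy orderings at n = 250–300 lines and 6–10 partitions.
Published analyses of this kind use 50 partitions and full-length chains;
nothing in the implementation is specific to the reduced sizes.

## Known limitations

* The Hadamard family assumes homogeneous residual variance across
  environments; heterogeneous residuals live only in the Kronecker family.
* MUC/MUCf cost grows with m³ per row update and the models are not
  recommended for many environments (a factor-analytic covariance would be;
  it is out of scope here).
* The intercept-vs-residual split within an environment (MUCf) and the
  kernel-vs-intercept split (l-models with near-identity kernels) are
  weakly identified by design of the models themselves; the package reports
  what the data identify and the vignette's tests are written against those
  quantities.
* Pedigree kernels, VCF/PLINK parsing, bandwidth estimation beyond fixed
  h, and additional fixed covariates are not implemented.
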
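---
title: "Multiblock latent-variable screening of adjuvant candidates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock latent-variable screening of adjuvant candidates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjuscreen)
```

This vignette is the package's account of the science it implements: the
statistical models, the assumptions they lean on, the tunable parameters and
their defaults, what the synthetic cohorts do and do not emulate, and the
design choices made where the design was genuinely open.

## The screening problem

A candidate adjuvant library is profiled three ways in vitro — human PBMC
cytokine/chemokine/growth-factor secretion, mouse splenocyte cytokine
secretion, and the distribution of nano-sized particles over 16 gates of a
log-scale FSC/SSC scatter plot — and in vivo by six antigen-specific
endpoints (fold-change total IgG, IgG1, IgG2c titers against the
antigen-alone group; background-subtracted IgE, IL-13, IFN-γ). The goal is a
small set of in vitro parameters, and thresholds on them, that screen for
substances with high in vivo adjuvanticity. Two features of the data shape
the statistics: there are more measured features than substances in some
blocks (so classical CCA is ill-posed), and the informative signal is
expected to be sparse (a few cytokines and particle populations carry it).

## Preprocessing

**Endpoint titers.** The titer is the reciprocal plasma dilution at which
the ELISA absorbance curve crosses a cutoff (OD450 of 0.2). `titer_from_od()`
interpolates linearly in (log10 dilution, OD) between the two measured
points bracketing the cutoff — "log-linear" read as log on the dilution
axis, because titers are reported on the dilution scale and ELISA response
is near-linear in log dilution over the transition region. Series entirely
below (or above) the cutoff are censored at the smallest (largest) dilution
and flagged rather than extrapolated. With a non-monotone series the first
crossing from the low-dilution end is used, with a warning; exact hits of
the cutoff at a measured point are returned as-is.

**Group summaries.** Fold changes are ratios of group arithmetic means
(`fold_change`), and background subtraction is a difference of group means
floored at zero (`background_subtract`): downstream blocks assume
non-negative concentrations, and per-animal ratios are deliberately out of
scope. Whether one should average before or after ratio-taking is not
determined by the data model; group-mean ratios are the package's choice and
the alternative is not emulated.

**Scaling.** All latent-variable fits operate on columns standardized to
mean 0, SD 1 (n − 1 denominator). Zero-variance columns cannot be
standardized and are dropped with a warning (`scale_columns`), never
imputed.

## Gating

Events are assigned to a 4 × 4 grid on (log10 FSC, log10 SSC); the default
edges carve the 4-decade instrument range into equal decades, the only
binning consistent with a 4-digit log display. Cells are half-open
`[low, high)` with the top edge closed; events outside the grid are counted
as out-of-range, not clipped. Labels run row-major A–P with rows ordered by
descending SSC and columns by ascending FSC, so A is FSC-low/SSC-high and M
(row 4, column 1) is the smallest/least dense population. This layout is a
reconstruction from the populations' verbal descriptors (M and I as
FSC-low/SSC-low, D/H/L as FSC-high, B/C/G as SSC-high), since exact gate
coordinates for such instruments are conventionally chosen per experiment.

Blank correction subtracts the paired buffer-only acquisition per
population, clamped at zero (counts cannot be negative); percentages are
taken over the sum of the 16 corrected gate counts, making the profile a
composition over the gates. The percentage profile is therefore invariant
to duplicating all events, and an all-zero corrected profile is returned as
all zeros with a zero total rather than an error.

## The latent-variable models

**Regularized CCA.** `rcca()` computes weights from the SVD of
\((\Sigma_{xx}+\lambda_1 I)^{-1/2}\,\Sigma_{xy}\,(\Sigma_{yy}+\lambda_2 I)^{-1/2}\).
Reported canonical correlations are the training correlations of the paired
scores, which coincide with the singular values in the classical limit
λ → 0 and keep the model honest in the regularized regime. At λ → ∞ the
weight directions converge to the singular vectors of the cross-covariance
(the PLS limit); both limits are verified against independent references in
the test suite. The ridge variant (not the shrinkage-estimator variant) was
chosen for its closed form and its two analytically known limits.
`tune_rcc()` grid-searches (λ₁, λ₂) by 5-fold cross-validation on the
held-out first canonical correlation, with ties broken towards the smallest
total penalty; the default grid is logarithmic over 10⁻⁴…10⁰, a range that
brackets the useful amount of ridge for correlation-scale data. The
feature-feature heatmap values (`similarity_matrix`) accumulate, over
dimensions, the product of each feature's correlation with the per-dimension
consensus score (average of the paired scores); the number of dimensions is
exposed because display conventions differ.

**Sparse multiblock PLS.** Per component, each block weight is updated as
`soft_select()` — keep the top-keepX absolute entries, soft-threshold by the
largest excluded magnitude, re-normalize — of the design-weighted sum of
covariances between the block and the other blocks' scores, with the
outcome carried as an additional densely weighted block. Convergence is
declared when no score moves more than `tol = 1e-6` in L2 norm
(`max_iter = 500`; non-convergence is an error carrying the last iterate,
not a silent truncation). Deflation is regression-mode: each block on its
own score, the outcome on its regression onto the consensus (average) block
score, which reduces exactly to textbook NIPALS PLS2 for a single dense
block — the equivalence is pinned in the tests against an independent NIPALS
implementation. Ties in the top-k selection are broken by lowest feature
index, and every stored weight vector is oriented so its largest-magnitude
entry is positive, so repeated runs are bit-identical. When all survivors of
the soft-threshold are tied with the threshold itself (which would zero the
vector), the survivors keep their magnitudes; this keeps the degenerate case
well-defined without affecting generic data.

**Discriminant variant.** `block_splsda()` dichotomizes nothing itself; the
caller supplies two classes (conventionally `dichotomize()`, high/low at the
cohort mean of an endpoint, ties going low). The outcome block is the
centered class-indicator matrix. For every selected feature the dominant
class — the class with the larger within-class mean — is recorded, which is
the information loading plots color: a low-dominant particle population is a
negative screening parameter. `tune_block_splsda()` uses stratified
folds × repeats (default 5 × 3) cross-validation, classifying held-out
substances by nearest class centroid in the space of block-averaged
component scores, and minimizes the balanced error rate with ties going to
the sparsest candidate. The centroid metric and the balanced error rate were
chosen because the high/low split at a mean is often unbalanced; both are
stated rather than configurable-by-accident.

**Design matrix.** The connection design defaults to outcome-to-every-block
weight 1 and block-to-block weight 0.1, favoring discrimination over
inter-block agreement; it is fully configurable because no canonical value
exists for these data.

**PCA.** `pca()` is an SVD of the centered (optionally standardized) matrix
with the same largest-entry-positive sign convention; explained-variance
ratios are computed over the full spectrum so a truncated model reports
honest fractions.

## The screening battery

`threshold_screen()` passes values ≥ threshold in the positive direction and
values < threshold in the negative direction — strictness at the boundary is
a free choice, resolved so a substance exactly at a negative threshold is
rejected (the conservative screen). Auto thresholds are arithmetic means
over all substances jointly (extracts and controls). `two_step_screen()` is
the logical AND of the negative screen and the positive screen, with
survivor counts per step; its mask is by construction a subset of the
negative step's. Separation between screened and non-screened substances is
a pooled-variance unpaired t test (`separation_test`; Welch available behind
a flag, pooled is the default because the screening tables report plain
unpaired t tests), and two-step p values compare pass-both against all
others, with the survivors-only comparison available to the caller by
masking. `pca_discriminate()` splits component-1 scores at their mean (zero
under centering, kept as a mean for robustness) and anchors the orientation
to the designated positive parameters: the side with the higher mean of
those parameters is the screened group. An anchored orientation is necessary
because a principal component's sign is arbitrary; note the anchor follows
the data, so globally negating the input flips which substances are
screened while preserving the partition. `screening_report()` runs the
battery per endpoint, marking endpoints whose model selects no
positive-direction cytokine parameter as not applicable rather than
screening on a negative parameter alone.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions the pipeline is meant
for: 73 extracts plus 7 control adjuvants; 18 human and 23 mouse cytokines;
16 particle populations; five planted positive cytokines per block (on the
columns named after the screening candidates: hGCSF, hGMCSF, hMIP1b, hIL4,
hIL5 and mRANTES, mMIP1b, mGMCSF, mIL4, mIL5); one planted negative particle
population (M). Two independent standard-normal latent factors drive the
data — positive `z_pos`, negative `z_neg` — rather than one bipolar factor,
because the negative particle parameter is meant to carry information
independent of the cytokine signal; that independence is what lets a
two-step screen beat a one-step screen, and it is asserted as a property
(|r| < 0.05 at n = 10,000).

Cytokine blocks are log-normal (`exp` of effect_pos·z_pos + Gaussian noise
on informative columns, pure noise elsewhere): concentrations are
non-negative and right-skewed. The particle block is a softmax of Gaussian
log-abundances scaled to percentages (rows sum to 100 exactly), with the
negative population's log-abundance raised by effect_neg·z_neg. Outcomes are
`exp(w_pos·z_pos − w_neg·z_neg + noise)`. Controls are drawn from the same
model with a +1 SD shift on `z_pos`, mimicking the potent adjuvanticity of
known adjuvants. Defaults `effect_pos = effect_neg = 1`,
`noise_sd = 0.5`, `w_pos = 1`, `w_neg = 0.5` give planted-feature
correlations in the 0.5–0.8 range typical of a usable biomarker; no
distributional summaries of the real measurements are published, so these
are realistic free knobs, chosen once, not calibrated to the study. All
randomness flows from the single config seed through a restored-state local
generator, so identical configs give bit-identical cohorts.

What the generator does **not** emulate: plate and batch effects,
donor-to-donor PBMC variability, detection limits and censoring in the
cytokine assays, instrument spillover, or correlated multi-population
particle signatures. Passing tests therefore demonstrate that the
algorithms recover the structure they assume, not that real cohorts satisfy
those assumptions.

Raw-data fixtures follow the same philosophy: `generate_event_table()` draws
a multinomial over populations and places events uniformly (log scale)
inside their cells, so re-gating recovers the draw exactly — a sharp oracle
for the gating chain; `generate_dilution_series()` builds monotone OD curves
whose bracketing segment passes exactly through the cutoff at the requested
titer, so titer interpolation is exactly invertible.

## Problem sizes and runtime choices

The validation battery runs at the cohort scale the method targets
(n = 80, 18 + 23 + 16 features): 20 cohorts for planted-parameter recovery,
100 for the two-step versus one-step comparison, 50 two-cluster cohorts for
PCA discrimination, 100 random titers for the interpolation round trip.
These sizes give Monte-Carlo error comfortably below the asserted margins
while keeping the whole suite in seconds.

## Interfaces

The package's surface is its functions — the fitting functions return
classed objects with `print`/`summary`/`coef`/`predict` methods, and
`run_pipeline()` orchestrates simulate/read → assemble → integrate → screen
→ report with TSV artifacts and a `key: value` run manifest (tool version,
input digests, hyperparameters, seed). A subcommand shell wrapper was
considered and deliberately omitted: the natural unit of use is an R
session or script, as with the established multivariate-omics packages, and
`scripts/acceptance.R` demonstrates the scripted entry point.

## Known limitations

* Two classes only in the discriminant variant; multi-class screening is
  out of scope.
* The rCCA tuning score is the first canonical correlation only; multi-
  dimension tuning criteria are not implemented.
* `pca_discriminate()` requires at least two parameters and breaks ties at
  the component-1 mean in favor of the screened side.
* Censored titers are returned flagged but the screening battery does not
  model censoring; callers should exclude or impute flagged substances.
* The generator's compositional particle block plants a single negative
  population; screens built on multi-population signatures are untested
  against truth.
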
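---
title: "Methods: models, parameters and design choices in poearray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in poearray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poearray` analyzes dye-swapped two-color spotted-microarray direct
comparisons between genotypes that differ only in the parent-of-origin of
their sex chromosomes. This vignette is the package's account of the
science behind each stage: what is modeled, which parameters matter, what
the synthetic generator does and does not emulate, and where the design
was genuinely open.

## Spot quality control

A printed spot contributes one measurement per channel (Cy3/Cy5). The
quantification summaries carried per spot and channel are the foreground
median, foreground pixel count, the fraction of foreground pixels above
background median + 2 background SD, and the background median and SD.
Three retention criteria are applied:

1. ≥ 70% of foreground pixels above background + 2 SD, in **at least one**
   channel. The threshold is inclusive (0.70 passes).
2. Foreground median ≥ 3 × background median, in at least one channel
   (inclusive; a zero background with positive foreground passes — the
   ratio is infinite).
3. Strictly more than 30 foreground pixels. The quantification dialect
   carries a pixel count per channel, so this is evaluated on both
   channels' counts (a property of the spot); if a source provides one
   channel-independent count it occupies both columns and the rule is
   unchanged.

A spot is retained iff all three hold. Filtering is idempotent, preserves
spot order, and reports per-criterion failure counts per array.

## Ratio construction and two-pass normalization

M = log2(fg₁/fg₂) and A = ½(log2 fg₁ + log2 fg₂) are computed from
foreground medians **without background subtraction**: background enters
only the QC rules. Subtraction creates negative intensities exactly in the
dim spots QC is about to remove, and the two-pass loess removes any
additive intensity-dependent distortion that subtraction would target. A
spot with nonpositive foreground in either channel is dropped and counted.

Two successive loess smoothings (local linear, tricube weights, robust
iterations) are then applied, in a fixed order:

* **Intensity pass** — M is replaced by the residual of loess(M ~ A) with
  span 0.3. This removes smooth dye bias of any shape a cubic-scale curve
  can take.
* **Spatial pass** — M is replaced by the residual of a 2-D loess over
  the slide coordinates with span 0.002, i.e. a fraction 0.002 of spots
  per local neighborhood (≈ 43 spots on a 21,487-spot array). Note the
  neighborhood implied by span 0.002 is ~43 spots, not the ~250 sometimes
  quoted for this span at this array size; we follow the explicit span.
  If span·n < 10 the span is widened to 10/n with a warning; degenerate
  (constant) coordinates are an error.

**Leverage correction.** Smoother residuals shrink genuine spot-level
deviations: each point's fitted value contains a fraction of the point
itself (its leverage), so the residual of a spot carrying a true
biological effect understates that effect by ≈ enp/n, the smoother's
equivalent number of parameters over the number of spots. For the spatial
pass at span 0.002 this is ~8% — enough to visibly bias group medians.
Residuals are therefore divided by (1 − enp/n), the average leverage
complement (the same logic as standardized residuals r/(1 − h)). The
switch `bias_correct = FALSE` restores raw residuals. The correction is
first-order: it uses the average leverage, not per-point values, and at
small n with widened spans it inflates residual noise noticeably — one
reason the package's calibration simulations run at full array scale.

## The dye-swap linear model

Each array directly contrasts the two genotypes; the dye orientation
o_j ∈ {+1, −1} records which genotype is in channel 1. For gene *g*, the
orientation-corrected values o_j·M_gj are i.i.d. around the
parent-of-origin log2 fold-change, so the per-gene model is a one-sample
location fit: log2FC_g is the mean, s²_g the sample variance on
d_g = n_g − 1 df (genes with fewer than two non-missing arrays are
untestable; there is no imputation). Dye bias cancels by the swap design;
batches are pooled after a concordance check (the batch-wise Spearman ρ
of fold-changes is always computed and reported).

**Variance moderation.** With 8 arrays, gene-wise variances are noisy.
They are shrunk by the standard empirical-Bayes scaled-F model:
s²_g ~ s₀²·F(d_g, d₀). Writing e_g = log s²_g − ψ(d_g/2) + log(d_g/2),
the model implies E[e] = log s₀² + ψ(d₀/2) − log(d₀/2) and
Var[e] = ψ′(d₀/2) + ψ′(d_g/2); the two moments give d₀ by inverting the
trigamma function (Newton iteration) and s₀² in closed form. The
posterior variance is s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g) and the
moderated t_g = log2FC_g/(s̃_g/√n_g) has d₀ + d_g df. When the observed
spread of log s² does not exceed what sampling alone implies, d₀ = ∞ and
the pooled mean variance is used (with a warning). At d₀ = 0 the
statistic reduces exactly to the ordinary one-sample t. The test suite
cross-checks this fit against an independent reference implementation of
the same model.

**Error control.** q-values are Benjamini–Hochberg. An empirical FDR is
computed alongside by sign-flip permutation: each array's orientation
sign is flipped under random patterns (identity excluded) — the natural
null for a direct two-color comparison, under which true effects cancel
but the correlation structure of the arrays is preserved. For threshold
τ, FDR(τ) = (mean null count of |t| ≥ τ)/(observed count), capped at 1
and monotonized; each gene is evaluated at its own |t|. The same
machinery runs with the robust median-based fold-change estimator
(`statistic = "median"`), which serves as the package's independent
second estimator; its rank concordance with the linear-model estimate is
reported as a standard consistency check.

## Tissue specificity

The atlas preprocessing follows the standard recipe: expression values
with an "absent" detection call are set to 1, and for genes with several
probe sets only the one with the strongest signal — read as the largest
total value across tissues (a max-based alternative is a config switch) —
is retained. τ = Σᵢ(1 − x̂ᵢ)/(N − 1), x̂ᵢ = xᵢ/max, is computed on
**log2** values, so the absent floor maps to 0 and fold-differences among
well-expressed tissues are downweighted; whether the original analyses
used raw or log intensities is not stated, so the raw-scale variant is
available (`log = FALSE`). Under the log2 convention τ is invariant to
raising all values to a positive power (not to scaling). A gene is
tissue-specific when τ > 0.9 strictly and the profile maximum is unique;
ties are never specific. A uniform profile, including all-absent, has
τ = 0 by definition.

The quantitative enrichment score for tissue *t* is log2(value_t) minus
the mean log2 value of the other 19 tissues — zero for a uniform profile.
The source analyses reference such a measure without defining it; this
log-ratio-to-mean definition is this package's choice.

## The statistical battery

* 2×2 tables report the **sample** odds ratio ad/(bc) — undefined (NA)
  when b or c is zero or a row is degenerate — with the two-sided Fisher
  exact P (sum of probabilities of tables no more probable than the
  observed). The sample OR, not the conditional-MLE OR, is what
  reproduces the published values for these tables.
* Chromosome-arm tables count DE genes per arm including an "Other"
  category for probes unmapped to the assembled reference genome;
  **percentages use mapped genes only as denominator**. Each mapped arm
  gets a two-category χ² goodness-of-fit of the DE set against the
  background proportions, BH-adjusted across the six arms at 0.05. The χ²
  is uncorrected by default; the Yates-corrected variant is provided
  because the published P = 0.007 for the X-chromosome deficit matches
  the corrected two-category test (0.0071) slightly better than the
  uncorrected one (0.0065) — which variant produced the published value
  is not stated.
* Mann–Whitney group shifts, Spearman ρ (average ranks, t-approximation
  P), exact binomial direction-bias tests, and standard major axis
  regression (slope sign(r)·sd(y)/sd(x), the geometric mean of the two
  OLS slopes) complete the battery.

## The synthetic generator

The generator emulates the targeted study design: 21,487 spots, eight
dye-swapped arrays per contrast (two batches), chromosome-arm proportions
matching the observed all-spot distribution (including ~3% unmapped),
12% testis-specific and 0.8% adult-midgut-specific genes, and an atlas in
which designated genes exceed τ = 0.9 with the maximum in their
designated tissue.

Per-gene true log2 effects are drawn normally per class and the **class
sample medians are pinned exactly** to the configured shifts, so planted
truth is unambiguous for recovery tests. Defaults: testis +0.24, midgut
−0.23, background −0.03. The background is deliberately nonzero: loess
normalization centers each array, so recoverable group medians must be
jointly centered — and the three published group medians (+0.24, −0.23,
−0.03 at 12%, 0.8%, 87.2% prevalence) are indeed consistent with
zero-centered normalized data. Planting the background at 0 would shift
every recovered median by the removed grand mean (~0.027).

Spot construction: channel medians are 2^(A ± M/2) with per-gene baseline
A ~ N(10.5, 1.2²) clamped to [8.5, 14]; M adds the orientation-signed
effect, a per-array cubic dye-bias curve in A (amplitude 0.3 log2 units —
curvature a span-0.3 loess removes comfortably), a per-array smooth
spatial field (low-order polynomial plus one Gaussian bump, amplitude
0.2), and Gaussian noise. Spot summaries (background statistics, pixel
counts, pixel fractions) come from closed-form log-normal pixel
populations rather than simulated pixels, giving exact control of QC:
5% of spots per array are pre-assigned one of three failure modes (low
pixel fraction, dim foreground, too few pixels) and built to violate that
criterion; all other spots are guaranteed to pass all three. Grid
geometry of the original arrays is unknown; the simulator uses a
near-square single-block grid with 150 µm pitch as a free parameter.

**Noise and spread defaults** (per-spot M noise: technical 0.08 +
biological 0.06 in quadrature ≈ 0.10; class effect spread 0.20;
background spread 0.30) were chosen jointly so the generator reproduces
the published study conditions: the Fig-2-style group medians, the
near-total one-sidedness of significant testis-class genes (>90%), and a
rank concordance ≥ 0.99 between the mean-based and median-based
fold-change estimators. The concordance condition binds: for a median
estimator, ρ ≈ 1 − 0.43σ²/(J·Var(true effects)), so at J = 8 arrays the
per-spot noise must be small relative to the spread of true effects.

**What the generator does not emulate.** Real arrays have print-tip
block structure, saturation, correlated background, and a sparser set of
truly nonnull genes; here most genes carry some (small) true effect, so
the fraction of genes passing the 5% FDR is much higher than in typical
real data, and class overrepresentation among significant genes is
correspondingly weaker at reduced scale. Passing recovery tests
demonstrates correctness of the pipeline's computations under the
planted model, not performance on real data. Calibration claims are made
at full array scale (21,487 spots): at a few thousand spots the fixed
spatial span produces ~10-spot neighborhoods whose widened-span fallback
and leverage correction inflate noise — a scale artifact, not a property
of the method.

## Numerical choices and edge cases

* Loess: degree 1, tricube weights, robust ("symmetric") iterations; if
  a perfect first-pass fit makes the robustness weights degenerate, the
  plain least-squares fit (already exact) is used.
* Trigamma inversion: Newton iteration with asymptotic endpoints
  (1/y for small y, 1/√y for large), tolerance 1e-10.
* Largest-remainder rounding apportions class and arm counts; remainder
  ties break by listed category order.
* τ of an all-equal or all-floor profile is 0; argmax ties are never
  specific.
* BH on an empty p-vector returns an empty vector; permutation FDR
  requires ≥10 permutations and warns below 4 arrays (small flip space).
* Determinism: every stochastic step (simulation, permutations) is
  seeded; identical config + seed gives byte-identical output tables.

## Problem sizes used by the checks

The packaged checks simulate at the full 21,487-spot scale for
calibration claims (medians, concordance, direction bias), 2,000–5,000
spots for distributional properties (FDR control, bias removal), and a
few hundred spots for structural tests. The acceptance script runs one
full-scale contrast end to end.

## Known limitations

* The permutation scheme for the empirical FDR is sign-flipping of whole
  arrays; with few arrays the null is coarse (2^J − 1 patterns).
* The leverage correction is global (average leverage), not per-point.
* Batch handling is pooling after a concordance check; no array weights
  or mixed models.
* GEO ingest of the original deposited arrays is a documented manual
  path (the GenePix dialect mapping), not an automated client.
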
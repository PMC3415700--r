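---
title: "Methods: elliptic Fourier analysis of leaf asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elliptic Fourier analysis of leaf asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafasym)
```

`leafasym` quantifies bilateral asymmetry in leaf outlines and tests how it
is modulated by node position along the shoot, by phyllotactic direction,
and by which face of the leaf was scanned. This vignette is the package's
account of the method: the model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
establish.

## From pixels to coefficients

A leaf scan enters as a binary mask. The largest 8-connected foreground
component is kept (extra components under 1% of its size are treated as
scanner dust and dropped with a warning; anything larger is an error, since
two comparable blobs mean the image does not contain exactly one leaf). Its
outer boundary is traced with Moore-neighbour tracing under Jacob's
stopping criterion, giving an 8-connected pixel path that round-trips
exactly through a Freeman chain code. Coordinates are converted at load
time to the mathematical convention (y up, 0-based, pixel centers at
integers) and oriented counter-clockwise, so that mirroring semantics are
unambiguous everywhere downstream. Components touching the image border are
rejected as clipped leaves rather than silently truncated.

The contour is expanded in elliptic Fourier descriptors: per harmonic
$n$ a $2\times2$ coefficient block $(a_n, b_n; c_n, d_n)$ obtained in
closed form for the piecewise-linear, **arc-length parametrized** polygon.
Arc-length (not vertex-index) parametrization matters because diagonal
chain-code steps are $\sqrt2$ longer than axial ones; it also means the
coefficients of an ellipse are *not* the angle-parametrized textbook values
— the truncated series still reproduces the exact geometry, and the test
suite checks the coefficients against an independent quadrature oracle
rather than against the angle-uniform closed form.

Normalization uses the first-harmonic ellipse: a starting-point phase
rotation places $t = 0$ on the semi-major axis, a spatial rotation maps
that axis onto x, and all coefficients are divided by the semi-major
length, leaving $a_1 = 1$, $b_1 = c_1 = 0$, $|d_1| \le 1$. Two deliberate
choices:

* **The 180° ambiguity is resolved by the proximal point.** The package
  must run unattended, so instead of manual orientation the petiole base
  is either supplied (`proximal_point`) or auto-detected as the outline
  extremity farther from the centroid along the major axis; it is mapped
  to negative x (tip at +x). For lanceolate leaves with a petiole, the
  proximal extremity is reliably the farther one because the area centroid
  sits inside the blade.
* **Reflection is never canonicalized.** Mirroring about the
  proximal–distal axis acts exactly as
  $(a,b,c,d) \to (a,-b,-c,d)$; chirality *is* the measured signal, so
  normalizing it away would destroy the study. Consequently $a,d$ span
  bilaterally symmetric and $b,c$ asymmetric shape variance, and averaging
  an outline with its own mirror image cancels $b,c$ identically.

Twenty harmonics are kept by default; reconstruction error is monotone
non-increasing in harmonic count, and at 20 harmonics generated leaf
outlines are reproduced to well under 1.5% of the semi-major axis (about
0.6% in practice), so the truncation is not a limiting factor.

## Shape PCA

Covariance PCA (no rescaling — after size normalization the coefficients
are commensurate, and this matches the conventional EFD workflow) is fitted
separately to the asymmetric subspace ($b_2..b_{20}, c_2..c_{20}$; the
constants $b_1 = c_1 = 0$ and $a_1 = 1$ are dropped as zero-variance
columns, $d_1$ is retained) and the symmetric subspace. The asymmetric
analysis pools both leaf faces, so the data are mirror-complete and every
directional asymmetry appears as paired scores of opposite sign; the
symmetric analysis uses abaxial-top outlines only, since mirror images add
no symmetric information. Eigenvector signs are fixed deterministically
(largest-magnitude loading element positive) so scores are reproducible
across runs and platforms. `reconstruct_at_sd()` re-embeds
$\mu + k\sqrt{\lambda_j}\,v_j$ into a full coefficient set — the other
subspace held at its mean, normalization constants restored — and inverts
the transform, the standard ±2 SD visualization of what each PC encodes.

## Inference

Each response (asymPC1–4, symPC1–4, leaf area) is modeled as a fixed-effects
factorial: `position * phyllotaxy * AdAb` for asymmetric PCs and
`position * phyllotaxy` for symmetric PCs and area (the leaf face cannot
carry symmetric information). Node position is an ordered factor by
default; a numeric-covariate analysis is possible by passing a numeric
column to `fit_anova()`, but positions are a small discrete design variable
and treating them categorically avoids imposing a trend shape.

Model selection is backward and single-term: repeatedly drop the term with
the largest nested-model F-test p-value above `alpha` (default 0.05) among
terms whose removal respects marginality; ties are broken by dropping the
higher-order term first, then lexicographically, so the trace is
deterministic. `forward_check()` then verifies that no excluded term would
enter at `alpha` by single-term addition. Unbalanced data are handled by
the model-comparison structure itself rather than by committing to a fixed
sums-of-squares decomposition. Per-term statistics of the *final* model are
reported as marginal (type-II) F-tests, so a main effect retained only to
support a significant interaction still receives an honest p-value — and in
the publication-style tables such terms are rendered "ns", mirroring the
usual convention. Degenerate situations are handled explicitly: empty
design cells raise an error naming the inestimable term, and on
(near-)perfect fits a term whose removal changes the residual sum of
squares only at rounding-error scale (below $10^{-8}$ of the total SS) is
treated as droppable, with the zero-RSS limit of the F test reported as
$p = 0$ for genuinely load-bearing terms.

The calibration of this procedure is itself under test: with one
two-level factor, the null retention rate over 500 simulated replicates
stays within ±0.03 of `alpha`, and power at a standardized mean difference
of 1.0 with 50 observations per group exceeds 0.99.

Two auxiliary summaries complete the layer: a χ² goodness-of-fit test of
clockwise vs counter-clockwise shoot counts against 50:50 (uncorrected
Pearson statistic, df = 1, two-tailed; with counts in the low tens this
statistic is slightly anti-conservative relative to the exact binomial
test — the suite verifies that every disagreement is in that direction),
and loess trends (span 0.75, degree 2, the method's conventional defaults,
both exposed in `pipeline_config()`) of scores along the node grid with
pointwise standard-error bands.

## The synthetic generator

No leaf scans ship with the package, so `generate_dataset()` produces
labeled datasets with the statistical structure the analysis is designed to
detect, and the tests assert recovery of known truth. A leaf is a petiole
segment plus a lanceolate blade with half-width profile
$w(u) = W\sin(\pi u^{q})$ along relative blade position $u$ (measured from
the blade base); the exponent $q(\text{node}) \ge 1$ increases through the
series, shifting laminar outgrowth toward the tip, while the petiole
fraction rises — the classic heteroblastic progression of outline shape.
Directional asymmetry is injected as a midline bend
$y \mapsto y + \kappa x^2 / L$: a shear, which conveniently cannot
self-intersect the outline, matching the "overall bending" character of the
dominant asymmetric PC. All developmental curves are logistic in an
effective node number, and clockwise shoots are delayed by `delay` nodes —
with `delay = 0` the CL and CC populations are draw-for-draw identical
because each leaf's random stream is seeded from the (shoot, node) stratum
only.

Default study conditions (chosen once, as a plausible emulation of a
resupinate-leaf dataset): blade length rising logistically from 2.5 to
12 cm (first usable leaves are a few cm long), 8 usable nodes per shoot,
fair-coin phyllotaxy per shoot, fixed bend handedness with
$\kappa_{\max} = 0.18$ (tip deflection ≈ 18% of leaf length, a clearly
visible arc), per-leaf fluctuating asymmetry SD 0.03 on $\kappa$, per-image
digitization jitter SD 0.02 cm smoothed along the contour with a
correlation length of 5% of the perimeter (white noise would self-intersect
the outline; smooth noise emulates flattening and tracing error), a
developmental delay of 1.5 nodes for CL shoots, and 150 dpi rasterization.
A `randomize_handedness` switch turns the directional bend into a
fluctuating one — the control in which mirror-pair averaging cancels the
population mean asymmetry, separating directional from fluctuating
asymmetry.

What passing tests show — and what they do not. The generator provides
outlines whose asymmetry, size and shape curves are known exactly, so the
suite can assert that asymPC1 scores track injected $\kappa$ (|r| > 0.9 on
320 leaves), that the ANOVA recovers the AdAb main effect and its
interaction with position, that CC leaves are larger and more asymmetric
than CL at equal mid-series nodes with late-series convergence, and that
position and phyllotaxy main effects on asymmetric PCs are null for
mirror-complete data. It does *not* emulate lobed or serrated margins,
holes, overlapping or torn laminae, perspective or lighting artifacts, or
any within-image segmentation problem beyond additive boundary jitter;
real scans exercise the mask-loading tolerances (dust, polarity, clipping)
in ways the generator cannot.

## Problem sizes and determinism

The shipped validation uses 40 shoots × 8 nodes (640 outlines) for the
end-to-end study, 104 rasterized leaves for the chain-code round-trip
property, 500 replicates for each calibration simulation, and 10,000 draws
for the isotropic-PCA check — sizes at which the measured quantities are
stable at the asserted tolerances while the whole suite runs in well under
a minute. Every stochastic step is seeded; `run_pipeline()` and
`generate_dataset()` are bit-reproducible given their seeds, and
`scripts/acceptance.R` derives all randomness from its `--seed` argument.

## Known limitations

* Shoot identity is a fixed-effects blocking variable at most; no
  mixed-effects model of shoot as a random effect is provided.
* No multiple-testing correction is applied across the nine responses;
  the per-response tables are reported as-is.
* The proximal-point auto-detection assumes the proximal extremity is the
  farther one from the area centroid, which holds for petiolate lanceolate
  leaves but can fail for strongly peltate or orbicular shapes — supply
  `proximal_point` explicitly in that case.
* Compatibility with legacy chain-code file dialects of older EFD software
  is not attempted; the package's own plain-text chain-code format is
  documented and round-trip tested.
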
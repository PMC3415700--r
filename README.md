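# leafasym

Outline morphometrics for leaf-shape **asymmetry** studies in R.

Some leaves are not bilaterally symmetric, and the asymmetry can be
biological signal rather than noise: resupinate leaves (leaves that twist
180° during development, as in *Alstroemeria*) acquire a consistent,
handed bend, and its magnitude can depend on where the leaf sits on the
shoot (node position, with node i nearest the apex) and on the direction of
the phyllotactic spiral (clockwise CL vs counter-clockwise CC). `leafasym`
implements the full analysis pipeline for such studies, from binary leaf
scans to publication-style ANOVA tables, together with a synthetic
two-sided leaf generator so every stage can be validated against known
ground truth.

## The method

Each leaf silhouette is reduced to a closed contour (Moore-neighbour
tracing, Freeman 8-direction chain code) and expanded in **elliptic Fourier
descriptors** (EFDs): truncated Fourier series of the arc-length
parametrized outline,

    x(t) = a0 + Σₙ aₙ cos(nt) + bₙ sin(nt)
    y(t) = c0 + Σₙ cₙ cos(nt) + dₙ sin(nt),    n = 1 … 20.

Coefficients are normalized with the first-harmonic ellipse (starting
point, rotation and size removed; the proximal–distal axis becomes the
x-axis with the tip at +x) so that a₁ = 1, b₁ = c₁ = 0. Crucially,
**reflection is never normalized away**: mirroring an outline about its
proximal–distal axis maps (aₙ, bₙ, cₙ, dₙ) → (aₙ, −bₙ, −cₙ, dₙ), so the
a, d coefficients carry bilaterally *symmetric* shape variance and the
b, c coefficients carry *asymmetric* variance. Scanning each leaf from
both faces (abaxial-top and adaxial-bottom) yields mirror pairs whose
asymmetric coefficients cancel on averaging only if the asymmetry is
fluctuating — a consistent, handed asymmetry survives and shows up as a
leaf-face ("AdAb") effect.

Covariance PCA on each coefficient subspace gives asymmetric and symmetric
shape PCs (with ±2 SD outline reconstructions of each mode), and the PC
scores, together with leaf area, are analyzed with factorial ANOVA
(`position * phyllotaxy * AdAb`) using backward single-term model selection
with nested F-tests (marginality respected, forward verification), plus
loess trends along the node series and a χ² test of CL:CC shoot frequency.

## Worked example

Everything below is synthetic and runs in seconds; with real data you
would start from `read_leaf_dataset("metadata.csv")` (PNG/TIFF masks plus
a CSV of shoot, node, phyllotaxy, side, dpi).

```r
library(leafasym)

ds  <- generate_dataset(synth_config(n_shoots = 12, nodes_per_shoot = 8, seed = 1))
res <- run_pipeline(ds$records, config = pipeline_config(seed = 1, plots = FALSE))
res
#> leafasym pipeline result: 192 outlines, 12 shoots
#>   asymmetric PC1 95.3% | symmetric PC1 89.0% of variance

res$tables$asymmetric
#> # A tibble: 7 × 5
#>   Factor                   asymPC1 asymPC2 asymPC3 asymPC4
#>   <chr>                    <chr>   <chr>   <chr>   <chr>
#> 1 Position                 ns      ns      ns      ns
#> 2 Phyllotaxy               ns      ns      ns      ns
#> 3 AdAb                     3.6e-70 ns      ns      ns
#> 4 Position:phyllotaxy      ns      ns      ns      ns
#> 5 Position:AdAb            2.2e-56 ns      ns      1.8e-05
#> 6 Phyllotaxy:AdAb          1.8e-10 ns      0.04    ns
#> 7 Position:phyllotaxy:AdAb ns      ns      ns      0.0027
```

Reading the table: node position and phyllotaxy by themselves do not shift
asymmetric PC scores (every leaf is scored from both faces, and the mirror
pairs cancel — those rows are "ns" by construction), but the leaf face
("AdAb") term is enormous: the two faces of the same leaf are *not*
mirror-equivalent in score, i.e. the population carries directional,
handed asymmetry. Its interactions with position and phyllotaxy show the
asymmetry growing through the leaf series at a phyllotaxy-dependent rate —
the generator injects exactly this structure (CL shoots developmentally
delayed by 1.5 nodes), and the pipeline recovers it.

```r
res$tables$symmetric
#> # A tibble: 3 × 6
#>   Factor              symPC1  symPC2  symPC3 symPC4 area_cm2
#> 1 Position            3.4e-44 2.5e-12 ns     0.0034 8e-266
#> 2 Phyllotaxy          5.5e-18 ns      ns     0.021  1e-175
#> 3 Position:phyllotaxy 3.5e-05 4.4e-09 ns     0.0004 2.5e-115

chi_square_direction(100, 109)
#> # A tibble: 1 × 5
#>   statistic    df p.value  n_cl  n_cc
#> 1     0.388     1   0.534    100   109
```

Symmetric shape and area change along the shoot (heteroblasty) and differ
between phyllotactic directions at equal nodes — the developmental-delay
signature — while the shoot-level spiral direction itself is a fair coin
(χ² = 0.388, p = 0.53 on 100 CL vs 109 CC shoots).

Figures: `autoplot()` on a `shape_pca` (scree) or a `trend_curve` (loess
band), `plot_pc_shapes()` for ±2 SD outline galleries, and
`superimpose_mean_outlines()` for layered group means.

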
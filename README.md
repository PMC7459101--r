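# radfish

Radial nuclear position and expression-neighbourhood analysis for 3D FISH.

## The problem

During human myoblast (Mb) to myotube (Mt) differentiation, nuclei shrink
and flatten, and specific gene loci move between the nuclear centre and
the periphery while their expression changes. Comparing raw spot
coordinates between the two populations is meaningless — the nuclei differ
in size and shape — so every positional statement has to be made in a
geometry-normalized coordinate system, and positional change has to be
confronted with expression change on the same loci. radfish implements
that joint analysis for anyone working with 3D FISH spot coordinates plus
a normalized expression matrix: image analysts quantifying radial
repositioning, and genome-organization researchers relating it to
TAD-scale expression neighbourhoods.

## What it computes

**Geometry.** Nuclei are ellipsoids (parametric or fitted to binary voxel
masks by second-order moments, a_i = √(5λ_i)). A spot's radial position is

    ρ = |x − c| / R(u),   R(u) = 1 / √(Σ u_i²/a_i²)

the distance from the nucleus centre over the boundary radius along the
ray through the spot. The **normalized distance index** rescales ρ by
dividing the nuclear volume into 10 000 concentric, equal-volume shells:
the index is ρ³ (0 = centre, 1 = border), so spots uniform in nuclear
volume give a flat histogram. Nuclear **flattening** is (c − a)/a from
volume and cross-sectional diameter; locus–centromere distances are
normalized per nucleus by the **Feret diameter** so size changes cannot
masquerade as repositioning.

**Statistics.** Mann–Whitney U (exact by enumeration for small groups,
tie-corrected normal approximation otherwise) for nuclear observations;
Welch t elsewhere; twofold + Benjamini–Hochberg p < 0.01 differential
calls; per-chromosome change coefficient C_co = n_down/n_up with the
0.5 < C_co < 1.5 "intermediate" band; the symmetric expression-change
magnitude K = |log2 fc| and its ~1 Mbp neighbourhood mean K_mean with
Spearman correlation (Fisher-z CI); and the 50 Mbp intra-chromosomal
mobility-threshold contingency.

**Synthetic data.** A seeded generator reproduces the study design end to
end — Mb/Mt morphology presets (970.9 ± 341.3 µm³ / −0.771 ± 0.286 and
811.1 ± 231.1 µm³ / −0.935 ± 0.308), Beta radial laws for probes,
block-correlated expression with known truth — so the whole pipeline is
testable and calibratable offline.

## Worked example

```r
library(radfish)

study  <- simulate_study(n_nuclei = 40, seed = 42,
                         expression_args = list(n_genes = 5000))
report <- run_pipeline(study, run_config(seed = 42))
report
#> <rf_report>
#>   morphology groups: Mb, Mt
#>   differential transcripts: 473 (275 up, 198 down)
#>   probes with positional tests: 2

report$morphology
#> # A tibble: 2 × 6
#>   group     n volume_mean volume_sd flattening_mean flattening_sd
#>   <chr> <int>       <dbl>     <dbl>           <dbl>         <dbl>
#> 1 Mb       40       1065.      374.          -0.775        0.177
#> 2 Mt       40        769.      240.          -0.936        0.0474

report$positional_tests[, c("probe_id", "statistic", "p_value", "n_a", "n_b")]
#> # A tibble: 2 × 5
#>   probe_id statistic  p_value   n_a   n_b
#>   <chr>        <dbl>    <dbl> <int> <int>
#> 1 SHIFTED        311 6.37e-23    80    80
#> 2 STABLE        3049 6.08e- 1    80    80
```

The simulated study plants one probe that relocates outward on
differentiation and one stable control; the pipeline recovers exactly
that: the SHIFTED probe's Mb-vs-Mt index distributions differ at
p ≈ 6e-23 while the STABLE control does not (p ≈ 0.61). The morphology
table shows the smaller, flatter Mt nuclei the presets encode.

The expression side, on its own:

```r
e   <- simulate_expression(seed = 42)          # 20000 genes, 1 Mbp blocks
goi <- sample_goi(e, 11)                       # 8 changed + 3 stable loci
kt  <- neighborhood_k_mean(e, goi, window_mbp = 1)
correlate_kgoi_kmean(kt)
#> Spearman rho = 0.809, 95% CI (0.407, 0.949), p = 0.002559, n = 11
```

Genes of interest that change expression sit in neighbourhoods that
change with them — the block structure the generator planted, recovered
as a strong K_GOI/K_mean rank correlation.

Plots: `plot_radial_distribution()`, `plot_k_correlation()`,
`plot_chromosome_activity()`, and `autoplot()` on summaries. Fitted-style
objects support `tidy()`/`glance()`.

A thin CLI over the same functions ships at
`system.file("cli/radfish.R", package = "radfish")` with `simulate`,
`radial`, `expression` and `report` subcommands.

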
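---
title: "Methods: radial nuclear position and expression-neighbourhood analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial nuclear position and expression-neighbourhood analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radfish)
library(dplyr)
```

radfish quantifies *where* gene loci sit inside the interphase nucleus and
how positional change relates to expression change, in the setting of human
myoblast (Mb) to myotube (Mt) differentiation. This vignette is the
package's own account of the models, the parameters that matter, the
synthetic-data generator and its limits, and the numerical choices made
where the design was genuinely open.

## The geometric model

Every nucleus is represented as an ellipsoid: a center in µm, semi-axes
`a >= b >= c`, and a rotation matrix mapping principal-axis coordinates to
the lab frame. Models come either from a parametric description (a nucleus
table) or from a binary voxel mask by the method of second-order moments:
the centroid gives the center, and each eigenvalue of the voxel covariance
maps to a semi-axis via `a_i = sqrt(5 * lambda_i)` (the second central
moment of a solid ellipsoid along a principal axis is `a_i^2 / 5`). A
per-voxel variance term `d^2/12` per lab axis compensates for voxel-center
sampling. Moments are fast and deterministic; no iterative surface fitting
is involved. For near-spherical masks the eigenvectors carry no
orientation information, so the orientation falls back to the identity.

The reported volume of a mask fit is the *mask* volume (voxel count times
voxel volume), not the model volume, so segmentation and model never
disagree silently; the Feret diameter of a model is `2a`.

### Radial ratio and the normalized distance index

A spot's radial position is the ratio `rho` of its distance from the
nucleus center to the boundary radius *along the ray through the spot*
(not a mean radius): in the principal frame with spot vector `v`,
`rho = sqrt(sum((v_i/a_i)^2))`, which is 0 at the center and 1 on the
border along every direction. Fitted ellipsoids do not perfectly contain
every segmented signal, so spots with `1 < rho <= 1.05` (tolerance
configurable) are clamped to 1 with a warning and anything further out is
an error naming the spot.

The **normalized distance index** rescales `rho` by the isovolumetric
shell construction: the nuclear volume is divided into `n_shells`
(default 10000) concentric shells of equal volume. In the default
`"volume"` mode the continuous index is `rho^3`, because the volume
enclosed within radial ratio `rho` of an ellipsoid is the fraction `rho^3`
of the total. The decisive property is that a spot population *uniform in
nuclear volume* has a flat index distribution, so departures from
uniformity are directly readable from the index histogram. A `"linear"`
mode (`index = rho`, equal-width shells) is provided because published
centre-to-periphery profiles do not always state which scale they use;
every output table records the mode. The volume-mode index is exactly the
cube of the linear-mode index.

```{r index-example}
normalized_distance_index(c(0, 0.5^(1/3), 1))
```

### Flattening

Flattening is computed from nuclear volume and the cross-sectional
(equatorial) diameter: with `a = d/2` and the polar radius
`c = 3V/(4*pi*a^2)` of the equivalent oblate spheroid,
`f = (c - a)/a` — 0 for a sphere, increasingly negative for flatter
nuclei. The defining convention in the upstream literature could not be
confirmed, so this one was chosen to reproduce the *sign and ordering* of
the reference values (both groups negative; the differentiated group more
negative). It is a convention, stated in the documentation, and
`flattening()` is a pure function, so an alternative convention can be
layered on top. Flattening is invariant to isotropic scaling, which the
test suite asserts.

An important consequence, discussed under the generator below: under this
convention the reference group means (−0.771 Mb, −0.935 Mt) sit close to
the physical lower bound of −1 (`c > 0`), i.e. they describe strongly
flattened nuclei.

### Feret normalization of distances

Locus-centromere distances are divided by the per-nucleus Feret (maximum
caliper) diameter, so that global size differences between Mb and Mt
nuclei cannot masquerade as locus repositioning. For masks, the Feret
diameter is computed from directional extreme voxels over a deterministic
fan of 512 directions — exact for convex shapes up to voxel resolution —
rather than a full 3D convex hull.

## Statistics

* **Mann-Whitney U** for nuclear observations (indices, normalized
  distances). For `min(n_a, n_b) <= 8` the two-sided p-value is computed
  by full enumeration of group assignments (valid under ties); larger
  samples use the normal approximation with tie and continuity
  correction. The enumeration branch is cross-checked against
  `wilcox.test(exact = TRUE)` on tie-free cases in the test suite.
* **Welch's t-test** for non-rank comparisons.
* **Differential expression**: fold change is `2^(mt - mb)` (Mt over Mb,
  so values > 1 mean up in myotubes), the filter is *at least twofold*
  (inclusive) with Benjamini-Hochberg adjusted `p < 0.01` (exclusive).
* **Change coefficient** `C_co = n_down/n_up` per chromosome;
  `0.5 < C_co < 1.5` defines the balanced ("intermediate") group, and the
  boundaries fall to the dominant groups because the defining interval is
  open. Chromosomes with no upregulated transcripts get an infinite
  coefficient and the group `undefined` rather than a misleading ratio.
* **K factor** `K = |log2(fc)|` (bits) makes up- and downregulation
  commensurable. `K_mean` averages the K factors of all genes on the same
  chromosome whose midpoint falls within a centered window (default width
  1 Mbp; per-gene widths of 0.95 or 1.5 Mbp ship with the locus panel).
  The gene of interest is excluded from its own neighbourhood by default
  to avoid self-correlation; a flag includes it. Overlap-based membership
  is available as a config alternative to midpoint membership.
* **Spearman correlation** of `K_GOI` vs `K_mean` with a 95% CI from the
  Fisher z-transform (`atanh(rho) +/- 1.96/sqrt(n-3)`) and a two-sided p
  from the t-approximation. At `rho = 0.83, n = 11` the Fisher interval is
  (0.458, 0.955). A bootstrap CI was considered and rejected as the
  default: at n around 11 the bootstrap is noisier than the z-interval and
  makes reports seed-dependent.
* **Mobility threshold**: each locus's positional Mb-vs-Mt comparison is
  joined with its intra-chromosomal gene-centromere distance
  (`|gene midpoint − centromere|` in Mbp) and tabulated as a 2x2
  contingency of (distance > 50 Mbp) x (p < alpha). Which statistic
  defines "significant positional change" was an open choice; the package
  uses the Mann-Whitney test on Feret-normalized locus-centromere
  distances, matching how nuclear observations are tested elsewhere in
  the pipeline. Each FISH signal is one observation by default (homolog
  signals are not averaged within a nucleus, and gene spots pair to their
  *nearest* centromere spot — both stated assumptions with config
  alternatives). No multiple-testing correction is applied across loci by
  default, mirroring per-locus reporting conventions; BH across loci is a
  flag.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised,
calibrated and regression-tested without microscopy or array data. It
emulates the *study design*, not the microscope.

**Nuclei.** Volume and flattening are drawn per group from the packaged
presets (Mb: 970.9 ± 341.3 µm³, −0.771 ± 0.286; Mt: 811.1 ± 231.1 µm³,
−0.935 ± 0.308) as truncated normals (volume > 50 µm³, flattening in
(−0.99, 0.5)), realized as oblate spheroids with `a = b`,
`c = a(1 + f)` — the two preset numbers then fully determine the shape —
and uniformly random orientations. Two numerical points deserve emphasis:

1. The truncated normal's *location* is solved (by `uniroot` on the
   closed-form truncated mean) so the **population mean equals the preset
   mean**. This matters because the flattening presets lie close to the
   physical bound at −1: naive truncation would bias the Mt mean by about
   +0.19 and no generator could then pass its own calibration.
2. No distribution on (−0.99, 0.5) can have mean −0.935 *and* SD 0.308
   (the maximum SD at that mean is 0.28), so the preset SD for flattening
   is necessarily an upper description; the realized spread is
   bound-limited. Volumes are essentially unaffected (the 50 µm³ bound is
   2.7 SD below the Mb mean). Sampling is by inverse CDF, which works
   even when the kept mass is a far tail.

**Spots.** A probe's radial law is a Beta distribution on the volume-mode
index: `v ~ Beta(alpha, beta)`, `rho = v^(1/3)`, direction uniform on the
sphere in the principal frame, position at `rho` times the boundary
radius. `Beta(1, 1)` is the uniform-in-volume null; `Beta(2, 5)` vs
`Beta(5, 2)` encode a centre-to-periphery repositioning between
conditions. Every generated spot satisfies `rho <= 1` by construction.

**Expression.** Genes are placed uniformly along the packaged chromosome
lengths (default 20000 genes, about the density of the protein-coding
annotation) and partitioned into 1 Mbp blocks emulating TAD-scale
co-regulation. Blocks are designated differentially expressed until the
target fraction of genes (default 0.1) is covered. A designated block
receives a shared latent log2 effect drawn from
`Normal(0, block_effect_sd)` **conditioned on |effect| >= 1.5 bits**: the
package defines a "DE block" as one whose shared change is detectable by
the downstream twofold + BH screen — an unconditioned draw would leave a
large minority of nominally DE blocks below twofold and make the
generator's own bookkeeping incoherent with its labels. Every gene adds
`Normal(0, 0.2)` bits of private noise. Group means and p-values are then
generated *consistently* from one two-sample model: 3 array replicates
per group with residual SD 0.1 (log2 scale, typical of RMA-processed
arrays), Welch t-test per gene (vectorized; verified against
`t.test` at 1e-12). With these defaults the differential filter recovers
the configured DE fraction to within about one percentage point, and the
`K_GOI`/`K_mean` Spearman correlation over a panel of 11 genes of
interest (8 from DE blocks, 3 stable, mirroring the study panel's
changed:stable ratio) averages above 0.7 across replicates, collapsing to
zero when block effects are removed.

**Masks.** `voxelize()` rasterizes a model at the acquisition geometry of
the imaging setup the pipeline targets (0.13 µm in-plane pixels, 0.2 µm
z-steps), setting voxels whose centers fall inside the ellipsoid, and
refuses to produce masks of fewer than 30 voxels.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: optical PSF and segmentation error,
chromatic shift between channels, nuclear shapes beyond ellipsoids
(lobed or bent myonuclei), spatial correlation between homolog signals,
probe-specific hybridization efficiency, and expression correlation
structure beyond single-scale blocks. Results on real data depend on
segmentation quality in ways the synthetic path cannot measure.

## Numerical choices and degenerate inputs

* Shell assignment uses `ceiling(index * N - 1e-9)` — the epsilon absorbs
  cube-root round-trips landing exactly on shell boundaries.
* A spot exactly at the center has no direction; its radial ratio is 0 by
  definition, no ray is evaluated.
* Mask fits require at least 30 voxels; coarser data are an error, not a
  guess. Geometry recovery to a few percent additionally needs the
  thinnest semi-axis to span several z-steps; population draws near the
  flattening bound can be thinner than one z-step and are then at the
  resolution floor of any fit.
* Degenerate (equal-moment) mask axes keep the lab frame rather than an
  arbitrary eigenbasis.
* `0/0` change coefficients are `NaN` ("undefined"), never silently 0 or 1.
* Genomic coordinates are 0-based half-open in BED inputs and 1-based
  inclusive in reports, converted once at the I/O boundary. The packaged
  GRCh38 chromosome lengths, centromere midpoints and the 12-locus panel
  coordinates are approximate public-reference values (0.1 Mbp scale),
  sufficient against a 50 Mbp threshold.

## Problem sizes in the test suite

The suite runs the uniformity null at 1e5 spots in a single random
ellipsoid (KS statistic < 0.01), the geometry oracle on 100 random
ellipsoid/direction pairs (1e-6 µm agreement with bisection
ray-marching), morphology calibration at 600 nuclei per group,
end-to-end repositioning detection at 80 nuclei per group across 20
seeds, and expression parameter recovery at 20000 genes across 20
replicates — sizes chosen to make the Monte-Carlo error of each check
small relative to its assertion while the whole suite stays in the
one-minute range.

## Known limitations

* The ellipsoid is a first-order nuclear shape model; strongly non-convex
  myonuclei violate it, and the radial ratio of a spot in a concavity is
  not well defined by the ray construction.
* The flattening convention is fixed by ordering, not by the original
  definition; absolute flattening values are comparable within this
  package only.
* The Fisher-z CI for Spearman's rho is approximate at small n and
  rank-tied data.
* The per-gene neighbourhood windows (0.95/1.5 Mbp) are treated as fixed
  per-locus configuration; the package takes no position on how they were
  originally assigned.
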
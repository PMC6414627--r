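# crestcurve

Sliding-semilandmark shape analysis of 3D anterior tibial crest curvature.

## What this is for

The anterior crest of the tibia is anteriorly bowed (medial view) and
follows a laterally concave/convex sigmoid course (anterior view). Both
features respond to habitual lower-limb loading, so comparing crest shape
across chronologically distinct skeletal samples probes the decline of
mobility from prehistoric to industrialized populations. `crestcurve` is
for osteologists and geometric morphometricians who digitize such curves
as dense 3D polylines and need the full quantitative chain from raw
digitizations to group-level inference — plus a synthetic study generator,
because skeletal datasets of this kind are usually not redistributable and
the pipeline must be validatable without them.

## The method

For each specimen, an ordered polyline of ~1,800–2,000 points (mm) is
subdivided *equidistantly by arc length* into k = 20 semilandmarks, the
endpoints being anatomically anchored landmarks. Configurations are
superimposed by generalized Procrustes analysis (GPA: centered, scaled to
unit centroid size, iteratively rotated to the consensus, proper rotations
only), and the 18 interior semilandmarks slide along their local tangents
t_i = unit(p_{i+1} − p_{i−1}) by the closed-form projection of
(consensus_i − p_i) onto t_i — Procrustes-distance minimization, not
bending energy — alternating with re-superimposition until the total
Procrustes SS stabilizes.

Shape variation is decomposed by PCA; the number of interpretable
components is chosen by the broken-stick rule
b_j = (1/p) Σ_{i=j..p} 1/i. Group differences are tested on the retained
PC scores with the two-sample Hotelling statistic

    T² = (n₁ n₂ / (n₁ + n₂)) · d′ S_pooled⁻¹ d

calibrated by label permutation (B = 10,000, p = (1 + #{T²_perm ≥
T²_obs})/(B + 1)); curve-length differences use the analogous permutation
test on |mean difference|. Allometry is screened per retained PC by the
ANOVA of score ~ curve length within each sex stratum. Digitization
repeatability is summarized by per-landmark repeat SDs and the reliability
coefficient σ_xx′ = 1 − ME²/SD² against a 0.95 acceptability threshold.
Mean-shape comparisons are exported as per-semilandmark vector fields
(sphere magnitudes + 3D arrows) with projections into the anatomical A–P
("medial view") and M–L ("anterior view") planes, and PC1–PC2 group
distributions as 70% confidence ellipses.

See `vignettes/crestcurve-methods.Rmd` for assumptions, parameter
defaults, and the design decisions behind every numerical choice.

## Worked example

The numbered scripts under `analysis/` run the workflow end to end on the
synthetic seven-group study (435 specimens, published group sizes):

```sh
Rscript analysis/01_simulate.R     # generate + digitize + resample
Rscript analysis/02_run_study.R    # align, test, export report bundle
Rscript analysis/03_error_study.R  # repeat-digitization reliability
Rscript analysis/04_calibration.R  # null calibration of the shape test
```

Stage 1 ends by re-estimating each group's anterior bow amplitude from the
digitized curves alone:

```
Recovered group-mean A-P bow amplitudes (mm):
 ENEOL BRONZE   IRON   EMED   LMED    C20    C21
  8.03   7.52   6.97   6.28   5.79   5.03   4.51
Strictly declining through time: TRUE
```

— the generator's declining-mobility signal (8.0 → 4.4 mm across groups)
is recovered in chronological order. Stage 2 aligns all 435 curves and
tests every group pair; with the default design's clean separation, PC1
(85.5%) and PC2 (14.0%) carry the M–L and A–P contrasts and all 21
Hotelling cells reject at the add-one floor (p = 1/10001 ≈ 0.0001), while
the curve-length matrix shows the 20th-century dip / 21st-century peak
pattern (e.g. C20 vs C21: p = 0.001). Stage 3 prints

```
Default digitization noise (0.03 mm per point):
<error_report> overall ME = 7.04e-05, between-specimen SD = 0.0007095
  reliability = 0.9902 (threshold 0.95: acceptable)
```

i.e. at the default noise the simulated 15 × 3 repeat study sits at
σ_xx′ ≈ 0.99, above the 0.95 cut. Stage 4 reports the empirical type-I
error of the whole pipeline at α = 0.05 (200 null datasets):

```
Empirical type-I error at alpha = 0.05: 0.045 (99% binomial band [0.015, 0.095])
```

The same chain is available programmatically:

```r
library(crestcurve)
bundle <- run_study(run_config(design = default_study_design(seed = 1),
                               B = 10000L, seed = 1))
pairwise_report(bundle)$shape   # Table-style p-value matrix
write_report_bundle(bundle, "report")
```

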
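# resgen

Individual-based landscape genetics at microgeographic scale: does landscape
heterogeneity — vegetation cover, humidity, temperature, elevation — shape
gene flow over distances of a few hundred metres?  `resgen` implements the
resistance-surface optimization workflow used to answer that question for
small, continuously distributed animals genotyped at microsatellite loci, plus
the population-genetic and movement analyses that surround it.

## What it computes

**Resistance optimization (the core).**  An environmental raster `x` is turned
into a resistance surface through one of eight curves built from the
monomolecular family *y* = 1 − e^(−bx) (saturating) and the Ricker family
*y* = x·e^(−bx) (hump-shaped), each optionally reflected in its input
("reverse", x → 10 − x) and/or output ("inverse"), then rescaled to [1, r] so
that `r` is the maximum resistance.  Connectivity between sampled individuals
is the commute-time distance on the 8-neighbour raster graph (vol(G) ·
R_eff(i,j) from the graph Laplacian — the circuit-theory measure).  Pairwise
genetic distance D_PS (1 − proportion of shared alleles) is regressed on the
standardized commute distances with the MLPE mixed model

y_ij = β₀ + β x_ij + u_i + u_j + ε_ij,   u_i ~ N(0, σ²_u),

whose per-individual random effects account for the non-independence of
pairwise distances.  A genetic algorithm searches (family, mode, b, r) to
minimize AIC; candidate surfaces are compared by AICc, Akaike weights and a
subsampling bootstrap (75% of individuals without replacement, rank/weight/
top-model% over iterations).  Categorical surfaces (per-category resistances,
first fixed at 1) and additive multi-surface composites with per-surface
contribution percentages are supported, with a Spearman |ρ| < 0.29 pre-filter
for composite candidates.

**Around it.**  Genotype I/O (genepop and CSV dialects); allele frequencies,
Na/Ne/Ho/uHe/FIS diversity summaries; Monte-Carlo exact Hardy–Weinberg tests;
Weir–Cockerham pairwise FST; maximum-likelihood dyad relationship
classification (U/HS/FS/PO) with greedy pruning of first-order relatives;
K-means/BIC cluster scans and DAPC; NDVI, ordinary kriging and binary
reclassification on matrix-backed rasters with ESRI ASCII I/O; Mantel tests
and correlograms; kernel utilization distributions with h_ref bandwidth,
isopleth home-range areas, overlap percentages, nightly activity metrics and
Mann–Whitney U tests; and a synthetic-data generator that emulates every
input (autocorrelated environmental fields, family-structured microsatellite
panels, MLPE-generated genetic distances with a known true transformation,
nightly telemetry tracks).

## Worked example

The bundled scenario plants an inverse-monomolecular transform of an NDVI-like
surface as the true driver of genetic distance among 40 individuals on a
60 × 60-cell raster (5 m resolution):

```r
library(resgen)
sc <- synthetic_scenario("mapimi-small", seed = 7)
rs <- transform_surface(sc$surfaces$ndvi,
                        transform_spec("monomolecular", "inverse", b = 0.5, r = 100))
cd <- commute_distance_matrix(rs, sc$points)
fit <- mlpe(dps ~ resistance, data = list(dps = sc$y, resistance = cd),
            k = "continuous")
fit
#> MLPE mixed model: 40 individuals, 780 pairs
#> (Intercept)  resistance
#>     0.56163     0.07475
#> sigma2_u = 0.0004662, sigma2_e = 0.000521, logLik = 1770.0713
#> k = 4, AIC = -3532.1426, AICc = -3530.9997
```

The slope 0.075 recovers the planted effect (0.08, slightly attenuated by the
[0, 1] clipping of the simulated dissimilarities), and both variance
components sit near their generating values (5 × 10⁻⁴).  Model selection
against isolation-by-distance and the null model:

```r
eu <- as.matrix(dist(sc$points)); dimnames(eu) <- dimnames(sc$y)
model_comparison(list(
  ndvi     = fit,
  distance = mlpe(dps ~ eu, data = list(dps = sc$y, eu = eu), k = "distance"),
  null     = mlpe(dps ~ 1,  data = list(dps = sc$y), k = "null")))
#>             model k  logLik      AIC     AICc   delta      weight rank
#> ndvi         ndvi 4 1770.07 -3532.14 -3531.00   0.000 1.00000e+00    1
#> distance distance 2 1679.48 -3354.96 -3354.64 176.360 5.05772e-39    2
#> null         null 1 1559.52 -3117.04 -3116.93 414.065 1.22155e-90    3
```

The resistance model takes all the Akaike weight: genetic distance tracks the
landscape, not geographic distance alone.  `optimize_single()` finds such
transformations without knowing the truth; `run_pipeline()` chains every stage
(diversity → HWE → relatedness/pruning → D_PS → clustering → Mantel →
optimization → bootstrap selection → home range) into one seeded, reported
run.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch: it generates the
bundled scenario at the given seed, runs the full pipeline on it (report
tables under `results/report/`), then optimizes the true and a decoy surface
against the model-generated distances and bootstrap-selects among
null/distance/surface candidates, printing the winning model.  The JSON
output is written to `--out`.
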
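---
title: "Methods: resistance-surface optimization and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resistance-surface optimization and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it fits, the
numerical choices behind them, and what its synthetic data can and cannot
establish.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

At microgeographic scale (hundreds of metres), gene flow in small,
continuously distributed animals may respond to landscape features —
vegetation cover, microclimate, topography — rather than to distance alone.
The workflow implemented here asks that question without assuming a shape for
the relationship: every environmental surface is a *hypothesis*, converted to
resistance by a flexible curve whose parameters are estimated from the genetic
data themselves.

## 2. Resistance transformations

`transform_surface()` maps a raster onto resistance in four steps: (1) affine
rescale of the input to [0, 10]; (2) optional input reflection x → 10 − x
("reverse"); (3) a base curve, monomolecular y = 1 − e^(−bx) (saturating) or
Ricker y = x·e^(−bx) (hump-shaped, maximum at x = 1/b); (4) optional vertical
reflection about the curve's range ("inverse"), then affine rescale to
[1, r].  Eight mode combinations result.  Bounded rescaling makes r directly
interpretable as the maximum resistance (explored up to r = 2500 by default)
and nests the flat surface as a degenerate limit; a constant input raster is
rejected because the transformation is undefined on zero range.

The hump-shaped family is implemented as x·e^(−bx), the standard Ricker form:
a pure exponential decay e^(−bx) would duplicate the reversed monomolecular
shape and could not produce the "optimal peak" responses (lowest resistance at
intermediate humidity or temperature) this family exists to express.

## 3. Commute distances

Connectivity is measured on the 8-neighbour graph over unmasked cells.  Edge
conductance is the arithmetic mean of the two cell conductances 1/R (the
`mean_resistance` alternative is a config switch), divided by √2 for diagonal
edges to account for the longer step.  The commute distance is
vol(G)·R_eff(i, j) with vol(G) twice the total edge conductance and R_eff the
effective resistance; it is proportional to the expected round-trip time of a
random walk and equivalent to circuit-theory resistance distance up to the
volume factor.  Multiplying all resistances by a constant leaves the commute
matrix unchanged (the volume and R_eff factors cancel), which is why
predictors are standardized before model fitting anyway.

Numerically, effective resistances come from a sparse Cholesky factor of the
grounded Laplacian (one column per distinct sampled cell); a dense
Moore–Penrose pseudoinverse route (`method = "dense"`) is retained for small
rasters and is the oracle the sparse path is tested against (agreement well
below 1e-8 relative).  Points are snapped to their containing cell under
half-open cell intervals, so ties are impossible; disconnected pairs and
points on nodata cells are errors, not silent results.

## 4. The MLPE mixed model

Pairwise distance regressions violate independence: pairs sharing an
individual are correlated.  `mlpe()` fits
y_ij = β₀ + Σ β_m x_m,ij + u_i + u_j + ε_ij with i.i.d. individual effects
u ~ N(0, σ²_u), by exact Gaussian maximum likelihood with covariance
σ²_ε I + σ²_u ZZᵀ (Z the pair-to-individual incidence).  β and σ²_ε are
profiled out analytically (Woodbury identity on the n_ind × n_ind inner
matrix), leaving a one-dimensional search over log(σ²_u/σ²_ε) on two brackets
plus an explicit comparison with the σ²_u = 0 boundary, where the fit
provably collapses onto ordinary least squares.  The profile is smooth and
unimodal in practice; the tests verify the optimum against an independent
dense-covariance oracle.  Predictors are standardized over the n(n−1)/2 pairs
before fitting, matching the convention that resistance distances enter
"scaled and centered".

The parameter count k for information criteria follows the convention of the
resistance-optimization literature rather than a naive count: null model 1,
Euclidean distance 2, binary feature surface (categories + 1), single
continuous surface 4 (family, mode, b, r plus intercept collapse to this
printed convention), composite of s surfaces 2s + 1.  Published model tables
in this workflow are internally inconsistent with any single per-parameter
rule, so the convention is codified as a lookup with `k_override` as the
escape hatch.  AICc uses the number of *individuals* as its sample size (a
config flag switches to pairs); AIC is the objective during optimization,
AICc the criterion for selection across optimized surfaces — both are always
reported.

## 5. Optimization, filtering, bootstrap

The genetic algorithm treats family and mode as categorical genes (uniform
mutation) and b, r as log-scale real genes (blend crossover, Gaussian
mutation), with tournament selection, elitism 1 and a stagnation stop.
Full-scale defaults are population 40, 100 generations, stagnation 15; the
tests and the acceptance script run reduced settings (population 10–12, 4–8
generations) and say so — the search space is small enough that the reduced
budget plus the polish below recovers planted signals.

After the GA, `optimize_single()` polishes (b, r) within *every* family/mode
by Nelder–Mead seeded from the GA optimum and keeps the best refitted AIC.
Blend crossover serves categorical genes poorly at small budgets; the polish
is the "separate search per mode, best-of" alternative folded into the
default, and equation choice is then decided by optimized fits rather than by
crossover luck.

**Identifiability caveat.**  Transformation families can mimic one another: a
plain Ricker whose peak sits below the data's effective input range is, over
that range, a monotone curve nearly indistinguishable from an inverse
monomolecular after rescaling, and on a fraction of simulated realizations
the mimic attains an equal or slightly better AIC than the generating family.
Surface identity (which raster drives gene flow) is recovered far more
robustly than equation identity (which curve family describes it); the
acceptance suite quantifies both on the bundled scenario.  Conclusions about
*which* landscape variable matters are therefore better supported than
conclusions about the precise functional form.

Composite surfaces add the individually transformed resistances and shift the
sum to minimum 1; a surface's contribution is its mean transformed value as a
percentage of the composite mean (the published tables print such
percentages without defining the metric; this definition is documented and
tested for its 100% normalization).  Candidate pairs for composites must show
cell-wise Spearman |ρ| below 0.29 (Cohen's small-to-medium cut); matrix-wise
correlation on commute distances is available as a flag since the published
description does not say which was used.

The bootstrap subsamples ⌈0.75·n⌉ individuals without replacement, subsets
all pairwise matrices, refits every candidate *without re-optimizing its
transformation* (the only computationally coherent reading of a 10,000-
iteration procedure), and averages ranks and Akaike weights; the default is
500 iterations for desk-scale runs (tests use fewer and say so).  With
fraction 1 and one iteration it reproduces the full-data comparison exactly.

## 6. Population-genetic components

Diversity follows textbook definitions: Ne = 1/Σp², uHe = 2n/(2n−1)·(1−Σp²),
per-locus FIS = 1 − Ho/uHe.  The *overall* FIS is 1 − mean(Ho)/mean(uHe) —
the aggregation that reproduces the published headline value from its own
printed means; monomorphic loci have uHe = 0 and undefined FIS, excluded from
the FIS mean.  Hardy–Weinberg testing is the Monte-Carlo exact test: random
re-pairings of the observed allele list scored by the Levene conditional
probability, p = proportion of tables (including the observed) at most as
probable; an exhaustive enumeration over genotype tables is included for
small problems and doubles as the test oracle.  FST is Weir–Cockerham θ with
components summed over alleles and loci.  D_PS uses optimal within-locus
allele pairing and pairwise deletion of untyped loci.

Relationship classification evaluates the dyad likelihood under the IBD
vectors U = (1,0,0), HS = (.5,.5,0), FS = (.25,.5,.25), PO = (0,1,0) with
known allele frequencies and independent loci; Mendelian exclusion makes the
PO likelihood exactly zero whenever a locus shares no allele.  First-order
pruning is a deterministic greedy vertex cover (remove the highest-degree
individual, ties by smallest id) — published counts imply dyads share members
but do not state the removal rule, so the rule here is one reproducible,
consistent choice.  Missing data policy: pairwise deletion for D_PS and
relatedness, locus-wise complete cases for HWE, keeping every individual
usable.

Cluster scans encode genotypes as individuals × (locus, allele) counts with
locus-mean imputation, run K-means on retained principal components and score
with BIC(K) = n·log(WSS/n) + K·log(n), the K-means BIC of the DAPC
literature (documented here because alternatives differ materially).  This
criterion's behaviour depends on the n-to-dimension ratio: with few
individuals relative to encoded alleles, splitting pure noise can lower BIC —
the same ambiguity the source workflow reports on real data — so the
panmictic recovery test uses a microsatellite-scale panel where K = 1 wins in
the majority of runs.  DAPC is PCA followed by LDA on retained components,
with an explicit `n_pcs` argument in place of cross-validation heuristics
(selection heuristics are implementation-specific; the re-assignment report
gives the user the same information).

## 7. Surfaces and kriging

Rasters are matrix-backed with top-left origin, half-open cell intervals and
planar-metre coordinates (study extents of ~1 km need no geodesy); I/O is the
ESRI ASCII grid, a text format that round-trips bit-exactly at the printed
precision including nodata.  NDVI is (NIR − Red)/(NIR + Red) with 0/0 cells
masked.  Interpolation of point measurements is ordinary kriging with an
exponential variogram fitted by Cressie-weighted least squares by default
(the source workflow names only "kriging", so the variogram is explicit
config, spherical available); with zero nugget the predictor interpolates
exactly and kriging weights sum to one — both are tested against a longhand
linear-system solution.  Resampling is bilinear for continuous surfaces and
majority-vote for categorical ones; the binary vegetation ("feature") surface
defaults to NDVI ≥ 0.1, the conventional bare-soil boundary.

## 8. Home ranges and activity

Utilization distributions are bivariate Gaussian kernel densities with the
reference bandwidth h_ref = ((sd_x + sd_y)/2)·n^(−1/6), on a grid padded by
3h at cell h/4 (the estimate is insensitive to these grid choices well below
its statistical error), renormalized to integrate to exactly 1.  The
home-range area at level p is the smallest-density region holding mass p,
reported in hectares; for bivariate normal data it converges to the analytic
χ²₂ contour area (the 95% case is asserted within 15% at n = 1000).
Least-squares cross-validation bandwidths are omitted: the reference
bandwidth is reported to give indistinguishable areas in this workflow's own
account.  Overlap is directed: area(A∩B)/area(A) on a common grid.  Activity
nights run noon-to-noon so that fixes after midnight group with the evening
that started them; step distances are consecutive Euclidean moves.  The
Mann–Whitney U implementation reports both one-sided U statistics and their
minimum, with the exact null distribution for small untied samples.  The
published sex comparison prints U = 45, which cannot arise from 6-vs-2
home-range areas (max U = 12); the enumeration here gives U = 8 from the
printed cells, and the bundled copy of those cells is used to reproduce the
printed male/female means instead.

## 9. The synthetic generator

`synthetic_scenario("mapimi-small")` emulates the study design at desk scale:
a 60 × 60-cell, 5-m raster with four autocorrelated Gaussian random fields
(Gaussian-kernel-smoothed white noise, rescaled to target moments) — an
NDVI-like field in [−1, 1] whose mean/sd put roughly a third of cells below
the 0.1 bare-soil line, humidity near 44%, temperature near 30 °C, elevation
near 1152 m, the values around which the source system's movement is easiest;
40 individuals placed uniformly; genetic distances generated *at the distance
level* from the MLPE model with a known true transformation (inverse
monomolecular, b = 0.5, r = 100, β₁ = 0.08 against noise σ²_u = σ²_ε =
5 × 10⁻⁴ — a strong but not noise-free signal); a family-structured
microsatellite panel (Dirichlet frequencies, Hardy–Weinberg founders,
Mendelian transmission for PO/FS/HS dyads) with its truth table; and nightly
telemetry on a 30-minute lattice in the 21:00–01:30 window.

Generating distances directly from the MLPE model (rather than simulating
genotypes on the landscape) matches the model being fit, which keeps
parameter-recovery tests sharp but also means a green recovery test
establishes *statistical* correctness of the estimation chain, not that real
microsatellite data follow the MLPE model.  The genotype-level generator is
deliberately landscape-free, so in the bundled pipeline run the
genotype-derived D_PS shows no landscape signal — the null model wins there,
and the planted signal is demonstrated on the model-generated distances.
Features of real data not emulated: null alleles, genotyping error, linkage,
spatially structured relatedness, temporal landscape change, telemetry
measurement error.

## 10. Known limitations

Equation-family identifiability (section 5) is the main scientific caveat.
Computationally, the dense commute oracle is limited to ~3000 vertices and
kriging solves the full n × n system (both fine at study scale); REML, partial
Mantel tests, least-cost paths, current maps and Bayesian (MCMC) clustering
are out of scope.  The MLPE random-effect structure is the variance-components
form of the published compound-symmetry parameterization; they induce the
same covariance family, and only the former is implemented.
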
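---
title: "Quantifying the spatial organization of cortical minicolumn maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial organization of cortical minicolumn maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(minicol)
```

## The scientific problem

Cortical minicolumns — narrow radial chains of interconnected neurons
spanning layers II–VI — are marked anatomically by compact bundles of
radially oriented myelinated axons. In tangential sections of primary
visual cortex (V-1) the bundle cross-sections form a planar point
pattern, and three families of questions about that pattern carry the
biology:

1. **Regularity.** Are bundles spaced more evenly than random? This is a
   second-order question, answered by Ripley's K function, the
   nearest-neighbour distance distribution G, and the Clark–Evans ratio.
2. **Inhomogeneity.** Does the local bundle density drift smoothly
   across a section? This is an intensity question, answered by Gaussian
   kernel density mapping with a cross-validated bandwidth, and — along
   one-dimensional traverses — by a scan over sequential groups of
   inter-bundle distances.
3. **Allometry.** Across species, does the *total number* of bundles in
   V-1 (density × area) track visual acuity better than bundle spacing
   or neuron counts do? This is a cross-species regression question on a
   packaged measurement table.

The original bundle coordinates are manual traces and are not deposited,
so the package pairs every estimator with a seeded synthetic generator
whose ground truth is known. All coordinates and distances are in
micrometres; densities are reported in bundles/mm² (the internal unit is
points/μm²; the conversion is a factor of 10⁶).

## Synthetic bundle maps

Five morphologies cover the hypotheses the statistics must distinguish:

* `gen_poisson(intensity, window)` — complete spatial randomness, the
  null everything is benchmarked against.
* `gen_hex_lattice(spacing, window, jitter_sd)` — the idealized
  arrangement in which every bundle is equidistant from six neighbours.
  With zero jitter the lattice is exact (interior nearest-neighbour
  distance equals `spacing` to 10⁻⁹ relative error), and windows whose
  sides are multiples of the column pitch and row pitch
  (`spacing · √3/2`) hold an exact integer number of points, making the
  realized intensity exactly `2/(√3·spacing²)`.
* `gen_hardcore(intensity, min_dist, window)` — a Matérn type II
  thinning: proposals from a Poisson parent carry i.i.d. uniform marks,
  and a proposal dies if any smaller-marked neighbour lies within
  `min_dist`. Regular but not lattice-like; the retained intensity has
  the closed form `(1 − exp(−λπh²))/(πh²)`, which the tests verify by
  simulation. Parameter combinations whose disk area fraction exceeds
  the hexagonal packing bound π/(2√3) are refused by name.
* `gen_banded(band_spacing, along_spacing, wobble, window)` — the
  morphology actually seen in sections: thin curving strings of closely
  adjacent bundles separated by broader empty bands. Strings run along
  one axis at lateral pitch `band_spacing`, with points every
  `along_spacing` along the string, a sinusoidal lateral displacement of
  amplitude `wobble` (random phase, period `wobble_period`), and a small
  isotropic per-point jitter (`jitter_sd`, default 1.5 μm — the scale of
  digitization error when clicking bundle centres). Optional string
  bifurcation (`branch_prob`, per μm of string) is off by default: real
  maps show branched strings, but no branching statistics are published,
  so branching is not part of the default morphology.
* `gen_gradient_poisson(base_intensity, gradient_ratio, window, axis)` —
  an inhomogeneous Poisson process whose intensity rises linearly along
  one axis, produced by thinning a homogeneous parent. This emulates the
  smooth up-to-2× density drifts seen across a few millimetres of
  section.

**Calibration of the banded defaults.** Published bundle maps constrain
the banded morphology three ways: most nearest-neighbour distances fall
in 20–45 μm; the Clark–Evans ratio of real sections is 1.20–1.41; and
the scaled K function at `r·√λ = 1` sits about 0.7 below the Poisson
value π. With the observed spacings (along-string 25 μm, band 60 μm) the
free parameters are the wobble amplitude and jitter. The defaults
(`wobble = 18`, `jitter_sd = 1.5`, `wobble_period = 1000`) were fixed
once against those three signatures: they give a K deficit near 0.66, a
Clark–Evans ratio near 1.22, and ~99% of nearest neighbours in 20–45 μm.
Note a geometric ceiling: with mean nearest-neighbour distance ≈ 25 μm
and intensity `1/(25·60)` μm⁻², the Clark–Evans ratio of any such
pattern cannot exceed ≈ 1.29, so the synthetic stand-in reproduces the
lower half of the observed 1.20–1.41 range; species with other spacing
ratios populate the upper half.

**Distance sequences.** Ordered inter-bundle distance records are
right-skewed and unimodal, and the published tables give exactly three
moments (mean 24–81 μm, SD 6–32 μm, skewness up to ~1.5).
`gen_distance_sequence()` therefore uses a shifted gamma matched by the
method of moments (shape `4/skew²`, scale `sd·skew/2`, shift
`mean − shape·scale`), falling back to a Gaussian at zero skewness and
refusing targets whose implied support would start below zero. Position
structure along the traverse is optional: an AR(1) Gaussian copula adds
autocorrelation without disturbing the marginal moments, and `mean_end`
imposes a linear location drift, emulating the smooth spacing gradients
seen along real traverses.

What the generators deliberately do **not** emulate: irregular section
outlines (windows are axis-aligned rectangles, matching the n/area
intensity convention), blood-vessel gaps and staining artefacts,
measurement of the third coordinate (analysis is planar), and any
coupling between the 2-D maps and the 1-D traverses. Passing tests
therefore demonstrate correctness of the estimators under clean
conditions, not robustness to those artefacts.

## Regularity statistics

Throughout, the reference intensity is λ = n/area of the analysis
window — never a fitted intensity — so "regular" always means "relative
to a homogeneous Poisson process at the observed density".

**Ripley's K** (`estimate_K`) uses
K̂(r) = (A/n²) Σᵢ Σⱼ≠ᵢ w·1[dᵢⱼ ≤ r]. The default edge correction is the
translation correction (w = A/|W ∩ W_shift|), which is unbiased under
homogeneity; border (reduced-sample) and uncorrected variants are
selectable, and the uncorrected variant is what the test suite compares
against a brute-force double loop. The radius grid defaults to 100
values up to a quarter of the shorter window side, and radii beyond half
the shorter side are truncated with a warning (corrections degrade
there). For cross-section comparison the curve carries the
dimensionless presentation: λK (a mean neighbour count) against
`r·√λ`; under CSR, λK = π at scaled radius 1 and ≈ 79 at scaled
radius 5. `lambda_k_at()` interpolates linearly, so for sharp benchmark
work the target radius should be included in the grid (interpolating a
convex curve on a coarse grid reads slightly high). One finite-n
subtlety: the n⁻² normalization gives K̂ a conditional CSR expectation
of πr²·(n−1)/n, an O(1/n) factor visible in large ensembles.

**G function** (`estimate_G`) is the empirical CDF of per-point
nearest-neighbour distances with a border (reduced-sample) correction by
default; the attached benchmark is 1 − exp(−λπr²) and the reported
`diff` is observed minus benchmark. Reduced-sample CDFs need not be
monotone, so the curve is clamped with a running maximum to keep the CDF
property.

**Clark–Evans** (`clark_evans`) reports
R = mean-NN / (1/(2√λ)); R > 1 means regular, R < 1 clustered. Three
edge-handling variants:

* `guard_margin` (default): the mean uses only points whose boundary
  distance is at least the largest observed NN distance, so every
  contributing neighbour is genuinely inside the window; this is the
  least-biased estimate of R itself.
* `donnelly`: all points, with Donnelly's edge-adjusted expectation and
  variance for rectangles. This is the variant to use for the
  *significance test*: the classical standard error
  0.26136/√(mλ) assumes independent NN distances, and under a true
  Poisson null its z-statistic is over-dispersed (SD ≈ 1.09), rejecting
  at ~7–9% instead of 5%. Donnelly's variance constant absorbs the
  neighbour-sharing correlation and restores the nominal size — the
  package's tests verify the type-I error falls in [0.03, 0.07] over
  1,000 simulations.
* `none`: classical moments on all points; edge effects bias R upward
  (~+2% at n ≈ 500) and inflate rejection further.

The p-value is two-sided by default (one-sided `regular`/`clustered`
flags exist) and the normal approximation is refused below 10 usable
points.

## Density mapping and bandwidth selection

`kernel_intensity()` smooths the map with an isotropic Gaussian kernel
of SD σ and divides by the kernel mass inside the window at the
evaluation point, so the map integrates to ≈ n (the tests require the
integral to be within 5% of n for σ up to a quarter of the window side).
Grid spacing defaults to σ/4; a spacing above σ warns about
under-resolution. Values are reported in bundles/mm², and
`scaled_values` (map divided by its mean) feeds `density_histogram()`,
the unit-mean histogram used to summarize inhomogeneity.

`cv_bandwidth()` maximizes the leave-one-out point-process
log-likelihood Σᵢ log λ̂₋ᵢ(xᵢ) − ∫ λ̂ over a candidate grid. Two
conventions are provided: the default uses the same edge-corrected
estimator as the density map (integral evaluated on an internal 64×64
grid); `edge_correct = FALSE` uses the raw kernel sum, whose window
integral has the closed form Σᵢ eσ(xᵢ), and is the branch checked
against an independently coded brute-force scan. The default candidate
grid spans 1/100 to 1/4 of the shorter window side — the same upper
limit as the map's validity domain. On genuinely inhomogeneous patterns
the likelihood has an interior maximum (a 204→424 bundles/mm² gradient
pattern selects σ ≈ 290 μm, the "several hundred" scale reported for
real sections); on an exactly homogeneous pattern the truth is flat, the
optimal σ is unbounded, the profile is nearly flat at large σ, and the
selector returns a value at or near the upper grid end with a boundary
warning. That boundary behaviour is a property of likelihood
cross-validation itself, not of the implementation.

Recovery accuracy at window edges deserves a caveat: for a linear
gradient, kernel smoothing is unbiased in the interior (a symmetric
kernel preserves linear functions) but acquires a bias of order
σ·√(2/π)·slope at the window boundary even with mass correction.
Endpoint densities should therefore be read at least ~σ inside the
window, which is how the gradient-recovery checks are framed.

## Distance-sequence analysis

`summarize_distances()` reports the sample moments (SD with n−1;
skewness and excess kurtosis as bias-adjusted standardized moments) and
a Kolmogorov–Smirnov test against a Gaussian with the sample's own
mean and SD, using the asymptotic law. Estimating the parameters from
the same sample inflates the KS p-value; published distance tables
report the naive statistic, so naive is the default and a Monte-Carlo
Lilliefors option (`lilliefors = TRUE`) is provided for honest
normality screening. Degenerate (constant) sequences are refused rather
than summarized.

`bin_histogram()` anchors bins at zero, left-closed/right-open, in the
5 μm (or 10 μm for widely spaced species) widths used for published
distributions; frequencies sum to 1 and counts reconstruct n.

`compare_groups()` is Mann–Whitney by default — exact enumeration when
both samples have ≤ 20 untied values, otherwise the tie-corrected
normal approximation (the two branches agree to < 0.005 in p at
n = 20/20 in the tails where decisions are made; mid-range p differs by
up to ~0.013 because the uncorrected normal approximation is used for
the continuity-free comparison) — with an unpaired Welch t-test as the
alternative. `kruskal_wallis_groups()` covers ≥ 3 groups with the
tie-corrected H statistic and delegates two groups to
`compare_groups()`.

`sequential_groups()` implements the traverse scan: consecutive
non-overlapping groups (default 100 bundles; the trailing remainder is
dropped and reported, since no published convention exists for partial
groups), per-group mean/SD/median in order, and adjacent-pair tests.
The default compares medians by rank-sum test; `method = "auto"`
switches a pair to the t-test only when both groups pass the KS screen
at 0.05, mirroring how published scans mix the two. Adjacent-pair
p-values are reported raw by default because that is how such scans are
published; a Holm adjustment is available (`p_adjust = "holm"`) for
family-wise control across a traverse.

## The species table and allometric fits

`load_species_table()` ships the ten-species measurement table (eye
axial diameter, retinal ganglion cells, acuity, body mass, V-1 area and
neuron totals, inter-bundle distance, orthogonal and — where measured —
tangential bundle densities), with explicit `NA` for missing entries and
the originally published derived values preserved in `printed_*`
columns for cross-checking only. The derivations are always recomputed:

* `total_bundles(density, area)` — rounded product. Recomputation
  reproduces every published total except the hedgehog, whose printed
  8,665 disagrees with its own density × area (591 × 15 = 8,865); the
  recomputed value is reported as is, with no silent correction.
* `derive_total_bundles(table, range_policy)` — species with both
  densities get a (low, high) bracket; `range_policy` picks midpoint
  (default), low, or high. In this table "high" coincides with the
  orthogonal-section density for every species, so it is also the
  "orthogonal-only" reading — the natural choice when comparing against
  results computed before tangential densities existed.
* `neurons_per_column(neurons, area, distance)` — the cylinder model:
  areal neuron density times π(d/2)², d the median inter-bundle
  distance. This reproduces the published non-primate values to ±1
  (and the pig to 1%), but *not* the published primate values, which
  are inconsistent with the tabulated V-1 neuron totals by roughly a
  factor of ten; primates are therefore excluded from exact checks.
* `per_pinwheel(total, n_pinwheels)` — rounded quotient, optionally
  divided further by 15 orientation columns per pinwheel.

`powerlaw_fit(x, y)` fits y = a·xᵇ. Two conventions matter and both are
implemented: `fit_space = "log"` (default) is OLS on log₁₀ values with
R² the squared correlation of the logs — the statistically conventional
choice, insensitive to which endpoint policy is used (the acuity–bundle
R² moves by < 0.03 across low/midpoint/high). `fit_space = "linear"`
refits by nonlinear least squares and computes R² from linear-scale
residuals — the convention of common graphing software, which weights
large-valued species heavily and is the convention under which the
published cross-species R² values (≈ 0.97 for acuity vs total bundles
with orthogonal densities, ≈ 0.0005 for acuity vs spacing, ≈ 0.21 for
spacing vs body mass) are reproduced. Missing species are excluded and
listed; non-positive values are an error because the log is undefined.

## Reproducibility plumbing

Patterns and sequences round-trip exactly through TSV (`#window:` JSON
comment line or sidecar; bounding-box fallback with warning; a third
coordinate column is dropped with a warning because the analysis is
planar). `run_pipeline()` executes any subset of
simulate → spatial → distances → allometry from one configuration (list,
YAML, or JSON) under a single integer seed, writes per-stage artifacts
and a consolidated JSON report with an MD5 config hash, and is
deterministic: same configuration + seed gives identical numbers. Every
generator seeds a local RNG stream and restores the caller's state.

## Problem sizes and numerical choices

The test-suite and acceptance computations use windows of 2–3.5 mm a
side at densities of 125–643 bundles/mm² (n ≈ 500–3,000 points per
pattern), 10–200 pattern replicates per ensemble and 1,000 replicates
for test-size calibration, chosen to keep Monte-Carlo standard errors
well inside the asserted tolerances. Other numerical choices: radius
grids are linear with 100 points by default; ties in rank tests fall
back to the corrected normal approximation; `lambda_k_at()` refuses
extrapolation beyond the estimated grid; kernel evaluations floor at
10⁻³⁰⁰ before logs; and all RNG flows through a single seed argument
per call.

## Known limitations

* Windows are rectangles; irregular section outlines are out of scope,
  so λ = n/area inherits any dead space a user includes.
* The Clark–Evans test assumes homogeneity; on strongly inhomogeneous
  maps R conflates regularity with density drift. The kernel map is the
  tool for that case.
* No inhomogeneous K, pair-correlation function, anisotropy analysis,
  or bootstrap envelopes; the Poisson closed forms are the only
  benchmarks.
* The banded generator's curvature and branching are qualitative: only
  spacing, wobble and jitter are constrained by published numbers.
* Cross-species fits are ordinary regressions; no phylogenetic
  correction is attempted, and published literature values are taken at
  face value.
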
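---
title: "Methods: spatio-temporal analysis of soil microbial communities across a farmed landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal analysis of soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Soil microbial abundance (measured as molecular microbial biomass, the
crude DNA yield per gram of soil) and bacterial richness (OTU counts from
16S amplicon data) vary across agricultural landscapes with soil
properties, land use and farming practices, and they also change over
time. Disentangling those drivers at the scale where farmers make
decisions requires three methodological ingredients, which this package
implements end to end and exercises on a synthetic landscape with known
ground truth:

1. **Interpolated mapping** of site-sampled variables: a rank-order
   (normal-score) transform, Matérn variography with weighted nonlinear
   least squares, leave-one-out χ² validation, ordinary kriging in rank
   space and back-transformation.
2. **Environmental covariates**: a daily two-compartment soil
   water-balance bucket model yielding cumulative water-stress days per
   site-year, and seventeen crop-rotation / farming-intensity indicators
   aggregated from plot-year operation logs.
3. **A PLS path-modeling engine** (mode A) for temporal latent-variable
   models linking soil resources, habitat, land use, crop rotation and
   farming intensity to the microbial responses in two sampling
   campaigns, with effect decomposition, goodness of fit and bootstrap
   validation.

Because the raw field tables of the motivating study system are not
publicly deposited, all empirical claims in this package are
property-based: the synthetic generator defines the statistical structure
the analysis assumes, and every stage is scored against the generator's
recorded truth.

# The synthetic landscape generator

`simulate_landscape()` builds a complete study system from one master
seed. Its defaults encode the study conditions the analysis is designed
for; they are not tuning knobs.

**Sampling design.** A 215-m regular grid over a 3225 m × 3440 m extent
(240 grid points) plus 30 uniformly placed extra sites with a 30-m
minimum separation, thinned at random to 269 retained sites — emulating a
field campaign in which a handful of sites are lost to incomplete
records. Sites belong to polygonal plots via a Voronoi tessellation of 80
plot seeds; one contiguous block of plots (grown from a randomly chosen
corner) is labelled forest until about 16 % of sites are forest.

**Soil fields.** Gaussian random fields with Matérn correlation (ranges
150–300 m, exponential smoothness) on observation scales typical of a
clayey/silty-loam arable landscape: cropland SOC 17.6 ± 6.5 g/kg with a
+23.5 g/kg forest offset (forest soils ≈ 2.3× cropland), pH 7.8 ± 0.5
(−0.7 in forest), clay 33 ± 6 %, silt coupled to clay (fine fraction
covaries) with sand closing the composition to 100 %. Forest soils
receive substantial *extra* independent spread (`forest_sd_extra`),
because forest-soil heterogeneity is far larger than cropland
heterogeneity; this also keeps land use and soil resources from being
near-collinear, which matters for the identifiability of the path
models. TN tracks SOC through a C:N ratio near 10.7 (10.1 in the second
campaign) with 0.15 g/kg noise; texture and depth are simulated once and
held fixed over time.

**Climate and water stress.** Daily rainfall follows a seasonal wet-day
probability (≈ 0.32–0.44) with gamma amounts, totalling ≈ 770 mm/y;
potential evapotranspiration is a seasonal cycle peaking ≈ 4.5 mm/d in
midsummer. Per-farming-year multipliers (0.7 in 2011, 1.4 in 2016)
encode the emulated condition that the first campaign year is dry and
the second wet, so stress-day counts drop between campaigns. A single
year's simulated weather is one random realization, so an individual
seed can still produce a wet 2011 — as real weather can; the condition
holds in distribution, not per seed.

**Farm history.** Per cropland plot and farming year (September to
August), a crop is drawn from a Markovian rotation: persistent plot
traits set winter-cereal affinity and rotation diversity jointly (mixed
cereal farms rotate several winter species), repeating the previous
crop is penalized and rapeseed after rapeseed heavily so. Tillage,
pesticide-application rates and fertilizer totals follow two regimes —
plowing-dominated with moderate pesticide pressure early, reduced
tillage with higher treatment-frequency indices late — interpolated
linearly between the campaign years when drift is enabled. A per-plot
intensity trait correlates plowing, TFIs and fertilizer loads, giving
the farming-intensity block its reflective structure.

**Responses and ground truth.** Latent-variable scores for the exogenous
blocks (land use, habitat, and the campaign copies of resources,
rotation, intensity) are standardized equal-weight means of their
standardized measured variables. Each generated response equals its
structural fitted value plus a residual made *exactly orthogonal in
sample* to its predecessors and scaled so the score has unit sample
variance. This construction has a useful property: a regression of the
realized scores recovers the true path coefficients exactly, so recovery
failures downstream are attributable to the estimator, not the
generator. Residual draws are keyed by the base latent-variable name
(campaign suffix stripped): with drift off, matching predictors and zero
noise, the two campaigns' responses coincide at every site. `noise_sd`
(default 0.3 on the standardized scale) is measurement noise added when
the responses are emitted onto their observation scales (biomass-like:
65 ± 35 mg/g; richness-like: 1925 ± 60 OTUs).

The default true path structure gives the biomass-like response strong
positive dependence on soil resources (β = 0.45), weaker positive
habitat dependence (0.15), negative farming-intensity dependence
(−0.2), a rotation effect that flips sign between campaigns (−0.15 to
+0.15) and a temporal carry-over (0.25). Land use has no *direct*
response arrow in the truth: its influence is routed through rotation
and resources, matching the mediation structure this architecture
describes; with forest plots carrying zero practice indicators, land use
correlates 0.7–0.9 with the other latent variables and a direct arrow
would in any case be barely identifiable at n = 269. The richness-like
truth uses deliberately weak effects (R² ≈ 0.1–0.3), so its recovery is
statistically noisy by construction. What the generator does **not**
emulate: sequencing reads, OTU tables, platform bias between campaigns,
within-plot sampling error, or spatially structured measurement error —
so passing tests say nothing about those features of real data.

# Interpolated mapping

**Normal scores.** Soil and microbial variables are far from Gaussian,
so kriging operates on normal scores: average ranks for ties, plotting
position (rank − ½)/n, then the standard normal quantile. The ½ offset
avoids the infinite score that rank n/n would produce; any plotting
position in common use changes the scores by less than the kriging
noise. The inverse map interpolates linearly between observed quantile
pairs and clamps outside the observed range (clamp counts are
reported).

**Variography.** The Matheron estimator over 25 equal-width bins up to
half the maximum inter-site distance. Twenty-five bins rather than a
coarser binning because, at a 215-m grid with ranges near 150 m, wide
bins blur all short-range structure into the first bin and the
cross-validation calibration below visibly degrades. The Matérn model
γ(h) = τ² + σ²[1 − 2^(1−κ)/Γ(κ) (h/φ)^κ K_κ(h/φ)] is fitted by
weighted nonlinear least squares with Cressie weights N(h)/γ(h;θ)²
(folded into the objective, so they track the current model), profiled
over the smoothness grid κ ∈ {0.5, 1, 1.5, 2.5} — smoothness is poorly
identified from one empirical variogram, so it is not optimized freely.
Nelder-Mead from three starting points per κ; parameters enter squared
to stay positive; the range is capped at ten times the largest lag,
beyond which the fitted curve is indistinguishable inside the window.

**Validation and kriging.** Leave-one-out ordinary kriging uses the
bordered-matrix inverse identity (one factorization for all n held-out
systems; unit tests verify it against brute-force refits). Standardized
squared errors θᵢ = (zᵢ − ẑ₋ᵢ)²/s²₋ᵢ follow χ²₁ under a correct model,
so the mean must sit near 1 and the median near qchisq(0.5, 1) = 0.455;
the validity envelopes default to ±0.1 and ±0.12 and gate the mapping
stage. Kriging is global (n ≈ 269 makes neighborhoods unnecessary), the
unbiasedness constraint is checked to 1e-10, and predictions are
back-transformed through the quantile map. Surfaces for any strictly
monotone re-expression of the data are identical in rank space by
construction.

# Water balance

Available water capacity comes from a texture-class pedotransfer table
(mm of available water per cm of soil; editable, with defaults in the
range of standard texture-triangle values) split into WHC1 (0–20 cm, the
sampled layer) and WHC2 (20 cm to profile bottom). Daily accounting, in
order: actual evapotranspiration min(Kc·ETPp, S1+S2) withdrawn from the
topsoil store first; rainfall refills S1 then S2, the excess is lost; a
day is stressed iff the end-of-day S1 is empty (tolerance 1e-9 mm).
Choices the underlying description leaves open, all switchable or
documented: evapotranspiration before rainfall (following the stated
enumeration), topsoil-first withdrawal, end-of-day stress evaluation,
constant Kc = 1.0 for forest, stores initialized full at the start of
each farming year. Water is conserved to 1e-9 mm daily, and the stress
count is antitone in WHC1 and rainfall and monotone in demand —
properties the tests check by brute force on toy series.

# Practice indicators

Farming years run 1 September to 31 August, labelled by the ending
(sampling) year, half-open at the boundary. Rotation: the sampling
year's crop class (winter / spring / summer / Brassicaceae / other, with
Brassicaceae taking precedence over season), the four class frequencies
over the 4 farming years ending at sampling, and the distinct species
over 8 years (fallow is not a species). Intensity: the sampling year's
tillage category; tillage and plowing frequencies over the 4-year window
(Freq_tillage counts any soil-disturbing operation, plowing included);
treatment-frequency indices as Σ applied/recommended dose per category
with the total over herbicide + fungicide + insecticide + anti-slug; and
the five fertilizer totals. OM = 1.72 × SOC. Plots with incomplete
history are excluded with a warning rather than patched.

# The PLS path-modeling engine

Mode A (reflective) throughout: loadings are MV–LV correlations, which
is what the measurement diagnostics below assume. The iteration is the
classical one — standardize MVs, equal initial outer weights, inner
estimate per scheme (centroid by default; factorial and path are
implemented and switchable), outer weights as correlations between MVs
and the inner estimate, rescore, repeat until the normalized weights
move less than 1e-7. Signs are anchored per block (the anchor MV's
loading is forced positive). Path coefficients are OLS of each
endogenous score on its predecessors; collinear predecessors are an
explicit error, not a silent pseudo-inverse.

Diagnostics follow the usual acceptance rules: Cronbach's α and
Dillon-Goldstein's ρ above 0.7 for multi-MV blocks; loadings positive
and larger than every foreign cross-loading. `prune_model()` removes the
worst-violating MV one at a time, refitting after each removal, and
applies every removal symmetrically to the paired campaign block so the
two years keep identical rosters. Effects decompose exactly: direct =
B, total = Σ Bᵏ (finite for a DAG), indirect = total − direct; tests
compare against exhaustive path enumeration. GOF = √(mean communality ×
mean R²) over all MVs (single-MV blocks contribute communality 1), with
"correct" above 0.4 and "very good" above 0.7, both strict. The
bootstrap resamples rows, refits, and flags a path accurate iff the
percentile CI excludes zero *and* |estimate/SE| exceeds the normal
critical value; the reference analysis size is 10,000 resamples, scaled
down in tests and demos. Percentile intervals without bias correction,
and a normal reference for the t statistic, are deliberate
simplifications and documented as such. `compare_architectures()` ranks
candidate structures by response R², GOF and k-fold out-of-sample RMSE
of the response MVs predicted from the exogenous blocks through the
fitted model.

One measurement-diagnostic caveat worth knowing: in a two-LV model,
mode-A outer weights are correlations with the *other* LV, so a junk MV
that correlates with the other block can hijack its host LV and evade
the cross-loading rule; the diagnostic has power only when the MV's true
home block is in the model. The planted-defect tests are built
accordingly.

# Problem sizes and runtimes

The suite and demo are sized for a single CPU: landscapes of 269 sites;
50 replicate fields for the kriging-calibration experiment; 20 seeds ×
11 paths for parameter recovery (signs all recovered, ≥ 90 % of
coefficients within ±0.1 at noise_sd = 0.3); bootstrap checks at 500
resamples over 20 seeds (a strong planted path β = 0.8 flags accurate,
a null path flags inaccurate at about the confidence level — asserted
with two-sigma binomial slack at that seed count); demo bootstraps at
200 resamples. These sizes are the package's chosen experiment scales;
the underlying operations handle larger runs linearly in replicates.

# Known limitations

- Isotropic variography only; no anisotropy, co-kriging or space-time
  covariance. Kriging neighborhoods are global.
- The bucket model has no runoff routing, snow, irrigation or capillary
  rise, and ETPp is consumed, never computed from raw weather.
- The engine is plain PLS-PM: no formative (mode B) blocks, higher-order
  constructs, consistent PLS or multi-group comparison.
- The generator's land-use dichotomy makes several latent variables
  strongly collinear — faithful to fragmented agricultural landscapes,
  but it means direct land-use response arrows are near-unidentifiable
  and are therefore routed through mediation in the default
  architectures.
- Richness-like responses carry weak true signals by design; estimates
  of their paths are correspondingly noisy, which the demo reports
  honestly rather than smoothing over.
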
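---
title: "Methods: spectral radiance moments as a biodiversity proxy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral radiance moments as a biodiversity proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, every tunable parameter that matters, the
synthetic data generator and what it does (and does not) emulate, the
numerical choices, and the known limitations.

## 1. The measurement model

A quadrat observation is a five-band image of at-sensor radiance digital
numbers (DNs). We assume the DN of pixel `i` in band `b` is, to a good
approximation,

> `DN_ib = g · r_ib + noise`,

where `r_ib` is a surface-dependent radiance and `g` is an unknown
*per-image* multiplicative illumination gain: solar conditions change
between flights, and without in-field reflectance panels `g` cannot be
removed. The package therefore never compares raw DN levels between images.
It characterizes each band's pixel distribution by its shape:

* `mean_dn`, `sd` (sample standard deviation, denominator `n − 1`),
* coefficient of variation `cv = sd / mean_dn`,
* skewness `m3 / m2^1.5` and non-excess kurtosis `m4 / m2^2`
  (central moments with denominator `n`),

and averages each moment arithmetically over the five bands
(`observation_moments()`). `cv`, skewness and kurtosis are invariant under
`DN → g·DN` for any `g > 0`; `sd` scales by exactly `g`. This invariance is
the load-bearing assumption, and the test suite asserts it to 1e-12
relative error. Additive sensor noise breaks the invariance slightly; in
the synthetic model its standard deviation is ~1–2% of vegetation DN
levels, and the residual gain sensitivity shows up only in `sd`, never
appreciably in `cv` (a property test checks that quadrat *rankings* of `cv`
are stable across gain regimes).

Pixels that are non-finite or negative are masked before moments are
computed, and masked counts are reported. A constant band has `sd = 0` and
`cv = 0` but *undefined* skewness and kurtosis; undefined values propagate
as `NA` and are excluded from the cross-band average rather than
zero-filled, which would fabricate signal. A zero-mean band has undefined
`cv`.

The quadrat region of interest is a 0-based, half-open rectangle
`[row0, row1) × [col0, col1)` (`crop_to_roi()`), matching how array slices
are usually specified in imaging code; the manifest carries it as four
integer columns.

Recording height coarsens the ground footprint of a pixel. Aggregating
`k × k` pixel blocks by their mean cannot increase `cv`: the variance of
block means is the total variance minus the mean within-block variance
(law of total variance), while the image mean is unchanged. Equality holds
only when every block is internally constant. This is the *smoothing
effect*: spectral diversity estimated from coarser pixels is biased
downward, which the analysis handles by modeling height explicitly and by
discarding observations above 8 m (`filter_observations()`, boundary
inclusive).

## 2. In situ biodiversity indices

Percent covers of overlapping canopies may total more than 100%, so
proportions are always `p_s = c_s / Σ c` from the quadrat's own total —
never capped. Zero-cover species are dropped first (`0·ln 0 = 0` limit
convention). From `p` the package computes richness, Shannon–Weiner
`H = −Σ p ln p` (nats) and Simpson's `D = Σ p²`. Two facts worth keeping in
mind:

* `D = Σ p²` is a *dominance/concentration* measure: it **decreases** with
  diversity (`1/richness ≤ D ≤ 1`). Field analyses sometimes report its
  complement; the package's default is the printed dominance form, with
  `simpson_index(p, variant = "gini")` giving `1 − Σ p²` explicitly, never
  silently.
* Bryophytes are weighed in clip strips but not scored in species-level
  cover, so they contribute to biomass (g/m², mass divided by the 0.2 or
  0.25 m² strip area) and never to the cover-based indices.

## 3. The hierarchical regression

One observation is a quadrat × sampling-day × recording-height combination
(or × band, in band-level models). The model for a moment `y`:

```
y_i = α + x_i' β + u_{q(i)} + ε_i,   u_q ~ N(0, σ_quadrat),   ε_i ~ N(0, σ_resid)
```

All numeric variables are z-scored over the full filtered observation table
(sample sd; "mean and variance centered" is read as standardization to unit
sd, the only coherent reading). Priors follow the averaged-moment analysis:
`N(0,1)` for intercept and coefficients, `exponential(rate 2)` for
`σ_quadrat`; band-level models, having many more parameters, use `N(0,0.7)`
and `exponential(rate 4)`. The residual-sd prior is unstated in the source
analysis; we use `exponential(rate 1)` — weakly informative on z-scored
data where the marginal sd is 1 — and expose it in `hier_priors()`.
Sampling uses 4 chains × 2000 iterations with 1000 warmup by default
(4000 posterior draws), with per-chain RNG seeds derived from one integer
seed; convergence is assessed by split-chain R-hat on every monitored
parameter, flagging (never silently accepting) any R-hat ≥ 1.01.

**Parameterization.** The sampler is Gibbs-based (JAGS). In the naive
parameterization `u_q ~ N(0, σ_q)` two ridges mix badly: `α` against
`mean(u)`, and — much worse when repeatability is high — any covariate that
is constant within quadrats, whose coefficient then trades off one-to-one
against the `u_q`. The package therefore detects quadrat-constant columns
of the design matrix automatically and centers them hierarchically:

```
u_q ~ N(α + xb_q' β_b, σ_quadrat),   y_i = xw_i' β_w + u_{q(i)} + ε_i
```

This is the same marginal model (coefficients keep their interpretation and
are reported under their design-matrix names), but between-quadrat
coefficients are updated jointly with the random effects and R-hat values
sit at 1.00 where the naive form produced 1.5–2. Biodiversity indices and
treatment are between-quadrat terms; height and band are within-quadrat.

**Repeatability.** `R = σ²_quadrat / (σ²_quadrat + σ²_resid)` per posterior
draw (variance-scale intraclass correlation, the Nakagawa–Schielzeth form;
an sd-scale variant would not be a variance proportion), summarized by the
posterior mean and 95% interval. `R ∈ [0,1]` holds draw-wise by
construction.

**Model comparison.** `loo_elpd()` computes PSIS-LOO: importance ratios
`1/p(y_i|θ)` per draw, tail smoothing by a generalized Pareto distribution
fitted with the Zhang–Stephens profile-posterior estimator (with the usual
weak prior pulling the shape toward 0.5), truncation at the raw maximum
weight, and the Pareto `k` diagnostic per observation (`k > 0.7` flagged).
The implementation is validated in the test suite against reference values
computed independently with ArviZ's `psislw` on fixed fixtures (agreement
to ~1e-9). `compare_models()` reports `Δelpd` against an intercept-only
base model (random effect only) with the paired pointwise standard error.
When an interaction model wins on elpd but its interaction coefficients all
have 95% intervals spanning zero, `select_preferred_model()` prefers the
interaction-free counterpart — an explicit, recorded parsimony rule, not
silent behavior.

**Categorical coding.** Treatment contrasts use `ambient` as the reference
level (so each coefficient is a shift against ambient plots); band models
use blue (450 nm) as the reference. Fixing these conventions makes
contrasts reproducible across runs.

## 4. The synthetic scene generator

The generator exists to give the pipeline ground-truthed inputs with the
statistical structure the analysis assumes, in exactly the file formats the
pipeline reads (per-band 16-bit TIFFs + manifest CSV, long-format cover and
biomass CSVs, treatment table, truth tables).

What it emulates, and the defaults (all configurable):

| Component | Default | Rationale |
|---|---|---|
| Species signatures | common vegetation DN profile (9k/16k/11k/22k/30k for B/G/R/RE/NIR) × `exp(0.25·z)` per species/band | chlorophyll absorption low in blue/red, high NIR; log-normal spread keeps signatures positive; `band_separation = 0.25` gives ~25% between-species spread |
| Within-species texture | `texture_sd = 1200` DN (~8% of mid-level DN) | leaf angle/shadow variation within a species patch |
| Community abundances | symmetric Dirichlet, concentration `10·evenness/(1−evenness+1e−6)`, default `evenness = 0.45` | monotone mapping; evenness → 1 approaches uniform; 0.45 gives the graminoid-dominated unevenness typical of temperate grassland |
| Spatial structure | abundance-weighted seed points, nearest-seed tessellation, `patch_scale_cm = 5` | plants grow in patches, not salt-and-pepper pixels; 5 cm is a plausible ramet scale |
| Solar gain | log-normal, median 1, `gain_sdlog = 0.15`, one draw per image shared across bands | the UAV's sunlight sensor compensates only partially; ±15% residual between flights is a deliberate, documented assumption (no field value is published) |
| Sensor noise | additive `N(0, 150)` DN | ~1% of vegetation DN |
| Height → pixel | `pixel_cm = 0.05·height_m`; base raster 0.1 cm (1000 px over 1 m), block factors 1/2/3/4 for 2/4/6/8 m | matches the 0.1–0.5 cm range over 2–8 m; integer factors make aggregation exact |
| Design | 37 quadrats; treatments 25/5/5/2 ambient/drought/irrigated/procedural control; 16–33 species; 7 sampling days | the field design |

DNs are clipped to the 16-bit sensor range [0, 65535] and stored as
`DN/65535` in 16-bit TIFFs (the R `tiff` convention), so integer DNs
round-trip exactly. Five single-band files per observation are written
because multiband writing is limited to 4 samples; the reader accepts
either layout. A single RNG stream is seeded once per `simulate_study()`
call, so equal seeds give byte-identical output files. Survey percent
covers are the realized pixel proportions times a random 95–135% total,
emulating overlapping-canopy totals above 100%.

What it deliberately does **not** emulate: 3-D canopy structure, shadowing
and vertical complexity; spatially correlated texture within a species
patch (texture is iid per pixel); phenology or any day-to-day change in the
vegetation; georeferencing and image registration; reflectance calibration
(out of scope by design — the analysis exists precisely because calibration
is not performed). Consequences to keep in mind when reading test results:

* Because texture is iid at the finest pixel scale, block averaging removes
  it at the full `1/k` rate, so the synthetic height effect
  (β_height ≈ −0.6 z-units) is *steeper* than a field effect
  (real canopies are spatially correlated and smooth more slowly).
* Because scenes are static across sampling days (only gain and noise
  change), repeatability of `cv` comes out near 1, higher than
  field values (~0.7–0.8) where the vegetation itself moves and grows.
* The generator's mechanism makes `cv` *increase* with diversity, so the
  association with Simpson's dominance `D = Σp²` is negative in synthetic
  recoveries. Field analyses that report a positive "Simpson" association
  with spectral diversity are implicitly using a complement-like reading;
  the tests therefore assert mechanism signs through Shannon's `H`.

Passing tests show the pipeline recovers known effects from data that
*satisfy the model's assumptions*; they do not certify performance on field
images with canopy shadowing, mixed pixels, or misregistered bands.

## 5. Numerical choices and degenerate inputs

* Variance uses the sample denominator `n − 1` (at ~10⁵ pixels per image
  the population/sample difference is ~1e-5 and irrelevant; the convention
  matters only for the test oracles). Skewness/kurtosis use population
  central moments, the common raster-statistics convention.
* Block averaging trims trailing rows/columns that do not fill a `k × k`
  block (the 1000-px base raster is not divisible by 3), keeping the
  aggregation exact on the retained region.
* All-constant bands, zero-mean bands, all-zero cover tables, zero-area
  ROIs, missing heights, single-level treatments, and fewer than two
  quadrats are all rejected or flagged explicitly — see the operations'
  error contracts; nothing is silently imputed.
* `run_pipeline()` drops `height_m` from the default model set when the
  design has a single recording height (a constant column cannot be
  z-scored and carries no information).
* Ties in nearest-seed tessellation are resolved by the kNN
  implementation's first-match rule; with continuous uniform seed
  coordinates ties have probability zero.

## 6. Problem sizes used for validation

The test suite and the acceptance script run scaled-down designs chosen to
exercise every code path while keeping a full run in minutes: moment and
index oracles at up to 10⁴ pixels; the smoothing property on 100 rendered
120-px scenes; parameter/repeatability recovery on 20 replicates of
37 quadrats × 200 observations at 2 chains × 1000 iterations (the reduced
setting for replicated recovery); and an end-to-end run of 20 quadrats
spanning richness 4–24 at a 480-px base raster. At 20 quadrats the
between-quadrat "species identity" noise is a real limit: the posterior
probability of a positive Shannon effect varies roughly between 0.78 and
0.98 across generator seeds, mirroring how modest the field-scale
coefficient itself is. The acceptance script runs the full 37-quadrat
design with two sampling days at the standard 4 × 2000 MCMC settings.

## 7. Known limitations

* The Gibbs backend needs the hierarchical centering described above; users
  adding covariates with near-zero within-quadrat variance that are not
  *exactly* constant per quadrat may still see slow mixing.
* PSIS-LOO `k` diagnostics above 0.7 are reported, not repaired; refitting
  without the offending observation (exact LOO) is left to the user.
* The Dirichlet evenness mapping is a modeling convenience; it is not
  calibrated to any field evenness measurement.
* Survey noise is limited to cover rounding and total-cover inflation;
  observer error in species identification is not modeled.
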
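# spectraldiv

Estimating plant biodiversity in grassland quadrats from the *variability* of
uncalibrated multispectral radiance — the "spectral diversity" idea — and
quantifying how trustworthy that proxy is.

## The problem

Botanical surveys of 1 × 1 m quadrats (percent cover per species, clip-strip
biomass) are accurate but slow. A low-cost UAV multispectral camera (five
bands: blue 450, green 560, red 650, red edge 730, near-infrared 840 nm)
images the same quadrat in seconds, but in the field the raw digital numbers
(DNs) cannot be calibrated to reflectance: solar illumination differs between
flights. The workable signal is *distributional*: because species differ in
their spectral signatures, a more diverse quadrat shows a wider spread of
pixel radiance within each band, and spread statistics that are scale-free
survive an unknown illumination gain.

For each band the package computes across the quadrat's pixels the mean, the
sample standard deviation, and

- coefficient of variation  `CV = sd / mean`,
- skewness `g1 = m3 / m2^(3/2)`,
- kurtosis `m4 / m2^2` (central moments, non-excess),

then averages each moment over the five bands. CV, skewness and kurtosis are
invariant to a multiplicative gain `g > 0` (the package tests this to 1e-12),
which is exactly why uncalibrated radiance is usable. Ground truth per
quadrat comes from the survey tables: richness, Shannon–Weiner index
`H = −Σ p ln p`, Simpson's index `D = Σ p²` (the dominance form; the
Gini–Simpson complement `1 − D` is available behind an explicit option), and
biomass in g/m², with proportions `p` taken from the quadrat's own cover
total, which may exceed 100% for overlapping canopies.

The two sides meet in a Bayesian hierarchical regression with a quadrat
random intercept,

```
cv_qij = α + β₁ shannon_q + β₂ height_ij + u_q + ε_qij ,
u_q ~ N(0, σ_quadrat),  ε ~ N(0, σ_resid),
```

fit by MCMC (JAGS) on z-scored variables with N(0,1) coefficient priors and
an exponential(2) prior on σ_quadrat (N(0,0.7)/exponential(4) for the
larger band-level interaction models). Models are compared by PSIS-LOO
expected log predictive density (Δelpd against an intercept-only base), and
the consistency of a moment across repeated observations of the same quadrat
is summarized by the repeatability (intraclass correlation)
`R = σ²_quadrat / (σ²_quadrat + σ²_resid)`.

Because recording height (2–8 m) coarsens the pixel footprint (0.1–0.5 cm),
block-averaging provably cannot increase CV — the smoothing effect the
height coefficient captures. Observations above 8 m are discarded.

A synthetic-scene generator (`simulate_study()`) provides fully ground-truthed
data in exactly the file formats the pipeline consumes: species spectral
signatures, Dirichlet abundances placed as patches by nearest-seed
tessellation, per-image log-normal solar gain, sensor noise, and exact
block-averaging for each recording height.

## Worked example

Simulate a 20-quadrat study (richness 4–24, heights 2 and 8 m, two sampling
days) and run the full analysis:

```r
library(spectraldiv)
run <- run_pipeline(list(
  out_dir  = "demo_run",
  simulate = list(n_quadrats = 20, heights = c(2, 8), n_days = 2,
                  richness_range = c(4, 24), n_species_pool = 30,
                  base_px = 480),
  mcmc     = list(chains = 4, iterations = 2000, warmup = 1000),
  seed     = 42
))
head(run$obs_table[, c("quadrat_id", "sampling_day", "height_m",
                       "cv_avg", "richness", "shannon", "simpson")], 4)
#>   quadrat_id sampling_day height_m cv_avg richness shannon simpson
#> 1        Q01            1        2  0.270       19    2.87  0.0616
#> 2        Q01            1        8  0.243       19    2.87  0.0616
#> 3        Q01            2        2  0.270       19    2.87  0.0616
#> 4        Q01            2        8  0.243       19    2.87  0.0616

run$fits$shannon_height$summary
#>       parameter    mean lower95 upper95 rhat
#> 1         alpha  0.0022  -0.344   0.348    1
#> 2       shannon  0.1563  -0.208   0.498    1
#> 3      height_m -0.6496  -0.657  -0.642    1
#> 4 sigma_quadrat  0.7900   0.588   1.081    1
#> 5   sigma_resid  0.0351   0.029   0.042    1

run$comparison
#>           model elpd   se delta_elpd delta_se
#>  shannon_height  143 5.43        243     5.84
#>  simpson_height  143 5.44        243     5.85
#>            base -100 2.48          0     0.00
```

Reading the output: every variable is z-scored, so `shannon = 0.16` means a
one-sd increase in Shannon diversity shifts the band-averaged CV by 0.16 sd
(positive, like the modest field-scale effect); `height_m < 0` is the
smoothing effect of flying higher (CV at 8 m is ~10% below CV at 2 m here);
both models beat the intercept-only base by ~240 elpd units. Repeatability
of the CV per quadrat (`repeatability(run$fits$shannon_height)`) is near 1
in this synthetic design because simulated scenes are static across days —
field data, with real phenology and wind, sit lower.

The run directory contains `moments.csv`, `indices.csv`, `obs_table.csv`,
`fits/` (coefficient summaries and posterior draws), `comparisons.csv`,
`repeatability.csv`, a `report.md` reconciling every row in = kept +
filtered + unmatched, and the resolved config with all seeds.

A thin CLI over the same functions is in `inst/scripts/specdiv.R`
(`simulate`, `moments`, `indices`, `run-all` subcommands).

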
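# lekfire

Fire refugia and postfire lek attendance trends in sagebrush ecosystems.

Wildfire removes sagebrush habitat for decades, but fires burn unevenly and
leave *unburned islands* inside their perimeters. For lekking birds such as
the greater sage-grouse — whose males return to the same display sites
(leks) year after year — those islands may act as fire refugia that keep
local breeding populations viable while the burn recovers. `lekfire` is an
R package for ecologists analysing lek count time series against mapped
fire history. It classifies leks by fire context, estimates before/after
attendance trends, compares those trends across fire categories, simulates
postfire habitat composition at multiple spatial scales, and ranks habitat
explanations of postfire trends by information-theoretic model averaging.
A synthetic fire-mosaic landscape generator makes the whole pipeline
testable end to end with known ground truth.

## The models at the core

**Per-lek trend.** Yearly peak male counts *Y* follow an interaction
Poisson regression on the log link,

    E(ln Y) = β₀ + β₁X₁ + β₂X₂ + β₃X₁X₂,

with *X₁* the survey year and *X₂* the postfire indicator, so β₁ is the
prefire attendance trend (log scale, per year) and β₁ + β₃ the postfire
trend. `lek_trend()` fits this by iteratively reweighted least squares and
returns a classed model object with the usual `print`, `summary`, `coef`,
`confint`, `predict`, `residuals`, `simulate` and `plot` methods.

**Category comparison.** Within each fire category (unburned island, fire
perimeter, 50 m–1.5 km small buffer, 1.5–6.4 km large buffer) the pre- and
postfire slope distributions are compared with a Welch two-sample t test,
or a Wilcoxon rank-sum test when Shapiro–Wilk rejects normality.

**Habitat inference.** Postfire slopes are regressed on standardised
habitat covariates (unburned sagebrush height, fraction of land with >8 %
cheatgrass cover, elevation — each at 0.8, 6.4 and 18 km radii). All 63
models with at most one scale per variable are fitted by OLS, ranked by
AICc, and their coefficients averaged with Akaike weights
(wᵢ = exp(−Δᵢ/2)/Σ exp(−Δⱼ/2)).

## Worked example

```r
library(lekfire)

# simulate a study: 51 x 51 km landscape, 10 fires, 42 leks
study <- simulate_study(landscape_config(rng_seed = 1))

# classify leks by fire context and fit per-lek trend models
a  <- classify_leks(study$leks, study$landscape$perimeters, study$landscape$island)
f  <- filter_leks(study$counts, a)
tr <- lek_trends(study$counts, f)

attr(tr, "fits")[[which(tr$category == "fire_perimeter")[1]]]
#> Before/after Poisson trend model (lek L010)
#>   fire year: 2009 (29 surveys, converged)
#>   prefire trend:  +0.0014 per year (SE 0.0066)
#>   postfire trend: -0.2249 per year (SE 0.0536)

compare_categories(tr)[, c("category", "n_leks", "test_used", "statistic", "df", "p_value")]
#>          category n_leks test_used  statistic        df     p_value
#> 1 unburned_island      9   welch_t -0.4493509 10.966586 0.661929487
#> 2  fire_perimeter      8   welch_t  4.0038635  7.913689 0.004016539
#> 3    small_buffer      5   welch_t  2.1016000  6.839857 0.074622794
#> 4    large_buffer     17   welch_t  0.4728202 24.446209 0.640535744
```

This lek sat inside a burned perimeter: a flat prefire trend
(+0.1 %/year) collapses to −22 %/year after the fire. Across categories,
only the fire-perimeter leks show a significant drop in trend (t = 4.00,
p = 0.004; a positive statistic means the prefire mean exceeded the
postfire mean), while unburned-island and buffer leks remain stable —
the refugia signal the package is built to detect. From here,
`habitat_covariates()` extracts the multiscale habitat table and
`aicc_average()` produces the model-averaged coefficient table and its
dot-and-interval plot; `run_pipeline(pipeline_config(...), out_dir)` runs
every stage in order and writes all tables plus a run manifest.

## Documentation

The methods vignette (`vignettes/fire-refugia-analysis.Rmd`) documents the
models and their assumptions, every fixed threshold and its rationale, the
synthetic generator's calibration, numerical edge cases, and known
limitations.
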
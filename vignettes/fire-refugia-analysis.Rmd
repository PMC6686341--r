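---
title: "Fire refugia and postfire lek attendance trends: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire refugia and postfire lek attendance trends: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lekfire)
```

## The scientific problem

Wildfire in sagebrush ecosystems destroys habitat that takes 35–120 years to
recover, yet fires leave behind unburned islands — patches of intact
vegetation inside the fire perimeter. For a philopatric, sagebrush-obligate
species such as the greater sage-grouse, whose males return to the same
communal display sites (leks) every spring, those islands may act as fire
refugia: places where breeding persists while the surrounding burn recovers.
`lekfire` implements a complete analysis for testing that idea with lek
count time series and mapped fire history, plus a synthetic landscape
generator so every stage can be validated against known ground truth.

## Fire categories

Each lek is assigned one of four categories from planar vector distances to
fire-perimeter edges and an unburned-island mask, in precedence order:

1. **unburned island** — inside an island, or within 50 m of an island or a
   perimeter edge;
2. **fire perimeter** — inside the burned area;
3. **small buffer** — 50 m up to 1.5 km outside the nearest perimeter;
4. **large buffer** — 1.5 km up to 6.4 km (the control group: roughly the
   radius within which most females nest around a lek).

Leks farther than 6.4 km are `outside` and excluded. Distances are exact
Euclidean point-to-edge distances on the shared planar grid, not raster
cell walks, so the 50 m rule is resolution independent. Boundary
conventions (the category definitions leave them open) are: `< 50 m`
strict, `[50 m, 1.5 km)` small buffer, `[1.5 km, 6.4 km]` large buffer.
The 50 m clause uses the *unsigned* edge distance, so a lek marginally
inside the burned edge is also treated as an unburned-island lek; this is
the literal reading of "close to a fire perimeter" and is worth a
sensitivity check in applications where leks hug the perimeter. When
several fires contain or tie for the nearest perimeter, the earliest fire
year is recorded, on the argument that the earliest disturbance sets the
habitat state.

## The before/after trend model

For a lek with yearly peak male counts $Y$ the package fits the interaction
Poisson regression

$$E(\ln Y) = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1 X_2,$$

where $X_1$ is the survey year and $X_2$ indicates postfire years. Setting
$X_2 = 0$ or $1$ shows that $\beta_1$ is the prefire log-linear attendance
trend per year and $\beta_1 + \beta_3$ the postfire trend; $\beta_2$ is an
immediate postfire level shift. `lek_trend()` centres $X_1$ on the fire
year internally for numerical conditioning — the slopes are invariant to
this shift (verified to 1e-10 in the tests), only the intercepts change.

Counts in the fire year itself are treated as postfire by default. Survey
timing relative to the fire within that year is unknown in typical
monitoring data, so this is a convention, exposed as `fire_year_is_post`.

Leks enter the analysis only if they (a) fall in one of the four
categories, (b) were surveyed in at least six years, (c) have at least two
counts before and two after the fire, and (d) were not already extirpated
before the fire. Criterion (d) is interpreted as "the two most recent
prefire surveys are not both zero"; the looser reading "no two consecutive
prefire zeros" is available via `zero_rule = "any_two"`.

### Fitting and its edge cases

The maximum-likelihood fit uses iteratively reweighted least squares on the
log link: starting from $\beta = (\log(\bar y + 0.5), 0, 0, 0)$, each step
solves the weighted least-squares problem by QR decomposition, halving the
step whenever the deviance would increase, and stops when the relative
deviance change falls below 1e-10 (at most 50 iterations). This is robust
for the small counts typical of lek series. The implementation is
self-contained; the test suite cross-checks it against `stats::glm` to
1e-6 on random series and against a coarse-to-fine grid search of the
likelihood on a toy series.

If every postfire count is zero, the postfire level is unbounded below and
$\beta_1 + \beta_3$ has no finite MLE. Such leks are flagged
(`post_extirpated`), their postfire slope reported as `NA`, and they are
excluded — with a message, never silently — from the category comparison
and the habitat-averaging stage. How extirpated leks should enter trend
summaries is genuinely open; the sentinel policy makes the choice explicit
and auditable.

## Comparing categories

Within each category the prefire slopes ($\beta_1$) and postfire slopes
($\beta_1 + \beta_3$) across leks are compared with a two-sample test:
Shapiro–Wilk at $\alpha = 0.05$ on each vector decides between a Welch
unequal-variance t test and a Wilcoxon rank-sum test. The two-sample (not
paired) form is deliberate: the non-integer Satterthwaite degrees of
freedom reported in published refugia analyses of this design identify
Welch two-sample usage, and a paired t test is retained as a sensitivity
option (`paired = TRUE`). P-values are two-sided; a positive statistic
means the prefire mean exceeded the postfire mean. Zero-variance samples
fail the normality gate by definition; two identical constant samples are
reported as a degenerate comparison (statistic 0, p 1) rather than an
error.

## Postfire habitat composition

Habitat effects on the postfire slope are assessed from three variables at
three radii around each lek — 0.8 km (≈2 km²), 6.4 km (≈129 km²) and
18 km (≈1,018 km²) — spanning nesting, foraging and seasonal-movement
scales:

* **vegetation height**: 0.5 m height classes are converted to class
  midpoints (0.25 m for 0–0.5 m, …, 3.25 m for the open-top class above
  3 m) and averaged over the unburned sagebrush cells of the disc; burned
  cells and unsuitable types (grassland, forest, juniper) count as 0 m.
* **cheatgrass cover**: the fraction of disc cells with unsuitable (>8 %)
  cover. Burned cells below 2,000 m elevation are unsuitable regardless of
  observed cover (burns at low elevation are highly invasible); burned
  cells at or above 2,000 m are suitable (cheatgrass does not establish
  that high — cells at exactly 2,000 m follow this rule); unburned cells
  keep their observed cover. The coarse 250 m cover raster is carried onto
  the 30 m analysis grid by nearest-neighbour resampling, which preserves
  cover values exactly.
* **elevation**: the mean over all disc cells.

"Burned" means burned in the window from 17 years before the lek's fire
year up to the fire year, both bounds inclusive — long-lasting fire effects
relative to sagebrush recovery times, and the span between the start of
typical fire records and the earliest analysable lek fire. Disc membership
is by cell-centre-in-circle; at 30 m cells the measured disc area is within
1 % of $\pi r^2$ at the 6.4 km radius. A disc that would leave the raster
is an error, never a silent truncation, so synthetic extents must pad the
largest radius. Vegetation layers are time specific: a lek is matched to
the layer of its fire year, else the nearest earlier layer; leks burned
before the first or after the last layer year are dropped with a message.

## Multimodel inference

Before modelling, `screen_collinearity()` reports Spearman rank
correlations and variance inflation factors ($VIF_j = 1/(1-R^2_j)$ from a
full OLS model) and reduces the predictor set until all pairwise
$|r| < 0.5$ and $VIF \le 3$, reporting every removal. The three habitat
variables pass this screen by construction; the function exists for the
general case where climate or other covariates are added.

Covariates are standardised to mean 0, SD 1 so coefficients are
comparable. The candidate set allows each variable to be absent or present
at exactly one scale: $(3+1)^3 - 1 = 63$ models (the intercept-only model
is excluded). This constrained enumeration — rather than the $2^9 - 1 =
511$ all-subsets set, which is available via `one_scale_per_variable =
FALSE` — is the only reading consistent with a 63-model candidate set for
nine predictors, and it prevents a variable competing with itself across
scales within one model.

Each model is fitted by OLS (QR decomposition) and scored with

$$AICc = -2\log L + 2k + \frac{2k(k+1)}{n-k-1},$$

with the Gaussian log-likelihood at the ML variance $\hat\sigma^2 = RSS/n$
and $k$ counting the intercept, the slopes and the residual variance.
Akaike weights $w_i = \exp(-\Delta_i/2)/\sum_j \exp(-\Delta_j/2)$ then
drive the averaging. The default is *full* averaging — a model without the
term contributes 0 with its weight, shrinking weakly supported effects
toward zero; *conditional* averaging (renormalising over the models
containing the term) is a flag. The unconditional standard error defaults
to the classic form $\sum_i w_i \sqrt{var_i + (\hat\beta_i -
\bar\beta)^2}$, with the square-root-of-weighted-mean variant available as
`se_method = "revised"`. Confidence limits are the symmetric normal form
$\bar\beta \pm 1.96\,SE$ and p-values use the normal approximation;
intervals excluding zero are read as strong evidence of an effect.

## The synthetic study generator

`generate_landscape()` and `simulate_study()` define the conditions under
which the pipeline is exercised and tested:

* **Fires** are blob-shaped polygons (a base radius modulated by a few
  random Fourier harmonics) rasterised onto the 30 m grid; overlapping
  burns keep the most recent year per cell. Default: ten fires with base
  radii 1.5–6 km on a 51 × 51 km landscape, mirroring the fire density and
  mean fire size of a heavily burned sagebrush study region.
* **Unburned islands** are the top-ranking cells of a smooth noise field
  within each perimeter, so the achieved island fraction matches its
  target up to cell rounding. Per-fire targets are drawn from a lognormal
  with median 8.3 % and mean ≈10 %, truncated to 2–78 % — the distribution
  reported for real unburned-island inventories. Island cells carry no
  burn year; an island re-burned by a later fire stops being an island.
* **Elevation** combines a random-direction regional gradient with
  mesoscale relief (quarter- and twelfth-extent wavelengths) rescaled
  exactly to 1,120–2,750 m, so that leks in the landscape interior span
  the 2,000 m cheatgrass threshold instead of sitting on one contour.
* **Cheatgrass cover** on the 250 m grid declines logistically with
  elevation with substantial local noise, putting the >8 % transition in
  the 1,500–2,200 m band.
* **Leks** are planted by rejection sampling with known fire context in
  all four categories (plus a few beyond 6.4 km), with safety margins
  (e.g. perimeter leks at least 80 m inside an edge and 90 m from any
  island cell) so the planted label is unambiguous — classification must
  recover the labels exactly, and does, in the tests. Default numbers
  (9/8/5/17 plus 3 outside) mirror the analysed composition of a typical
  refugia study.
* **Counts** are Poisson draws from the trend model with per-category
  parameter distributions: stable islands and control buffers
  ($\beta_3 \approx 0$), crashing perimeter leks ($\beta_2 \approx -0.5$,
  $\beta_3 \approx -0.22$), mildly declining small buffers. Years span
  1984–2017 with each year surveyed with probability 0.85, emulating
  incomplete monitoring.

What the generator does *not* emulate: detection error and observer
effects in counts, overdispersion beyond Poisson, movement of males
between leks, fire-severity gradients within a burn, sagebrush recovery
within the 17-year window, and nodata holes (water, clouds) inside
extraction discs. Passing tests therefore validate the estimators and the
plumbing under clean conditions; they do not certify robustness to those
field realities.

## Numerical choices and problem sizes

All randomness flows from a single integer seed per entry point
(`rng_seed` in the configurations); rerunning the pipeline with the same
seed reproduces every output file byte for byte. Distances and grids are
planar metres throughout; mismatched input grids are an error, not a
silent reprojection, because reprojection choices would move leks across
the 50 m rule. The test suite runs its simulation benchmarks at sizes
chosen to make the checks sharp yet quick: 100 random series for the GLM
cross-check, 1,000 simulated leks for confidence-interval coverage,
10,000 replicates for the type-I error of the gated comparison, 500
replicates of a 32-lek design for sign recovery in model averaging, and a
12-lek/2-fire fixture for the end-to-end determinism check.

## Known limitations

* The Poisson model ignores overdispersion; a negative-binomial or
  state-space trend model would be the next step for noisy count series.
* Lek counts are treated as a detection-free index of male abundance.
* The burned/unburned dichotomy ignores burn severity.
* The habitat stage treats burned areas as uniformly unsuitable for the
  full 17-year window rather than modelling recovery.
* Model averaging uses normal-approximation intervals; small candidate
  sets with strongly skewed weight distributions may warrant bootstrap
  intervals instead.
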
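---
title: "Automated mammographic density measurement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated mammographic density measurement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodensity)
```

This vignette documents the scientific model behind `mammodensity`, the
parameters that matter, the choices made where the design was genuinely
open, what the synthetic generators do and do not emulate, and the known
limitations.

## The measurement model

A digitised film mammogram is a single-channel intensity image in which
fibroglandular ("dense") tissue is brighter than fatty tissue, which is in
turn brighter than the unexposed background. The pipeline estimates, per
image and with no reference to any other image:

* the **breast area** (pixels), by separating tissue from background and
  scanner artefacts;
* the **dense area** (pixels), by finding an optimal intensity threshold
  within the breast;
* **percent density**, their ratio times 100.

Working per image matters: scanned film has unknown, drifting digitiser
gain and offset, so any method requiring cross-image intensity
standardisation would inherit that drift. All intensities are handled as
integers at the image's native bit depth (8 or 16); nothing is rescaled to
8-bit, because the threshold search space *is* the native intensity range.

### Breast segmentation

Scanner borders are detected per side as edge-adjacent rows/columns whose
mean intensity reaches the `border_percentile` (default 99th) percentile of
the whole image, grown inward while the criterion holds and capped at
`max_border_frac` (default 10%) of the dimension; detection is skipped when
the percentile does not exceed the image median (near-constant images have
no meaningful "bright" frame). Border pixels are zeroed.

Background and tissue are then split by the same between-class criterion
used for density (below) applied to the border-stripped histogram — a
parameter-free, auditable choice. Connected components use 4-connectivity
throughout. The breast candidate is the largest foreground component (ties
prefer a component touching a vertical edge); all other foreground
components are reported as detached artefacts (tags, nameplates). An
artefact that touches the breast merges with it by construction and is
handled as a downstream failure, not silently cut away.

Failure, not repair, is the contract for pathological images. The
candidate fails with `FAIL_BREAST_SEGMENTATION` when it touches both
vertical image edges, three or more edges, or no vertical edge at all (a
CC-view breast is attached to exactly one vertical edge — the chest wall),
or when its area leaves `[min_breast_frac, max_breast_frac]` (defaults 1%
and 90% of the image). Because a breast truncated by a stripped scanner
frame cannot literally touch the edge behind the frame, adjacency to a
stripped band counts as touching that edge; this same rule makes a breast
that merely reaches under a frame on its chest side segment normally. The
no-vertical-edge rule is our addition: it enforces the breast-mask
invariant rather than leaving floating components to produce nonsense
densities. Empty or constant images fail with `FAIL_EMPTY_IMAGE`. The
thresholds behind these rules are exposed in `density_config()` and
snapshotted with every run.

No pectoral-muscle handling is performed: these are CC views.

### Preprocessing

Inside the breast only: a median filter of radius `median_radius` (default
1), then a linear contrast stretch clipped at the `stretch_lo_pct`/
`stretch_hi_pct` breast-pixel percentiles (defaults 1 and 99; `0`/`100`
recovers a pure min–max stretch). Two deliberate details:

* **Mask-restricted windows.** At the breast boundary the median window
  excludes background pixels entirely instead of mirroring or zero-padding;
  background zeros would otherwise drag boundary medians toward the
  background and thin the segmented dense rim. Even-sized windows take the
  lower integer mean of the two central order statistics, keeping output
  integral.
* **Clipped stretch.** Pure min–max stretching is hostage to single hot or
  cold pixels; nearest-rank percentile clipping makes the stretch robust to
  residual specks. Whether the clip points should be 1/99 or 0/100 is an
  open choice; both are reachable via configuration.

The dense-pixel *set* (and hence dense area and percent density) is
invariant to affine gain/offset changes of the intensities, because the
threshold criterion rescales uniformly under affine maps; the stretch
therefore changes the reported threshold's units but not the measured
areas on images it maps affinely.

### The threshold criterion

For a cut `t`, let class 0 be breast pixels with intensity ≤ t (count
`n0`, intensity sum `S0`) and class 1 the strictly brighter pixels. The
package maximises

$$J(t) = \frac{(S_0 n_1 - S_1 n_0)^2}{n_0 n_1} = n_0 n_1 (\mu_0 - \mu_1)^2$$

over all intensities present in the breast. `J` is a positive rescaling of
the classic between-class variance, so its maximiser is the
between-class-variance maximiser; the formulation via `S0`, `S1`, `n0`,
`n1` is chosen because those are exact integers in double precision, which
makes `J` deterministic up to a single final rounding and lets the test
suite demand *exact* agreement with an independent exhaustive scan. Ties
take the smallest candidate. "Dense" means *strictly greater than* `t*` —
fixed once, so criterion and mask cannot drift by one level. The criterion
sits behind a single interface (`compute_threshold()`) so an alternative
(e.g. entropy-based) could be swapped in and compared.

Degenerate (constant) breast histograms return the maximum breast
intensity, giving dense area 0, with a `degenerate` flag — the density
stage never hard-fails on a successfully segmented breast; only breast
segmentation can reject an image.

## The phantom generator

`generate_phantom()` emulates the artefact inventory of scanned screening
film: a half-ellipse breast attached to one vertical edge, dense discs
whose union is solved (by bisection on a common radius scale, re-seeded up
to 100 times) to hit a target dense fraction within ±2% of breast area,
additive Gaussian film grain clipped to the intensity range, an optional
maximal-intensity border frame, and an optional detached bright tag blob.
Ground-truth breast and dense masks are returned, satisfying the same
invariants the pipeline's masks declare. Generation is deterministic given
the `phantom_spec` object (one seeded RNG per call; the caller's RNG
stream is untouched).

Defaults (256×256, 8-bit, fatty mean 110, dense mean 190, background 8,
noise SD 6) represent a clean, high-contrast film scan. What the phantom
does **not** emulate: parenchymal texture, scatter/blur, spatially varying
illumination, or X-ray physics. Passing the phantom recovery tests
therefore demonstrates correctness of the algorithmic contract (exact
thresholding, artefact handling, failure detection), not clinical accuracy
on real film, which would require validation against expert readings.

## The cohort simulator

`generate_cohort()` draws, per woman: a latent density percentile uniform
in the screened population; a dense-area value via a lognormal quantile
transform (median ≈ 20,000 px, `sdlog` 0.8, matching the scale of
film-digitised dense areas); screening covariates (six age bands 40–49 …
70–79, hormone-therapy use 20%, family history 10%, symptoms 15%, first
round 45%); and an outcome from a multinomial logistic model over
{control, small screen-detected, large screen-detected, interval} whose
coefficients are the designed log-odds. Controls carry analysis weight
1/0.0155 (first round) or 1/0.0325 (subsequent rounds) — the inverse
control-sampling fractions of the emulated study design — and cases weight
1. Default density effects rise linearly on group percentile midpoints to
highest-decile odds ratios of 2.2 (small), 6.4 (large) and 4.7 (interval)
versus the lowest quintile, the magnitudes reported for film screening
cohorts. A second, correlated density measure (normal copula, ρ = 0.63) is
generated for the agreement analyses.

For the parameter-recovery experiments the acceptance harness uses a
deliberate simplification: small and large screen-detected cancers share
one coefficient vector. Then the case-only log-odds of interval versus
screen-detected cancer is *exactly* linear in the model terms, so the
designed reference-profile programme sensitivity (70%, i.e. interval odds
3/7 among cancers at Q1) is identifiable without misspecification bias.
The generator's defaults keep distinct per-outcome coefficients; the
simplification is an experiment design, not a package default.

## Statistical conventions

* **Weighted percentiles** use the mid-rank weighted CDF,
  `100·(W(<v) + W(=v)/2)/W`: ties share a percentile, and a weight-2 record
  equals two unit-weight copies exactly.
* **Group boundaries** are left-closed (`[20,40)` …); a percentile exactly
  on a cut joins the upper group. `[90,100]` is the top decile.
* **Odds-ratio models** are unconditional ML logistic fits (exposure: the
  six density groups, Q1 reference; adjustment: age group, hormone-therapy
  use, family history, symptoms, screening round), with Wald 95% CIs on the
  log-odds scale. On a 2×2 table this reproduces `ad/bc` with the Woolf
  interval exactly, which the tests assert. (Near-)separation raises an
  explicit error naming the offending term; the batch driver reports and
  skips such contrasts instead of aborting. A round×density interaction
  term is available for tests of whether rounds require separate analysis.
  No multiple-testing adjustment is applied.
* **Programme sensitivity** shares the same fitting core: a case-only
  logistic model of interval vs screen-detected cancer; sensitivity is the
  pure transform `100/(1+odds)` of the predicted odds for a covariate
  profile, with CIs obtained by transforming the linear-predictor interval
  (guaranteeing limits inside [0, 100]). The CI method for predicted
  sensitivity is a documented choice, not a claim about how any particular
  historical analysis computed it.
* **AUC** is the Mann–Whitney statistic with ties counted one half —
  exactly pair counting, which the tests verify by brute force.
* **Trend tests**: the Cuzick rank test for ordinal groups (permutation
  mean/variance with the standard tie correction; zero variance returns
  z = 0) and Kruskal–Wallis for nominal groups. P-values use the normal/χ²
  approximations.
* **Agreement**: Pearson correlation of weighted percentiles (p-value via
  the Fisher transform with the effective sample size `(Σw)²/Σw²`),
  Bland–Altman on natural-log dense areas (non-positive pairs are dropped
  from this component only, with the count reported), and a weighted 6×6
  cross-classification whose perfect agreement is the trace and whose
  within-one agreement counts cells `|row − col| ≤ 1` (diagonal included).

## Problem sizes used in the test and acceptance harnesses

Chosen as the smallest sizes at which each property is sharply testable:
200 mixed phantoms (128×128 8-bit and 64×64 16-bit) for the
threshold-oracle sweep; 40 clean 256×256 phantoms across dense fractions
{0.10, 0.25, 0.40, 0.60} for density recovery; a 100-image batch with 5%
constructed violations for failure-mode fidelity; and 200 replicates of
50,000-woman cohorts per designed odds ratio {1.5, 3, 6} for CI coverage
and sensitivity recovery. At 200 replicates, the Monte-Carlo SD of an
empirical 95% coverage is about 1.5 percentage points.

## Known limitations

* The threshold criterion is a documented stand-in honouring the published
  behavioural contract of film-density tools (per-image optimal threshold,
  no cross-image standardisation, zero failures at the density stage); no
  claim is made that it reproduces any specific proprietary implementation
  pixel for pixel.
* Area-based density only: no volumetric estimation, no step-wedge
  calibration, no raw digital-mammography support, no DICOM ingestion, no
  MLO-view (pectoral muscle) handling.
* Failed segmentations are final; no alternative-strategy retries.
* The simulators are validation instruments. Their realism limits
  (texture-free phantoms; additive clipped Gaussian grain; independence of
  covariates and density in the cohort model) are deliberate and documented
  above.
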
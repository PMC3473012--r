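---
title: "Mapping local cell-cycle length from dual thymidine-analogue labelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping local cell-cycle length from dual thymidine-analogue labelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxelcycle)
```

## The model

Thymidine analogues (IdU, CldU, BrdU, EdU) are incorporated into DNA only
during S-phase. If an analogue is administered for the final $T_{exp}$ hours
before fixation, a cell is labelled exactly when its S-phase overlaps that
window. Under the standard assumptions — cycling cells occupy a random phase
of the cycle, cycle length $T_C$ is locally constant, and the population does
not grow during the exposure — the labelled fraction is

$$F \;=\; GF \cdot \min\!\left(1,\; \frac{T_S + T_{exp}}{T_C}\right),$$

with $T_S$ the S-phase length and $GF$ the growth fraction (the fraction of
cells cycling at all). Exposing one specimen to *two* analogues for two
durations that both end at fixation gives two labelled fractions measured on
the *same* nuclei, and their difference is linear in the exposure-time
difference:

$$\frac{\Delta F}{\Delta T} = \frac{GF}{T_C}
  \quad\Longrightarrow\quad
  T_C = \frac{GF \cdot \Delta T}{\Delta F},
  \qquad T_S = F_{short} \cdot T_C - T_{exp,short}.$$

Because both fractions share one denominator (the same counted nuclei), the
sampling error of the totals largely cancels in $\Delta F$ — the reason this
design is far more precise than comparing labelling indices across
specimens.

`expected_labelling_index()`, `simulate_population()`,
`estimate_cycle_length()` and `estimate_s_phase()` implement this model;
`simulate_cycle_experiment()` wraps replicate simulation plus estimation.

### Growth fraction and doubling time

With `growth_fraction = 1` (the default everywhere) the estimator returns
the *population doubling time*. True $T_C$ requires an independent per-boxel
growth-fraction measurement (e.g. Ki67), which can be supplied to
`cycle_maps()` as a scalar or per-boxel vector. The two quantities are
deliberately kept distinct in the documentation because they are different
biological parameters that happen to coincide when every cell cycles.

### Censoring

When $\Delta F \le \Delta T / T_{max}$ the cycle length cannot be resolved
below the cap $T_{max}$ and the estimate is reported right-censored as
"> `r 32` h". The default cap of 32 h matches the regime in which slow
embryonic myocardium is typically reported. Censored values carry
`censored = TRUE` and the cap value, so they stay usable downstream (e.g. in
clustering, where dropping them would delete exactly the slow-cycling
population of interest).

### The nested design

The short exposure is the terminal part of the long one, so every truly
short-labelled nucleus is also long-labelled. This makes one-directional
antibody cross-reactivity (long-analogue antibody recognising the short
analogue) irrelevant, and it is why `exposure_schedule()` refuses
non-nested schedules. The default schedule is 4 h (long) / 1 h (short),
i.e. $\Delta T = 3$ h.

An optional `dead_time_h` models an incorporation lag by shortening both
windows; it defaults to 0, and no claim is made that this matches any
particular derivation of non-instantaneous uptake.

## The measurement chain

### Detection (`detect_nuclei()`)

Per section: a 3×3 adaptive (Wiener) filter whose noise variance is the mean
of the locally estimated variances; subtraction of a moving-average
background (default window 10 px, ideally about one nucleus diameter), which
makes detection independent of smooth background gradients; thresholding
(per-section Otsu on the background-subtracted image by default — the
histogram-based threshold is computed on the possibly-negative filtered
values, and can be overridden with a fixed `maxima_threshold`); 8-connected
components with a minimum object area (default 4 px).

Objects larger than twice the median object area are treated as possibly
fused. Markers are the regional maxima of the object's intensity after
grey-value opening-by-reconstruction with a disc whose radius is tied to the
median nucleus size ($\lceil\sqrt{A_{med}/\pi}/2\rceil$ px, self-calibrating),
and pixels are partitioned among markers by seeded propagation on the
intensity image. Oversized objects with a single interior maximum are left
whole. The operation is idempotent.

Detection is strictly 2D per section: per-section counts are later converted
to volume densities with Abercrombie's correction, so linking nuclei across
sections would double-correct. Centroids are intensity-weighted (sub-pixel);
the rounded "centre pixel" is used only for control images. Note that the
even 10 px background window is anchored half a pixel off-centre (as
moving-average filters with even windows are), which limits centroid accuracy
after preprocessing to about 1 px; this is irrelevant at 21 µm boxel
resolution.

### Classification (`classify_nuclei()`, `calibrate_short_threshold()`)

Analogue staining is speckled, so per-nucleus calls use means over the
nucleus's pixels against a local background ring from which all detected
nuclei (dilated by `exclusion_dilation_px`) are excluded; the ring expands if
too few background pixels remain. The difference is standardised by the
experiment-wide mean of the local background standard deviations, and a
nucleus is positive when that standardised difference reaches `k_sd`
(long analogue: 1 sd by default).

The short-analogue threshold is re-calibrated per experiment against the
known double-labelling ratio (default 0.928: at equal exposure the long
analogue is detected in 92.8% of the nuclei in which the short one is,
a constant 7.2% deficit). Two implementation details matter:

* **Plateau noise.** The double ratio as a function of the threshold rises
  while false positives drop out, then plateaus near the true detection
  efficiency — but the plateau of a finite experiment fluctuates (binomial
  sd ≈ 0.008 at ~1,000 short-positives). An algorithm that insists on
  crossing the target ratio exactly either fails spuriously or discards
  genuine short-positives chasing noise. The calibrator therefore pools the
  observed ratio curve with count-weighted isotonic regression (the curve is
  non-decreasing in expectation, since raising the threshold only removes
  short-positives) and selects the smallest threshold whose *mirror-estimated
  contamination* — the count of nuclei at or below the negated threshold,
  valid because unlabelled standardised differences are symmetric about
  zero — is at most 0.5% of its short-positives. The target ratio is then
  checked at that threshold: calibration fails only when the pooled ratio
  falls short of the target by more than `max(0.002, 3 binomial SE)`,
  i.e. by more than counting noise can explain.
* **Compensation direction.** The 7.2% deficit is corrected by *dividing*
  long counts by 0.928 (×1.0776), not multiplying by 1.072, because the
  measured relation is detected-long = 0.928 × detected-short.

### Boxel quantification (`quantify_boxels()`)

Nucleus records are binned into cubic boxels (21 µm edge). Every quantity
assigned to a boxel is measured over a 105³ µm³ sampling window centred on
it (an odd multiple of the boxel edge), restricted to one mask material;
the window slides one boxel at a time, which deliberately smooths
neighbouring boxels in exchange for reliable per-window counts. Boxels whose
window holds fewer than `min_nuclei_per_sample` records (default 30, which
bounds the binomial SE of an index by about 0.09) carry no indices. The grid
is anchored at the included material's bounding-box minimum with half-open
boxel intervals, so central assignment is an exact partition. In z,
records carry their section's mid-plane depth; window membership is
evaluated in µm, so no rounding to whole sections is needed.

Cell size uses Abercrombie's correction: the areal density over the window's
sections, $N_A$, overcounts nuclei cut by more than one section, so
$N_V = N_A / (t + d)$ with $t$ the section thickness and $d$ the mean
nucleus diameter (estimated from the median detected object area, or
supplied); the average cell size is $1/N_V$ µm³. Boxels where
$F_{short} > F_{long}$ are flagged inconsistent and excluded from the maps,
since under the nested design that indicates calibration failure rather
than biology.

### Clustering (`cluster_boxels()`)

K-means (squared Euclidean) on z-scored cell size and cycle length, with 20
restarts and a seed; labels are canonicalised by increasing mean cycle
length so repeated runs are comparable. Censored cycle lengths enter at the
cap value with their flag (config: `censored_policy`), a choice made here
explicitly rather than inferred from any prior practice.
`spatial_contiguity()` reports, per cluster, the fraction of boxels whose
6-neighbourhood majority shares their label — clusters formed without
spatial information but spatially organised score near 1, permuted labels
near their size fraction.

## The phantom

`phantom_spec()` / `generate_truth()` / `render_sections()` emulate what the
wet protocol produces: aligned 16-bit per-section channels (nuclear stain,
two analogues) plus an integer material mask, with full ground truth.

* Nuclei are a hard-core point process (dart throwing) at each region's
  density. The hard-core separation defaults to the nucleus diameter
  (non-overlapping nuclei); the standard two-region phantom uses 1.2
  diameters because nuclei sit in cells — at tissue densities,
  centre-to-centre spacings below that leave nuclei superimposed within a
  section, which no 2D detector can resolve.
* Label states are drawn per region from the population model
  (via `simulate_population()`), then long-label detectability is thinned
  by `detection_efficiency_long` (default 0.928) — this is what the
  calibration and compensation machinery is later asked to recover.
* Each nucleus is a sphere appearing in every 5–7 µm section slab it
  intersects, with in-plane radius equal to its maximal chord in the slab;
  this is what makes the Abercrombie correction genuinely testable.
  Intersections with chord radius below `min_chord_um` (default 2 µm) are
  below the phantom's detection floor: such grazing caps hold roughly a
  tenth of the nuclear volume and are neither rendered nor listed as
  detectable truth.
* The nuclear profile is a squared projected-sphere dome (centre-weighted
  chromatin); analogue labelling is Bernoulli per-pixel speckle at density
  0.35. Backgrounds have a planar gradient plus Gaussian noise.
* The per-section *detectable truth* additionally merges appearances whose
  centres lie closer than `merge_factor`·(r₁+r₂) (default 0.65) in
  projection — a widefield section physically shows one blob there — into
  one object carrying the dominant constituent's labels.

### The standard two-region phantom

`two_region_phantom_spec()` places a fast region (true $T_C$ = 8 h,
$T_S$ = 3 h, 6×10⁻⁴ nuclei/µm³, 84×126×60 µm) beside a slow region
(true $T_C$ = 40 h, $T_S$ = 8 h, 2.6×10⁻³ nuclei/µm³, 126×126×60 µm), both
with growth fraction 1, at 0.5 µm/px in 5 µm sections with 5 µm nuclei —
section thickness of the order of the nucleus diameter is the same regime
as 7 µm sections of ~7 µm embryonic nuclei, and keeps within-slab nuclear
superposition rare. The slow region is deliberately dense: distinguishing
$\Delta F = 3/40$ from the censoring boundary $3/32$ requires on the order
of a thousand nuclei per sampling window (binomial power analysis), while
the fast region's $\Delta F = 0.375$ is easy. The whole phantom holds
roughly 3,000 nuclei and renders plus analyses in seconds.

### What the phantom does not emulate

No optical PSF or depth attenuation; no chromatic mis-registration or
section-to-section deformation (inputs are assumed aligned); speckle is
independent Bernoulli rather than clustered grains; nucleus size is
constant per region; label dilution across divisions and cell migration are
absent; noise parameters are free settings, not fitted to any instrument.
Passing the phantom tests therefore demonstrates correctness of the
measurement chain under its own model assumptions, not performance on real
microscopy. One intrinsic effect the phantom *does* reproduce: when two
nuclei overlap in projection, the blob's label call is effectively an OR of
its constituents, which inflates both labelling indices slightly — a bias
real dense sections share.

## Test and validation scale

The validation suite simulates 100-replicate experiments at 2,000 cells for
the fast (8 h) and slow (40 h) regimes, checks closed-form/simulation
agreement at n = 10,000, and runs the full imaging pipeline on three
replicates (seeds 1–3) of the standard phantom, pooling their boxels: a
single ~2,500-nucleus realization measures the slow-region censoring
fraction with several percent of sampling noise, and replication is the
appropriate remedy. Threshold robustness (long-analogue threshold at 1, 2
and 3 sd with recalibrated short threshold) is checked on one phantom
replicate by re-thresholding the stored standardised differences.

## Known limitations

* With growth fraction unknown, maps are doubling-time maps; see above.
* The exposure time must be shorter than G2+M, or labelled cells divide
  during exposure and cycle lengths are underestimated; the simulator warns
  only in the extreme case $T_{exp} > T_C$, the user owns the rest.
* Boxels near tissue boundaries have clipped sampling windows: unbiased but
  noisier, which matters most where $\Delta F$ is near the censoring
  boundary.
* The annulus background is sampled isotropically around the nucleus; in
  strongly anisotropic backgrounds the local-background estimate can be
  biased despite the gradient subtraction in detection (classification
  reads the raw analogue channels).
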
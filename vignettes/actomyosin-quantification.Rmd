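---
title: "Quantifying actomyosin motility, cell morphometry and ring constriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actomyosin motility, cell morphometry and ring constriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`actomotion` quantifies three related readouts of the actin–myosin
interaction:

1. **In vitro gliding (surface motility) assays.** Fluorescent actin
   filaments glide over a myosin-coated surface; a time-lapse movie is
   segmented, filaments are tracked, and abrupt displacements
   ("wobbling") or losses ("detachment") are scored with a frame-ratio
   change detector.
2. **Spherocylinder cell morphometrics.** Fission-yeast cells are
   modelled as cylinders with hemispherical caps; volume and surface
   area follow from per-cell length and width.
3. **Cytokinetic-ring phase timing.** Per-cell traces of ring state and
   diameter are segmented into node coalescence, dwell and constriction
   phases, giving total cytokinesis time and constriction rate.

Because raw assay movies are rarely shareable, the package includes a
ground-truthed simulator for each input so that every stage is testable
end to end.

# The frame-ratio event detector

## Model

Let $I_t$ be frame $t$ of the movie. Each frame is smoothed with a
Gaussian of standard deviation $\sigma_b$ (default 2 px; "blur radius"
in common imaging software denotes this sigma), and the ratio stack

$$R_t = \frac{\tilde I_{t+1} + \varepsilon}{\tilde I_t + \varepsilon}$$

is formed, where $\varepsilon$ (default $10^{-6}\times$ the movie
median) guards empty denominators without perturbing realistic
backgrounds. Where nothing changed, $R_t \approx 1$; where a filament
landed, $R_t \gg 1$; where one left, $R_t \ll 1$.

The decision threshold is derived from the background of the *original*
movie, segmented per frame and pooled per movie:

$$\theta = 1 + k\,\frac{\mathrm{SD}_{bg}}{\mathrm{mean}_{bg}},\qquad k = 4.$$

With background mean 100 and SD 5, $\theta = 1.2$. Connected
supra-threshold components of at least `min_spot_area_px` (default 4)
pixels become candidate spots; spots in the same or adjacent
ratio-frames within `merge_radius_px` (default 5) of each other are
merged into one event, because one physical event routinely exceeds
threshold in two successive ratios and, at realistic noise, its
footprint can break into fragments along the filament. Fragments are
united by morphological closing before labelling, and spot centroids
are weighted by the ratio-change magnitude, which localises an
asymmetric footprint better than the unweighted mask.

## One-sided vs two-sided detection

The default is one-sided (only $R > \theta$, i.e. brightening), which
matches the convention of displaying ratio projections on a linear
$[1.3, 3]$ scale. A detachment in which the filament simply vanishes
produces *only* a darkening footprint; with `two_sided = TRUE` the
detector also tests $1/R > \theta$ and catches it. The simulator's
detached filaments vanish outright (they do not rebind or drift in
focus), so the detector benchmarks in this package run two-sided; on
real movies, where detaching filaments often reappear nearby, the
one-sided default already sees most events.

## The detection floor, and how the simulator defaults were chosen

The assay movies behind this pipeline are not public, so the simulator
defines the study conditions. Most defaults are straightforward
(1-min movies at 1 s/frame — the nonmuscle-myosin condition; 0.065
um/px; background mean 100, SD 5; 10 filaments per field; gliding
speed 0.2 um/s; 60% motile). Two interact with the detector and were
set by analysis, not trial:

* **Peak SNR 5 with PSF sigma 4 px.** For a ridge-like filament of
  cross-sectional width $\sigma_1$ blurred by the detector's
  $\sigma_b$, the peak attenuates by
  $\sigma_1/\sqrt{\sigma_1^2+\sigma_b^2}$. A supra-threshold response
  requires the *blurred* peak to exceed $k\cdot\mathrm{SD}_{bg}$ — a
  floor independent of the background mean. At peak SNR
  $A/\mathrm{SD}_{bg} = 5$ and $k = 4$, detection therefore requires
  attenuation above $4/5 = 0.8$, i.e. $\sigma_1 \gtrsim 2.7$ px.
  The default $\sigma_1 = 4$ px places an SNR-5 filament at
  $4.47\,\mathrm{SD}_{bg}$ after blurring: above the floor, but close
  enough that the recall benchmark is informative rather than trivial.
  SNR and PSF are config knobs, not claims about any particular
  instrument.
* **Filament lengths 1.5 ± 0.4 um, truncated below at twice the PSF
  FWHM (~1.2 um).** A fragment much shorter than the PSF renders as a
  point spot whose longitudinally attenuated peak falls below the
  floor; such fragments are not countable "filaments" in this assay and
  are excluded from the length distribution rather than silently
  missed.

Wobbles displace the whole filament laterally by 1.5 um within one
frame; gliding reflects off a soft field boundary and a wobble that
would exit flips inward, so ground-truth events stay in view. Noise is
additive Gaussian: the threshold formula consumes only the background
mean and SD, so Poisson statistics would add realism the detector
cannot distinguish. Not modelled (and therefore untested here):
photobleaching, fixed-pattern noise, focus drift, filament crossing
resolution, rebinding after detachment.

# Segmentation and measurement

Filaments are segmented per frame from the smoothed image by a robust
threshold: background mean and SD are seeded from the frame median and
MAD (×1.4826), and pixels above mean + `k_sigma`·SD (default k = 4)
form the foreground. Otsu's method is available as an alternative but
is not the default: on frames with little or no foreground — the normal
case in a sparse assay — Otsu places its threshold inside the noise
distribution and corrupts the background statistics that the event
threshold depends on. The robust threshold is invariant to adding a
constant offset to the frame.

Filament length is the geodesic diameter of the morphological skeleton
(Zhang–Suen thinning; step weights 1 and $\sqrt 2$) times the pixel
size. Thinning erodes rounded ends by roughly the mask half-width while
thresholding extends the mask slightly past the true ends, so the
estimate is nearly unbiased when the mask is thin (narrow PSF, strong
signal) and biased short when the mask is much wider than the object.
The length-recovery tests therefore run in a thin-mask imaging regime
(PSF sigma 1 px, amplitude 12 SD); with the broad default PSF the
skeleton underestimates length by ~15–20% — a resolution property, not
a bug, and worth remembering when comparing length distributions across
imaging conditions.

Background statistics are pooled over the label-0 pixels of all frames,
one (mean, SD) pair per movie.

# Tracking and motility summaries

Linking is greedy globally-nearest-pair between consecutive frames,
with a per-step gate `max_disp_um` (default 2 um — above the wobble
jump, so a wobble displaces rather than splits its track), a gap
tolerance of 1 frame, and a minimum reported track length of 5 points.
Densities in these assays are low; the determinism and reviewability of
greedy linking outweigh the marginal optimality of global assignment.
Crossing filaments can still fragment tracks, which inflates track
counts in dense fields; the summary therefore reports both the mean
per-frame segmented count ("landed filaments") and the track count.

"Moving" is not defined in most assay reports; here a track is moving
iff its mean frame-to-frame speed exceeds 0.05 um/s *and* its net
displacement exceeds 0.5 um. The dual criterion excludes stationary
filaments whose centroids jitter with noise (jitter alone can reach
0.05–0.08 um/s at these settings). Note that a filament that wobbles
repeatedly can legitimately satisfy both criteria.

Speed is the mean over consecutive point pairs of displacement divided
by elapsed time; on curved paths this recovers the true speed times the
chord/arc factor, within 2% at ten or more samples per revolution.

# Spherocylinder morphometrics

With total length $L$ (including caps) and width $w$:

$$V = \pi (w/2)^2 (L - w) + \tfrac43 \pi (w/2)^3, \qquad
  SA = 2\pi (w/2)(L - w) + 4\pi (w/2)^2.$$

At $L = w$ both reduce exactly to the sphere. Cohort summaries compute
per-cell values first and then average; evaluating the formula at the
cohort mean dimensions agrees with the cohort mean of per-cell values
to within ~1–2% for coefficient of variation up to 10%, because the
formulas are only mildly nonlinear. Records violating
$L \ge w > 0$ are dropped with a warning rather than failing the
cohort. Rank-sum p-values use the normal approximation with tie
correction; exact enumeration is infeasible beyond n ≈ 50 and the
comparisons of interest are far from the significance boundary.

# Ring phase timing

A trace samples ring state every `frame_interval_min` (default 3 min):
`nodes` during coalescence, `ring` with a diameter during dwell and
constriction, `done` afterwards. The phases were historically timed by
eye; this module fixes reproducible rules, all snapped to the sampling
grid (the data are 3-min sampled; subframe interpolation would imply
precision the data do not carry):

* **Coalescence** — first `nodes` sample to first `ring` sample.
* **Initial diameter** — median of the first `smoothing_window`
  (default 3) ring diameters.
* **Constriction onset** — the sample *preceding* the first ring sample
  whose median-smoothed diameter has dropped below
  $(1 - 0.05)\times$ initial and stays down. Taking the first
  sub-threshold sample itself would systematically hand one frame of
  constriction to dwell; the preceding sample is the last moment the
  ring is demonstrably unconstricted, and recovers simulated dwell
  exactly when the phase boundary falls on the grid.
* **Constriction end** — the first `done` sample when the trace has
  one. The diameter threshold `end_diameter_um` (default 0.5 um) is a
  fallback for traces that end while the ring is still resolvable;
  applying it to complete traces would cut constriction short by
  (end/initial) × constriction ≈ 6 min at typical values, because a
  linear collapse spends its last ~13% of time below 0.5 um.
* **Censoring** — traces whose diameter never completes are flagged and
  excluded from summaries, not guessed.

Total time is the exact sum of the three phases (asserted, not
approximated), and the constriction rate is the initial diameter
divided by constriction time — "initial diameter" being the natural
reading of ring diameter for a rate that describes the whole collapse.
The simulator draws the three durations independently per cell
(truncated at one frame interval: a shorter phase is unobservable at
this sampling), an initial diameter of 3.7 ± 0.2 um — consistent with
the measured rates, since rate × constriction time = diameter — and
adds 0.05 um of diameter measurement noise.

# Problem sizes and numerical choices

The test suite and benchmarks run at the sizes the analyses are
reported with: 20 simulated movies (~30 events each) for
recall/precision, 50 pure-background movies for the false-positive
rate, 20 seeds for tracking identity, cohorts of 143/122 cells for
morphometrics, and 25 cells per strain (100 replicate pairs for the
ordering check) for ring timing. Gaussian kernels are truncated at
4 sigma and normalised; convolution uses reflective padding; the
separable implementation is tested against a dense brute-force
convolution oracle at 1e-6. Greedy linking breaks ties by lower label;
event lists are sorted by frame, then row, then column; all
coordinates are 0-based (frame, row, col), a single convention used in
every output. Simulations restore the caller's RNG state and are
bit-reproducible given a seed.

# What passing tests do and do not show

The simulators reproduce the statistical structure the analyses assume
— additive Gaussian noise, rigid gliding, vanishing detachments,
independent normal phase durations — not the full physics of an assay
movie. Passing benchmarks demonstrate that the pipeline recovers known
ground truth under those assumptions at realistic noise levels; they do
not certify performance on movies with focus drift, dense crossing
filaments, photobleaching, or motors with strongly heterogeneous
speeds. The morphometric and timing modules, by contrast, are exact
computations plus standard tests, and their checks against published
cohort statistics carry over directly.
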
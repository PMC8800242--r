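---
title: "Measuring elbow range of motion with electromagnetic tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring elbow range of motion with electromagnetic tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowrom)
```

This vignette explains the science inside `elbowrom`: the measurement
model, the statistics, the synthetic-data generator, and the numerical and
design choices that a user or reviewer should know about.

## The measurement model

An electromagnetic tracker reports, at 60 Hz, the position (mm) and
orientation (unit quaternion, scalar-first) of small sensors in the
transmitter's field. Two sensors are fixed to the humerus and forearm; a
third, hand-held, digitizes five bony landmarks: the greater tubercle
(`p_g`), the medial and lateral epicondyles (`p_m`, `p_l`), and the radial
and ulnar styloid processes (`p_r`, `p_u`). Digitization inverts the host
sensor's pose at each stylus sample and averages, so every landmark is
stored in a bone-fixed frame and can be reconstructed in world coordinates
from that sensor's pose alone — the core trick that makes the method
insensitive to where exactly the sensors sit on the segment.

The landmark-to-sensor assignment is fixed: the three humeral landmarks
ride on the humerus sensor, the two wrist landmarks on the forearm sensor.
Treating the radial styloid as rigid with a single forearm sensor is only
valid because the measurement protocol locks the forearm in supination; if
pro/supination were allowed, the radius would rotate relative to the ulna
and a second forearm sensor (or a radius-mounted one) would be needed.

With `p_lm2` the midpoint of the epicondyles and `p_ru2` the midpoint of
the styloids, the upper-arm frame takes `uz` along the shaft toward `p_g`,
`uy = normalize((p_l - p_lm2) × uz)` (normal to the plane of the lateral
epicondyle and the shaft), and `ux = uy × uz`. The forearm frame takes
`fz` from the wrist midpoint toward the elbow, `fy = normalize((p_r -
p_ru2) × fz)`, and `fx = fy × fz`. The flexion angle is

$$\varphi = \arccos(u_y \cdot f_y) \in [0^\circ, 180^\circ].$$

The notation conventionally used for these constructions is ambiguous
about cross-product argument order and axis signs; the order implemented
here is the one under which a straight arm gives `fy = uy` exactly and
therefore $\varphi = 0$, rising to ~135° in deep flexion. This is a
documented convention of this package, verified by construction in the
test suite, not a claim about any particular lab's internal sign choices.

Both `uy` and `fy` are normals of near-frontal planes, so $\varphi$ is in
effect a projected hinge angle. Two consequences are worth noting:

* **Hyperextension is unsigned.** `acos` cannot distinguish −5° from +5°;
  a hyperextended elbow folds onto small positive angles. Systems that
  need signed hyperextension must add a sign convention from a third axis;
  this package records the limitation instead.
* **The angle is invariant under any common rigid motion** of the whole
  arm (shoulder movement, patient repositioning), which the property tests
  assert to 1e-9 degrees.

## Plateau extraction

During a trial the examiner pauses roughly 3 s at each target angle. The
detector marks a sample "steady" when the SD of a centered rolling window
(default 0.5 s) is at most a threshold (default 1.5°); steady runs
separated by at most one sample are merged, runs shorter than a minimum
duration (default 2.0 s) are dropped, and each surviving run is summarized
by the mean and sample SD of its angles. The published protocols that
motivated this package do not state how a single angle per hold was
extracted from the timeline; the mean over the hold is used here because
it is the natural estimator under zero-mean sensor noise (a mid-hold
snapshot would inherit the full per-sample noise).

Defaults were sized once against the protocol, not tuned: a 0.5 s window
spans 30 samples at 60 Hz (enough to average sensor noise, short relative
to a 3 s hold); 1.5° cleanly separates holds (per-sample angle noise is a
few tenths of a degree) from ramps (a 45° transition in 1 s sweeps >20°
through any window); 2.0 s keeps genuine holds whose edges are eroded by
half a window on each side while rejecting brief pauses. All three are
exposed as parameters.

Matching plateaus to nominal targets takes, for each plateau, the nearest
nominal within 10°; when two plateaus claim the same nominal the closer
one wins and ties go to the earlier plateau. Unmatched plateaus are kept
with a missing nominal rather than discarded, so protocol deviations stay
visible.

## Agreement and reliability statistics

* **Pearson correlation** with the exact transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df for the two-sided p-value, and
  the conventional strength bands (slight ≤ 0.20 < fair ≤ 0.40 < moderate
  ≤ 0.60 < substantial ≤ 0.80 < almost perfect), band edges belonging to
  the lower band.
* **Bland–Altman** limits of agreement: differences are test minus
  reference, the SD uses the $n-1$ denominator, and the multiplier is the
  fixed 1.96 (not a t quantile) — the form in which such limits are
  conventionally reported. `limits_from_summary()` recomputes limits from
  a published mean ± SD row alone.
* **ICC** follows the Shrout–Fleiss definitions from the ANOVA mean
  squares — one-way random for intra-rater designs, two-way random for
  inter-rater designs, in single and average-of-k forms — with F-based 95%
  confidence intervals (Satterthwaite denominator df in the two-way case).
  Published reliability tables in this area are inconsistent about whether
  k counts repetitions or series (e.g. "ICC(1,3)" in text against
  "ICC(1,10)" in a table for the same analysis); both forms are exposed
  and k is always caller-supplied, so the package asserts neither reading.
  Estimates are reported clamped to $[-1, 1]$ (raw ANOVA ratios can fall
  outside on pathological data); the tests compare against an independent
  explicit sum-of-squares oracle to 1e-12 after mapping into the same
  domain.

## The synthetic-data generator

`sim_config()` encodes the study conditions as defaults:

| parameter | default | meaning |
|---|---|---|
| `rate_hz` | 60 | tracker sampling rate |
| `pos_noise_rms` | 0.76 mm | RMS of the 3-D sensor position error vector |
| `ori_noise_rms` | 0.15° | RMS sensor orientation error angle |
| `hold_s`, `ramp_s` | 3 s, 1 s | hold and transition durations |
| `hold_sd_deg` | 1° | examiner placement SD around each target |
| `digitization_noise_mm` | 0.76 mm | stylus-tip RMS during digitization |
| `artifact_gain` | 0.08 | soft-tissue artifact SD per degree of flexion (in vivo) |
| `xray_noise_sd_deg` | 1° | radiographic reading SD |
| segment lengths | 300/250 mm, half-widths 30/25 mm | adult arm geometry |

Noise conventions: position noise is isotropic Gaussian with per-axis
$\sigma = \mathrm{RMS}/\sqrt{3}$, so the RMS of the 3-D error vector
matches the stated accuracy (verified empirically to 5% in the tests);
orientation noise is a rotation by $|N(0, \mathrm{RMS}^2)|$ degrees about
a uniformly random axis. The stylus tip is taken as the stylus sensor
origin (an optional constant tip offset is supported); pivot calibration
is out of scope, so digitization error is modeled directly as tip noise.
Hold targets are clamped to $[0, 180]$ — an examiner cannot push through
the extension stop — which slightly truncates the placement distribution
at the 0° target; the hold-variability recovery test therefore pools the
unclamped targets.

The generator is a *simplified planar hinge*: flexion happens about a
fixed epicondylar axis with supination locked and no carrying-angle
obliquity, matching the bench protocol in which the measured quantity is
the single projected angle. Both reference sensor poses are deliberately
non-identity (translated and rotated off the bones' axes) so that the
digitization/reconstruction path is exercised with non-trivial transforms.

For in-vivo trials a soft-tissue artifact perturbs the forearm sensor by a
per-hold rotation with SD equal to `artifact_gain × true angle` — a
stand-in for brace displacement under biceps contraction. No quantitative
artifact model exists for this setting; the proportional form is this
package's own construction, motivated by the qualitative observation that
EMS–radiograph disagreement grows with flexion, and the 0.08 gain was
chosen once so that simulated flexion-difference SDs land near the
reported order of magnitude (~10°). The radiographic reference is modeled
as truth plus small Gaussian error, not as an image simulation.

What passing simulation tests do **not** show: the generator contains no
magnetic-field distortion, no marker occlusion, no muscle-driven artifact
dynamics, and no elbow deformity. In particular, the published in-vivo
correlations against radiographs (moderate r around 0.4–0.6 on real
arms) arise from real anatomy and cannot be reproduced by this simulator;
the package covers that regime only qualitatively (flexion spread larger
than extension spread, proportional error visible in the Bland–Altman
pairs).

## Seeding and determinism

One global integer seed drives everything; per-trial sub-seeds are derived
arithmetically (`seed + 104729·index mod 2^31 − 1`), so experiments are
reproducible byte for byte and individual trials can be regenerated in
isolation (the CLI `register` subcommand exploits this to replay the
digitization windows of a simulated trial).

## Numerical choices

* Quaternions are scalar-first and normalized on ingest; construction
  rejects norms within 1e-12 of zero. On file read, quaternions off unit
  norm by ≤ 1e-6 are renormalized silently, ≤ 1e-3 with a warning, and
  beyond that rejected as corrupt.
* `acos` arguments are clamped to $[-1, 1]$; dot products that round just
  past ±1 give exactly 0°/180° rather than NaN.
* Frame construction rejects landmark triples whose triangle area is
  below 1 mm² (collinear or coincident landmarks); in a time series such
  samples are excluded, counted in a warning, and indexed in an attribute
  rather than failing the whole trial.
* Frame orthonormality and right-handedness are asserted at 1e-9 by the
  `anatomical_frame` constructor itself, so no downstream code can hold a
  malformed frame.
* The rolling SD uses cumulative sums after removing the series mean —
  exact to within double rounding at these magnitudes — and window
  lengths are forced odd so the window is truly centered.
* Stream pairing is nearest-timestamp with a gap tolerance of half a
  sample period; anything worse is an alignment error, not a silent
  extrapolation.
* CSV/JSON serialization keeps 17 significant digits; rounding (1 dp for
  angles, 3 dp for r/ICC) happens only in printed reports.

## Problem sizes

The shipped experiments use the protocol's own sizes: 2 raters × 10
repetitions × 4 angles (80 plateau measurements) for the bench validation,
and 6 subjects × 2 raters × 3 repetitions (36 paired measurements per
position) for the in-vivo analog. A bench experiment runs in about a
second; the heaviest test (hold-variability recovery over 100 trials)
takes a few seconds.

## Known limitations

Single projected angle only (no carrying angle, pronation/supination or
varus/valgus laxity); unsigned hyperextension; no magnetic-distortion or
occlusion modeling; the soft-tissue artifact is a statistical stand-in,
not a biomechanical model; plateau detection assumes near-uniform
sampling; the in-vivo simulator shares one zero reference between EMS and
radiographs, which real protocols must establish by calibration.
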
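# elbowrom

Elbow range-of-motion (ROM) measurement from electromagnetic sensor
tracking, with the statistics needed to validate such a system against a
goniometer or radiographic reference.

## The problem

Clinical elbow ROM is usually measured with a universal goniometer, whose
accuracy and reproducibility suffer from soft-tissue landmarks and examiner
technique. An electromagnetic tracking system (EMS) offers an alternative:
two small sensors are fixed to the humerus and forearm, a third hand-held
sensor digitizes five bony landmarks, and the flexion angle is computed
from anatomical coordinate systems at 60 Hz. `elbowrom` implements that
whole measurement chain for people developing or validating such systems —
biomechanists, clinical-movement researchers, and methodologists who need a
reference implementation with a fully seeded simulator in place of the
hardware.

## The model

Five landmarks are digitized into their host sensor frames: `p_g` (greater
tubercle), `p_m`/`p_l` (medial/lateral epicondyle) on the humerus sensor,
and `p_r`/`p_u` (radial/ulnar styloid) on the forearm sensor. With
`p_lm2 = (p_m + p_l)/2` and `p_ru2 = (p_u + p_r)/2`, the upper-arm frame is

    uz = normalize(p_g - p_lm2)
    uy = normalize((p_l - p_lm2) x uz)
    ux = uy x uz

and the forearm frame is

    fz = normalize(p_lm2 - p_ru2)
    fy = normalize((p_r - p_ru2) x fz)
    fx = fy x fz

The elbow flexion angle is `phi = acos(uy . fy)`, in degrees: 0° for a
straight arm, ~135° in deep flexion. Held measurement phases (the examiner
pauses ~3 s at each target) are found with a rolling-SD plateau detector
and summarized as one angle per hold.

Validation statistics follow the standard method-comparison toolkit:
Pearson correlation with exact t-based p-values and conventional strength
bands, Bland–Altman 95% limits of agreement (mean difference ± 1.96 SD),
and Shrout–Fleiss intraclass correlation coefficients — one-way random for
intra-rater and two-way random for inter-rater reliability — with F-based
95% confidence intervals.

The simulator models a planar hinge driven through ramp-and-hold
trajectories, with the tracker's stated noise (0.76 mm position RMS, 0.15°
orientation RMS), examiner hold variability, stylus digitization error,
and — for in-vivo trials — a soft-tissue artifact whose spread grows with
flexion, paired with noisy radiographic readings.

## Worked example

Simulate one bench trial, run it through the pipeline, and reproduce the
full two-rater validation experiment:

```r
library(elbowrom)

cfg <- sim_config(seed = 42L)
trial <- simulate_model_bone_trial(cfg)
series <- angle_timeseries(trial$humerus_stream, trial$forearm_stream,
                           trial$registry)
plateaus <- match_to_nominal(detect_plateaus(series))
plateaus[, c("t_start_s", "t_end_s", "mean_deg", "sd_deg", "nominal_deg")]
#>   t_start_s   t_end_s   mean_deg    sd_deg nominal_deg
#> 1  0.250000  2.866667   1.447984 0.1963425           0
#> 2  4.133333  6.850000  44.396218 0.1861756          45
#> 3  8.150000 10.866667  90.340139 0.1852360          90
#> 4 12.133333 14.750000 135.610734 0.1593763         135

run_validation_experiment(cfg, "model_bone", n_reps = 10, n_raters = 2)
#> == Validation report (model_bone mode) ==
#> 2 raters x 10 reps at nominal angles 0, 45, 90, 135 deg
#>     0.0 deg: mean    0.50, SD  0.39 (n = 20)
#>    45.0 deg: mean   45.39, SD  1.11 (n = 20)
#>    90.0 deg: mean   90.25, SD  1.07 (n = 20)
#>   135.0 deg: mean  135.30, SD  0.71 (n = 20)
#> max |mean error| = 0.500 deg, max SD = 1.112 deg
#> Pearson r = 1.000 (almost perfect), n = 80, two-sided p = 5.701e-140
#> intra-rater ICC(1,10) = 1.0000, inter-rater ICC(2,2) = 1.0000
```

Each detected plateau is one measurement: its mean is the angle the
examiner held, its SD the within-hold sensor noise, and `nominal_deg` the
target it was matched to. The report aggregates 80 such measurements (2
raters × 10 repetitions × 4 targets): per-target bias stays well below 1°,
the spread is dominated by the 1° examiner hold variability, and both the
pooled nominal-vs-measured correlation and the reliability ICCs sit at the
ceiling — the behaviour expected of a tracker whose noise is two orders of
magnitude below the signal.

A command-line wrapper (`exec/elbowrom`) exposes the same pipeline as
subcommands: `simulate`, `register`, `angles`, `plateaus`, `agree`,
`validate`, each taking `--seed`, `--out` and friends.

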
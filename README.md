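# kinectqa

Quality assurance for markerless body-tracking recordings made with the
Azure Kinect DK and its Body Tracking SDK. Studies that record human
movement over months or years (gait labs, longitudinal cohorts) need to
know whether their camera and tracker deliver *comparable* results across
sessions — and ambient light, in particular additional infrared light, can
shift both the depth sensor's noise and the tracker's joint jitter.
`kinectqa` implements the metrics and the statistical protocol used to
audit that comparability, plus a synthetic-data generator so the whole
pipeline can be exercised and tested without multi-gigabyte recordings.

## What it computes

**Random error of depth measurement.** For a static scene, the per-pixel
random error over the analyzed frames is the RMS deviation from the pixel's
mean depth,

    re[p] = sqrt( Σ_t (d[p,t] − d̄[p])² / n_p ),

in millimetres, where invalid depth samples (sentinel 0: saturated, weak or
mixed fore-/background signal) are excluded and `n_p` is the pixel's number
of valid samples (a strict fixed-denominator variant is available).
Computed over user-chosen regions of interest and summarized as
min / max / median [IQR].

**Mean distance error (MDE) of joint trajectories.** For each joint j, a
sliding-window centroid

    c[j,t] = mean of positions over frames [t−N, t+N]   (N = 30 = fps)

is compared with the joint's position frame by frame,

    se[j,t] = ‖ p[j,t] − c[j,t] ‖ ,   MDE[j] = mean_t se[j,t],

with windows clipped at the sequence ends. For a static pose the MDE is a
pure jitter metric (under i.i.d. isotropic jitter of SD σ it converges to
`2·sqrt(2/π)·sqrt(2N/(2N+1))·σ ≈ 1.583 σ` for N = 30). The first 60 frames
of each recording are discarded to skip the tracker's start-up transient.

**Inter-joint distances.** Per-frame Euclidean distance between any two
joints — e.g. the ankles, giving stance width (static) or step width
(gait) — with boxplot-ready five-number summaries.

**Condition comparison.** The distributions of per-pixel random errors are
screened with a Lilliefors-corrected Kolmogorov–Smirnov test, then compared
with a Kruskal–Wallis test (independent light conditions) or a Friedman
test (the same pixels across repeated recordings), followed — when the
omnibus test is significant at α = 0.05 — by pairwise z-tests on mean ranks
with Bonferroni correction.

**Synthetic data.** `simulate_depth()` and `simulate_tracking()` generate
depth stacks (per-pixel Gaussian noise, invalid-pixel dropout, a moving
drop-out "black spot" blob) and static-pose joint trajectories (per-joint
isotropic jitter, decaying start-up transient, transient position peaks)
with known ground truth, reproducibly from a seed.

I/O uses the JSON dialect of the SDK's offline processor for tracking
results (32 named joints, millimetres, camera space) and a JSON manifest of
16-bit grayscale images for depth stacks.

## Worked example

A synthetic four-condition study in which the two infrared-on conditions
carry 15% more tracking jitter and higher depth noise:

```r
library(kinectqa)
sp <- standing_pose()
make_rec <- function(label, sigma_scale, depth_sigma, seed) {
  list(label = label,
       tracking = simulate_tracking(
         pose_sim_config(sp$true_positions, sp$sigma * sigma_scale,
                         n_frames = 2000), seed = seed),
       depth = simulate_depth(
         depth_sim_config(1900, sigma = depth_sigma, invalid_prob = 0.01,
                          n_frames = 500, height = 25, width = 25),
         seed = seed + 500))
}
recs <- list(make_rec("LightOff_IrOff", 1.00, 1.4, 1),
             make_rec("LightOff_IrOn",  1.15, 1.6, 2),
             make_rec("LightOn_IrOff",  1.00, 1.4, 3),
             make_rec("LightOn_IrOn",   1.15, 1.6, 4))
cfg <- experiment_config(recs, rois = list(roi("ankle", 0, 0, 25, 25)),
                         mode = "independent")
report <- run_experiment(cfg)
report
#> <experiment_report> 4 recording(s), mode independent
#>   MDE medians (mm): LightOff_IrOff 1.04, LightOff_IrOn 1.19, LightOn_IrOff 1.04, LightOn_IrOn 1.19
#>   comparisons: ankle p=0
```

The MDE medians recover the injected ordering: the infrared-on conditions
sit ~0.15 mm above the others. Per-recording details:

```r
report$recordings$LightOff_IrOff$mde
#> <mde_result> 18 joint(s), N = 30, frames 60..1999
#>   MDE median 1.04 [0.85; 1.61] mm
report$recordings$LightOff_IrOff$depth$ankle$summary
#> <depth_summary> min 1.29, max 1.56, median 1.42 [1.39; 1.46] mm (625 px, 2676 invalid samples)
report$comparisons$ankle
#> <comparison_result> kruskal_wallis: statistic 1852, df 3, p 0 (alpha 0.05)
#>   6 pairwise comparison(s), 4 significant after Bonferroni
```

The four significant pairs are exactly the IrOn-vs-IrOff contrasts; the two
like-vs-like pairs are not significant — the pattern such an audit is meant
to reveal. `make_report_tables(report, "out/")` writes the random-error
summary, the per-joint MDE table (per-joint minimum flagged, median/IQR
footer), stance-width five-number summaries, invalid-sample counts, tidy
pairwise results, a structured event log and a provenance block as
CSV/JSON.

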
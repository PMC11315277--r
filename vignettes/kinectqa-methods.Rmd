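---
title: "Quality-assurance metrics for markerless body tracking: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-assurance metrics for markerless body tracking: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectqa)
```

## The problem

A time-of-flight depth camera plus a markerless body-tracking model is an
attractive measurement instrument for movement studies: no markers, no
per-subject setup. Its downside is that the instrument is a black box
whose noise level can drift with the environment — most notably with
ambient and infrared light, since the sensor itself works by emitting and
timing near-infrared pulses. A study that records subjects over months
therefore needs a quality-assurance procedure answering two questions:

1. How noisy are the depth measurements and the tracked joint positions in
   a given recording?
2. Are recordings taken under different (or nominally identical)
   conditions statistically comparable?

`kinectqa` implements the three noise metrics and the comparison protocol
for this audit, on recordings of a *static* scene (a mannequin or any
motionless figure), where all frame-to-frame variation is instrument
noise.

## Metrics

### Per-pixel random error of depth

For pixel $p$ with valid depth samples $d[p,t]$ over the analyzed frames,

$$ re[p] = \sqrt{\frac{1}{n_p}\sum_{t}\left(d[p,t]-\bar d[p]\right)^2 }, $$

a population-variance RMS in millimetres. Invalid samples — the sensor's
sentinel 0, produced by saturated, weak, or mixed foreground/background
signal — are excluded from both the mean and the sum. Two conventions are
defensible for the divisor when invalid samples occur, and
`compute_random_error()` offers both:

* `denominator = "valid"` (default): divide by the pixel's own number of
  valid samples $n_p$. A pixel valid in exactly one frame then has
  $re = 0$ and a pixel never valid is undefined (excluded from
  summaries). This keeps $re$ an unbiased dispersion of what was actually
  measured.
* `denominator = "analyzed"`: divide by the fixed number of analyzed
  frames. This is the literal fixed-length normalization; it deflates
  $re$ for pixels with many dropouts and is provided for comparison.

Maps are computed over rectangular regions of interest. Region placement
is scene-dependent and therefore user-supplied configuration; typical
choices for a standing figure are a large torso patch (clean interior
surface), a knee patch, and an ankle patch that deliberately includes some
object boundary, where mixed-signal dropouts and boundary noise
concentrate.

### Mean distance error (MDE) of joint trajectories

For joint $j$, frame $t$, the sliding centroid
$c[j,t]$ averages the positions over frames $[t-N,\,t+N]$, and

$$ se[j,t] = \lVert p[j,t]-c[j,t]\rVert, \qquad
   MDE[j] = \frac{1}{T}\sum_t se[j,t]. $$

For a static pose this measures tracking *jitter* — there is no ground
truth involved. Two conventions needed fixing:

* **Root, not squared.** The per-frame error is the Euclidean distance,
  so MDE carries millimetre units and is comparable across joints; a
  `squared = TRUE` flag exposes the squared variant for completeness.
* **Clipped end windows** are normalized by their actual frame count
  (`normalize = "clip"`). Dividing clipped sums by the full $2N+1$ would
  shrink end centroids toward the coordinate origin — a clear artifact —
  but the `"full"` mode exists so the effect can be inspected.

Under i.i.d. isotropic Gaussian jitter of SD $\sigma$ per axis, the
residual $p - c$ has per-axis SD $\sigma\sqrt{2N/(2N+1)}$ (the window
includes the frame itself), so the distance is a scaled $\chi_3$ variable
and

$$ \mathbb{E}[MDE] = 2\sqrt{2/\pi}\,\sqrt{\tfrac{2N}{2N+1}}\;\sigma
   \approx 1.583\,\sigma \quad (N = 30). $$

This closed form is the package's main self-check: the acceptance suite
verifies the across-joint median of $MDE/\sigma$ lands in
$[1.57, 1.62]$ at 9{,}000 frames.

### Inter-joint distances

`joint_pair_distance()` returns the per-frame Euclidean distance between
two joints with a five-number summary — for the ankle pair this is stance
width, a posture quantity whose stability across recordings matters
directly for gait outcomes. Note that under independent jitter on both
joints the mean measured distance slightly *exceeds* the true distance
(Jensen's inequality); the bias is second-order in $\sigma$/distance and
negligible at millimetre jitter on a ~200 mm stance.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `cut` | 60 | frames | the tracker converges over the first ~2 s at 30 fps; frames 0–59 are discarded everywhere |
| `N` | `fps` (30) | frames | centroid window half-width; coupling to the frame rate gives a fixed 2-s (61-frame) window so jitter is measured against a locally stationary reference |
| `alpha` | 0.05 | — | the conventional level, applied to the screen, both omnibus tests and the adjusted pairwise p-values |
| joint selection | 18 joints | — | pelvis/trunk/neck, shoulders–wrists, hips–feet: the joints relevant for gait and posture; hand detail and face landmarks excluded |
| quantiles | type 7 | — | linearly interpolated order statistics, used identically for pixel maps and across-joint summaries |

## Statistical protocol

Random-error distributions are heavily non-Gaussian (boundary pixels
produce long right tails), so the protocol is: Lilliefors-corrected
Kolmogorov–Smirnov screen per group, then rank-based omnibus tests —
Kruskal–Wallis across independent conditions, Friedman across repeated
recordings of the *same pixels* (rows = pixels, columns = recordings,
incomplete rows dropped and counted) — and, only when the omnibus test is
significant, pairwise z-tests on mean ranks with Bonferroni multiplication
by the number of pairs. The Kruskal–Wallis post-hoc is Dunn's test with
the tie correction $\sum(t^3-t)/[12(N-1)]$ in the standard error; the
Friedman post-hoc uses $SE = \sqrt{k(k+1)/(6n)}$ on column mean ranks.
These are the procedures mainstream statistics suites run under "pairwise
comparison with Bonferroni correction"; exact replication of any
particular suite's p-values is not promised. Omnibus statistics come from
base R (`kruskal.test`, `friedman.test`, both tie-corrected); fully tied
inputs, where the rank statistics degenerate to 0/0, are defined as
statistic 0, p = 1.

Pixels are treated as independent observations, as this protocol implies.
Neighbouring pixels are in fact spatially correlated, so omnibus p-values
on pixel populations are anti-conservative; the package follows the
protocol and documents rather than corrects this (a caveat for
interpretation, not a computation choice).

The Lilliefors screen requires $n \ge 5$ per group (the plain-KS variant
$n \ge 4$). On thousands of pixels the screen rejects normality for any
realistic depth-noise map; the nonparametric path is effectively always
taken.

## The synthetic generator

`simulate_depth()` draws each pixel–frame as
$\mathrm{round}(\text{base}[p] + \varepsilon)$,
$\varepsilon\sim N(0,\sigma[p])$, sets it invalid with probability
$q[p]$, clamps negative depths to invalid (counted), and optionally
invalidates a moving disk of pixels — the "black spot" dropout artifact
observed when a dust particle drifts closer than the depth mode's minimum
range. `simulate_tracking()` draws per-joint isotropic Gaussian jitter
around a static pose, optionally preceded by an exponentially decaying
start-up offset (rate chosen so the offset falls below 1% of its initial
value within its configured length, default 60 frames — the data show
only "convergence", so the exact decay shape is a modelling choice) and
perturbed by a transient position peak on one joint. One master seed
yields reproducible output; depth and tracking draw from separate
streams so adding an artifact to one never shifts the other's draws.

What the generator deliberately does **not** model: temporal
autocorrelation of jitter is off by default (the audited quantities are
marginal SDs; an AR(1) knob exists for sensitivity probes), there is no
illuminance→noise coupling (the pipeline *measures* that relationship, it
does not assume one), and no physical time-of-flight simulation.
Consequently, passing tests demonstrate the pipeline's correctness and
sensitivity on data with the assumed noise structure — they do not certify
any physical camera.

Two numerical consequences of realism are worth noting:

* Depth values are integer millimetres, so a simulated $\sigma$ is
  recovered as $\sqrt{\sigma^2 + 1/12}$ (Sheppard's quantization
  correction); the calibration tests target the corrected value. At
  $\sigma \ge 1$ mm the inflation is below 4%.
* `standing_pose()` fixes the shared study conditions for synthetic
  experiments: an anatomically plausible 18-joint standing figure ~1.9 m
  from the camera, with per-joint jitter SDs spanning the realistic range
  for this tracker class (≈0.4 mm at the pelvis, ≈1 mm at ankles/wrists,
  ≈2 mm at the feet).

## Test and acceptance problem sizes

The unit suite runs small fixtures (≤ 9{,}000-frame single-purpose
sequences, 5×5×50 stacks against brute-force oracles). The acceptance
checks use: 9{,}000 frames for the $\chi_3$ closed form and σ-recovery
(matching a 5-minute recording at 30 fps); 2{,}000 frames per condition
for the multi-condition recovery studies (at that length the sampling
error of an MDE median is ~1%, an order of magnitude below the injected
15% effect); 2{,}000 null replications for the type-I calibration of both
omnibus tests (binomial 3σ ≈ 0.015 around 0.05); and full enumeration
(34{,}650 Kruskal–Wallis assignments, $6^7$ Friedman orderings) for the
exact-permutation oracles, where the χ² approximations are expected to
agree within 0.06 and 0.15 respectively at those sample sizes.

## Degenerate inputs and edge rules

* Pixels with no valid sample are undefined, excluded from summaries, and
  logged; a region with *no* defined pixel is an error.
* `cut` ≥ sequence length is an error; `cut = 0` is the identity.
* Frames with zero tracked bodies are gaps: recorded, logged, excluded
  from all means. Multiple bodies: body 0 is used, with a warning.
* Tracking JSON without an explicit joint-name list must carry exactly 32
  positions per body (SDK order); files written by the package always
  carry explicit names, so joint subsets round-trip.
* Depth stacks are stored as uncompressed 16-bit grayscale TIFF plus a
  JSON manifest — lossless and bit-exact on round trip; 16-bit PNG input
  is also accepted. 8-bit images are rejected.

## Interfaces

The package's functions are its interface: `run_experiment()` +
`make_report_tables()` orchestrate the full audit from a single config
object, and `scripts/acceptance.R` is a runnable end-to-end entry point.
No shell CLI is shipped: the intended users drive the analysis from R,
and every pipeline verb (simulate / depth-re / mde / pairdist / compare /
run) corresponds one-to-one to an exported function.

## Known limitations

* Statistical comparisons of pixel populations ignore spatial
  correlation (see above).
* The MDE is a jitter metric; it says nothing about absolute joint
  position accuracy, for which a non-interfering reference system would
  be required.
* Static scenes only: dynamic movement changes tracker behaviour in ways
  a static audit cannot capture.
* The generator's Gaussian jitter is an assumption; the real tracker's
  error distribution is unspecified and may be heavier-tailed.
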
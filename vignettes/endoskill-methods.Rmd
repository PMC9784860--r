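---
title: "Scoring endoscopic skill from simulation video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring endoscopic skill from simulation video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoskill)
```

## The problem

Flexible ureteroscopy (fURS) is hard to learn and risky to practice on
patients: wall contact can cause perforation, bleeding and infection, and an
incomplete inspection misses lesions. Bench-top kidney phantoms let trainees
practice safely, but most give no objective feedback. `endoskill` turns a
recorded phantom session — the endoscopic video plus a short annotation log —
into four quantitative skill scores, each on a 0–100 scale, and compares
groups of sessions statistically.

The four metrics:

* **Target Detection** — completeness of the examination: the percentage of
  renal calculi placed in the phantom that the operator exposed,
  $TD = 100 \cdot \mathrm{detected}/\mathrm{total}$.
* **Fine Movement** — quality of scope manipulation, via frame differencing.
  For frames $I_i$ and $I_{i-0.3\,\mathrm{s}}$ the difference image
  $D_i = |I_i - I_{i-0.3\,\mathrm{s}}|$ is binarized at a threshold
  $D_{Th} = 50$ (strictly greater), and the coverage $A_i$ is the percent of
  frame pixels set. A pair scores 100 when
  $\varepsilon_{low} \le A_i \le \varepsilon_{high}$ (inclusive) and 0
  otherwise — too slow and too fast both score zero. The session score is
  the mean over all sampled pairs.
* **Visualization** — how much of the view carries usable information.
  Pixels with intensity strictly above 245 are over-exposed; over-exposure
  commonly means the scope tip is against the wall. After a denoise step,
  each saturated blob's centroid distance $d$ from the frame centre is
  compared with the half-diagonal $r$ and weighted
  $w = 1$ for $d \le r/3$, $2/3$ for $r/3 < d < 2r/3$, $1/3$ for
  $d \ge 2r/3$ — central saturation is worst. A frame takes the maximum
  $w \cdot A$ over its blobs ($wA_i$), and the session scores
  $100\,(1 - \overline{wA_i}/100)$, clamped to $[0, 100]$.
* **Efficiency** — task time against a budget:
  $\mathrm{Duration} = 100\,(T_{max} - T)/T_{max}$ with $T_{max} = 5$ min,
  and Efficiency is the two-term average of Target Detection and the mean
  Duration.

Group comparison screens each group's scores for normality
(Kolmogorov–Smirnov at $\alpha = 0.05$) and applies an unpaired two-tailed
t-test, flagging significance at $p < 0.01$.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `diff_threshold` | 50 | gray levels | motion binarization; fixed constant of the method |
| `eps_low`, `eps_high` | 0.5, 20 | % of frame | the "appropriate speed" coverage band |
| `interval` | 0.3 | s | pair separation and trace cadence |
| `saturation_threshold` | 245 | gray levels | over-exposure cut |
| `opening_size` | 3 | px | denoise kernel (square opening) |
| `min_blob_area` | 0.02 | % of frame | denoise area filter |
| `t_max` | 5 | min | time budget |
| `alpha`, `p_threshold` | 0.05, 0.01 | — | normality screen, significance cut |

`eps_low`/`eps_high` deserve emphasis: they are **calibration parameters**,
not universal constants. The band that separates "appropriate" from "too
slow/too fast" depends on resolution-independent coverage, but still on
optics, lighting and phantom texture. The defaults (0.5% and 20% of frame
area) were chosen so that smooth continuous intubation of the synthetic
phantom scenes lands inside the band; recalibrate them once per capture
setup and keep them fixed across subjects being compared.

All percentages are relative to the native frame size (frames are never
resized), which makes coverage and blob areas resolution-independent; the
same changed-pixel *fraction* gives the same score at any resolution.

## Numerical and design choices

* **Strict vs inclusive boundaries.** Binarization and saturation are
  strict (`> 50`, `> 245`); the coverage band and the outer weight band are
  inclusive. These follow the metric definitions exactly and the tests pin
  them at the boundary values.
* **Pair alignment.** Pairs are taken at disjoint steps
  $t = k \cdot 0.3\,\mathrm{s}$ with nearest-frame rounding, so timestamp
  error is at most half a native frame period. (A sliding window — every
  frame differenced against the frame 0.3 s earlier — is a defensible
  alternative; disjoint stepping was chosen so each pair is an independent
  sample of the speed trace, and the cadence is configurable.) The number
  of pairs is `floor(last_timestamp / interval)`; when the duration is an
  exact multiple of the interval the final sampling time falls one frame
  period past the last frame and is dropped rather than double-counting the
  final frame.
* **Denoise step.** A 3×3 morphological opening followed by a minimum-area
  filter (0.02% of frame). Opening removes salt noise without eroding solid
  blobs (a solid digital disc survives essentially unchanged); the area
  filter catches surviving specks. Both are configurable; connected
  components use 8-connectivity.
* **Visualization composition.** The score is computed as
  $(1 - \overline{wA}/100) \cdot 100$ so that a blob-free video scores
  exactly 100 and a fully saturated central view scores 0; values are
  clamped to $[0, 100]$. Per-frame $wA$ uses the **maximum**-weighted blob;
  $wA$ is evaluated at the same 0.3 s cadence as the motion trace so the
  two traces align (full-rate evaluation is a config switch).
* **Duration clamping.** Sessions longer than $T_{max}$ would score
  negative (a 15.4 min session gives −208%); the score is clamped at 0 by
  default so every metric lives on $[0, 100]$, and the unclamped value is
  kept in the scorecard. Efficiency is read as the two-term *average* of
  Target Detection and mean Duration — both operands are percentages, and
  an average keeps the result on the same scale; the raw sum is also
  reported. Note that with a 5-minute budget even fast expert sessions
  (≈4.3 min) earn small Duration scores, so Efficiency saturates well below
  100 for realistic times; it is a ranking device, not an absolute grade.
* **t-test variant.** Welch (unequal variances) by default — the safer
  choice at n = 8 per group — with pooled-variance and Wilcoxon rank-sum as
  options. The KS normality screen uses sample-estimated parameters and is
  therefore approximate (anticonservative); a Lilliefors-corrected screen
  is available via `stats_config(normality = "lilliefors")`.
* **Degenerate inputs.** Zero sampled pairs (stream shorter than one
  interval) is a computation error for `fine_movement` but an empty pair
  list from `sample_pairs`; an all-equal histogram sample is flagged
  `degenerate` with SD 0; groups with fewer than 2 sessions refuse to be
  compared.

## What the synthetic generator emulates

Real validation data — phantom sessions by professionals and trainees —
cannot ship with a package, so `endoskill` includes a generator whose whole
point is *sharp, closed-form ground truth*:

* Frames are piecewise-constant over 0.3 s blocks, so each sampled pair
  spans exactly one block transition. At a transition the renderer changes
  **exactly** `round(f/100 * N)` pixels by more than the motion threshold
  (scene-event toggles first, then randomly drawn background pixels to make
  up the count, each shifted by 60 gray levels on a background confined to
  [30, 160]). Expected coverage is exact by construction, not statistical.
* Saturated blobs are sets of exactly `round(area/100 * N)` pixels placed
  so their centroid sits at a commanded fraction of the half-diagonal
  (iteratively recentred when the frame border clips the shape; the
  renderer verifies the realized centroid stays in the commanded weight
  band). Ground-truth $wA$ follows directly from the commanded geometry.
* Stone appearances at known times produce the annotation log.
* Backgrounds carry vessel-like random curves, mimicking the vascular
  patterns that give phantom scenes their texture.

Default scene dimensions are 96×72 px at 10 fps for 30 s — small enough
that a full render-and-score cycle takes a fraction of a second, large
enough that one block holds ~7000 pixels and commanded fractions are
realizable to within 0.008 points. These sizes are the package's validation
conditions; the scoring pipeline itself is resolution-independent and runs
unchanged on 1080p/60 fps recordings.

The presets encode the qualitative signatures of the two skill groups: the
**professional** profile moves continuously at in-band speed (≈88% of
transitions in band), shows rare small central saturation, finds all three
stones and finishes in ≈4.3 min; the **trainee** profile alternates static
and abrupt out-of-band movement, shows frequent larger saturated blobs
coinciding with abrupt motion (wall contact), always misses the
inferior-calyx stone — the hard target behind the infundibulopelvic angle —
sometimes a second, and takes ≈15.4 min. Preset parameters are drawn per
trial, so groups of trials have realistic within-group variance.

What the generator does **not** emulate: photorealistic anatomy, motion
blur, irrigation debris, lens distortion, lighting drift, or correlated
camera ego-motion. Passing the parameter-recovery and discrimination tests
therefore shows the *pipeline* is correct and discriminative under
controlled conditions; it does not validate the calibration of
`eps_low`/`eps_high` for any particular real capture setup.

## Known limitations

* Container decoding is not bundled: extract frames to a PNG directory
  (e.g. `ffmpeg -i session.mp4 frames/%06d.png`) and score the directory.
* Detected targets come from the annotation log; the package does not
  recognize calculi in video.
* The monotonicity of Visualization under added saturation holds for the
  generic cases the property tests exercise, but is not a theorem: a blob
  whose centroid sits exactly at a weight-band edge can, when merged with
  added peripheral mass, drop a band faster than its area grows. The band
  discontinuity is inherent to the three-step weight function.
* Fine Movement measures global frame change; it cannot distinguish scope
  translation from irrigation turbulence or specular flicker. Frame
  differencing is the method's deliberate simplicity, not an oversight.

## Problem sizes used in validation

The shipped tests validate against brute-force oracles on 8×8–16×16 frames,
parameter recovery on twenty 96×72×30 s synthetic sessions, and group
discrimination on 8 + 8 preset sessions; the whole suite runs in well under
a minute on one core.
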
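---
title: "Evaluating facial regions for camera-based heart-rate measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating facial regions for camera-based heart-rate measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppgroi)
library(dplyr)
```

## The problem

Remote photoplethysmography (rPPG) estimates the cardiac pulse from the
subtle color modulation of facial skin in ordinary video. The choice of the
facial region of interest (ROI) whose pixels are averaged into the raw RGB
trace strongly affects accuracy, yet region definitions in the literature
are often vague ("forehead", "cheek"). `rppgroi` implements a reproducible
evaluation pipeline over 28 anatomically defined facial regions, each given
as an ordered polygon of keypoint indices in the 468-point face-mesh
convention (`roi_table()`), so that any detector emitting those landmarks
can be benchmarked region by region.

The pipeline has two phases. *Raw signal extraction*: per frame, each ROI
polygon is rasterized from that frame's landmarks (even-odd fill on pixel
centers) and the mean of each color channel over the mask forms one sample
of the ROI's RGB trace. *HR estimation*: an rPPG algorithm converts the
trace into a pulse signal, a 6th-order Butterworth bandpass (0.65–4 Hz,
zero-phase) removes out-of-band noise, and heart rate is read per sliding
window (6 s length, 5 s overlap) as 60 times the frequency of the power
spectral peak inside the band.

## The rPPG algorithms

Four classic conversion methods are implemented on the 3×N channel matrix:

* **CHROM** — chrominance combination on temporally normalized channels,
  X = 3R − 2G, Y = 1.5R + G − 1.5B, combined as X − (σ(X)/σ(Y)) Y on 1.6 s
  Hann-windowed, half-overlapping sub-windows with overlap-add.
* **POS** — projection of window-normalized channels onto the plane
  orthogonal to the skin tone, rows (0, 1, −1) and (−2, 1, 1), α-tuned by
  the ratio of the two projections' standard deviations, overlap-added with
  a one-sample stride.
* **LGI** — projection I − uu′ with u the leading left singular vector of
  the channel matrix; the pulse is the second projected component.
* **OMIT** — thin Householder QR of the channel matrix; P = I − q₁q₁′ from
  the first orthonormal column, pulse = second row of P C.

Temporal normalization divides by the within-window channel mean, which is
what makes the downstream HR estimate exactly invariant to a global gain on
the trace (a property the tests verify for all four methods). Whenever a
σ-ratio denominator falls below 10⁻¹² the ratio is set to 0 so constant
channels cannot produce NaN. All outputs are zero-mean. CHROM and POS use
their original publications' sub-windowing; LGI and OMIT operate on whole
segments. Samples flagged invalid (empty mask, off-frame face) are linearly
interpolated across gaps of at most 1 s; longer gaps split the trace into
independently processed segments, and analysis windows containing more than
20% invalid samples are dropped from metric computation.

## Spectral HR estimation

Each 6 s window is mean-detrended, Hann-tapered, and evaluated on a
zero-padded frequency grid no coarser than 0.1 BPM, implemented as a cached
band-restricted DFT operator (mathematically identical to zero-padding the
FFT and keeping the 0.65–4 Hz bins; the hot loop runs as one single-precision
matrix product in compiled code). The estimate is the grid frequency of
maximum power, ties resolved toward the lower frequency; the timestamp is
the window center. The filter is applied once to the full signal before
windowing. Estimated and reference HR series are aligned by linear
interpolation of the reference onto the estimate's timestamps; points
outside the reference span are dropped.

## Metrics and the overall score

For each ROI × method × recording the package computes

* **MAE** (BPM): mean absolute difference of the aligned HR pair;
* **PCC**: mean per-segment Pearson correlation between the bandpassed
  pulse and the reference contact PPG interpolated onto the video grid and
  identically bandpassed (segments reuse the 6 s / 5 s grid — the window
  length is a config default, `pipeline_config()$window_s`);
* **SNR** (dB): per segment, the FFT power ratio inside versus outside a
  binary mask of ±12 BPM around the reference HR and its first harmonic,
  averaged over segments. Segment SNRs are clamped to ±60 dB and the
  denominator floored at 10⁻¹² of total power so pure tones cannot produce
  ±∞. The per-segment reference is the median of the aligned reference HR
  within the segment.

Per activity, metrics are aggregated over participants by the median and
min–max normalized across ROIs into the overall score
OSₖ = ⅓[(MAEmax−MAEₖ)/(MAEmax−MAEmin) + (PCCₖ−PCCmin)/(PCCmax−PCCmin) +
(SNRₖ−SNRmin)/(SNRmax−SNRmin)] ∈ [0, 1]. If a metric is constant across
ROIs its component is set to a neutral 0.5 rather than dividing by zero.
Since the construction already yields [0, 1], no second normalization is
applied; `overall_score(..., renormalize = TRUE)` exposes an optional
per-activity min–max rescaling for users who want the full span exactly.
Summing OS over activities and sorting descending gives the ranking
(`rank_rois()`); ties break by lower aggregated MAE, then ROI index. When
several rPPG methods are evaluated the default pools them by averaging OS
across methods (`method_mode = "mean"`), recorded in the report metadata; a
per-method mode is available. A "top group" is flagged as the largest
ranking prefix separated from the rest by a summed-OS gap above 0.3 — a
reproducible, advisory formalization of what is otherwise a visual judgment
on the stacked-bar chart.

Two agreement summaries complement the ranking: the **acceptance rate**,
the fraction of consecutive non-overlapping 25 s windows whose MAE is at
most 10 BPM (the boundary counts as acceptable; a trailing partial window
is ignored), and **Bland–Altman** statistics over the same windows (bias
and ±1.96 SD limits of agreement of the window-mean differences).

## The synthetic study generator

Because real benchmark videos cannot ship with a package, `sim_config()` /
`simulate_study()` generate ground-truth-known inputs with the statistical
structure the analysis assumes: a quasi-periodic pulse
p(t) = sin φ(t) + 0.3 sin 2φ(t) with φ′ = 2π HR(t)/60 and a piecewise-linear
HR trajectory in 48–180 BPM; per-ROI pulsatile amplitudes (graded so the
glabella, foreheads, malars, and upper nasal dorsum are strongest,
reflecting regions with rich superficial perfusion); green-dominant channel
gains (0.4, 1.0, 0.6); white noise per ROI and channel; a slow illumination
drift shared by all channels; and Poisson-timed motion bursts correlated
across channels. Ground truth (contact PPG and HR) is sampled at 60 Hz —
deliberately different from the video rate so alignment is always
exercised. `render_frames()` additionally paints each ROI polygon with its
trace color on a textured background using a **synthetic** hand-built
468-point landmark template (`landmark_template()`, generated in code, not
a detector output), so the extraction phase round-trips without any model
download.

The default study uses 6 participants × 2 activities ("resting": σ = 1
intensity count, rare bursts; "talking": σ = 2.5, faster drift, frequent
bursts), 20 Hz video, and 30 s recordings. These sizes are the package's
desk-scale choice: large enough that every stage (alignment, windowing,
acceptance windows) is exercised and the amplitude grading is recoverable,
small enough that seeded replication studies run in minutes. What the
generator deliberately does *not* model: photorealistic appearance, PPG
waveform morphology, skin-tone diversity, and non-rigid facial deformation.
Passing tests therefore demonstrate the correctness and discriminative
behavior of the pipeline, not field accuracy on real video.

## Numerical choices and degenerate inputs

* Landmarks are pixel coordinates, origin at the top-left pixel corner;
  pixel (i, j) has center (j + 0.5, i + 0.5); a pixel is in a mask iff its
  center is inside the closed polygon under the even-odd rule (vertices in
  the shipped listing order; self-intersections are not repaired). The
  rasterizer is checked pixel-for-pixel against a brute-force oracle.
* Zero-area or fully off-frame polygons give empty masks, which become
  invalid trace samples, not errors.
* `bandpass_filter()` rejects sampling rates at or below 8 Hz (the 4 Hz
  cutoff would be unrepresentable) and marks valid runs shorter than
  3 × order samples invalid instead of filtering them.
* Zero-phase (forward–backward) filtering doubles the effective order;
  this is deliberate — evaluation is offline and only the spectral peak
  location is consumed.
* Welch windows with zero variance cannot occur after detrending plus the
  clamp/floor rules; PCC segments with zero variance in either signal are
  excluded and counted in the `excluded` attribute.
* All generators are pure functions of their configuration, including the
  seed; study sub-seeds are drawn once from the study seed.

## A worked run

```{r study, eval = FALSE}
study <- simulate_study(seed = 1)
records <- evaluate_study(study)
ranking <- rank_rois(records)
glance(ranking)
autoplot(ranking)
export_roi_report(ranking, "report")
```

On this seeded study the glabella ranks first and the seven
strongest-amplitude regions occupy the top seven positions, with a visible
summed-OS gap separating them — the generator's embedded structure, which
the acceptance tests require the pipeline to recover in at least 95/100 and
90/100 seeds respectively.

## Known limitations

* The 28-region table presumes the 468-point mesh convention; other
  landmark sets need an adapter.
* The ranking's absolute OS values depend on the set of ROIs evaluated
  (min–max normalization is relative), so rankings are comparable only
  within one evaluation.
* Acceptance-rate windows are non-overlapping and complete; very short
  recordings (< 25 s of aligned span) have no defined acceptance rate.
* The live face-mesh detector is out of scope; the package consumes
  precomputed landmark files (JSON lines) or in-memory matrices.
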
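---
title: "Methods: thermal response analysis for lamina I projection neuron imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal response analysis for lamina I projection neuron imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1resp)
```

This vignette is the package's own account of the models and conventions it
implements: the stimulus protocols, the ΔF/F normalisation, the responder
criterion, the threshold estimator, the synthetic-population generator, and
the numerical choices behind each. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

In vivo recordings image GCaMP6s-labelled spinoparabrachial projection
neurons in lamina I of the dorsal horn while the ipsilateral hind paw is
stimulated. The raw observable is mean pixel intensity per hand-drawn ROI
per frame, at 0.5–4 Hz (typically 4 Hz, the package default). Analysis
proceeds in the order the package modules mirror:

1. **Background subtraction.** A background ROI drawn in a cell-free region
   is subtracted frame-wise from every cell ROI. Doing this *before*
   computing F0 (the order is a package choice) makes ΔF/F independent of
   the ambient background level.
2. **Normalisation.** ΔF/F(t) = 100·(F_t − F0)/F0, in percent, with F0 the
   mean background-subtracted fluorescence over a stimulus-free baseline
   recording period. The default F0 window is the first 30 s of the
   recording; its length is a package choice (the source convention states
   only that the period precedes any stimulation), and rendering defaults to
   a 60 s lead-in so the window fits comfortably.
3. **Responder criterion.** For each stimulus, the baseline period is the
   5 s window starting 10 s before onset. With b and σ the mean and sample
   SD (n−1) of ΔF/F over that window, the cell responds iff
   max(ΔF/F − b) over the response window ≥ 70 + 4σ (percent). The
   per-stimulus re-referencing exists to keep slow drift from being scored
   as a response. We read "70% above baseline plus 4 SD" additively on the
   ΔF/F percent scale rather than multiplicatively on raw fluorescence
   (1.7·F0), because every quantity in the convention is defined on the
   ΔF/F percent scale; both constants are configurable
   (`threshold_base`, `threshold_sd_mult`).
4. **Response window.** The window runs from stimulus onset to offset plus
   `post_lag` (default 10 s). The post-stimulus allowance is a package
   choice: the source convention does not state how long after offset a
   response may be counted; 10 s covers the slow indicator's decay without
   approaching the 90 s inter-trial interval, and the window is always
   truncated before the next trial's baseline window. Ties at exactly
   threshold count as responses.
5. **Thresholds.** On the simple ramp series (fixed 32 °C baseline, graded
   end temperatures), a cell's heat threshold is the lowest end temperature
   of any responded heating trial and its cold threshold the highest
   responded cooling end temperature. Thresholds are therefore
   *grid-valued*: heat thresholds live on {34, 36, …, 50} and cold
   thresholds on {27, 22, 17, 12, 7, 4}. The estimator is refused on
   variable-baseline protocols, where end temperature no longer orders
   stimulus strength.
6. **Aggregation.** A cell "responds to" a modality iff it responded to at
   least one trial of that modality. Percent-responding uses the postmortem
   cell count as denominator (all labelled cells accumulate calcium and
   brighten after death, so the count includes cells silent throughout the
   session). Polymodality tables report conditional overlaps
   (100·|A∩B|/|A|, integer-rounded for display, full precision retained).
   Heatmaps sort cells by descending |Pearson r| between trace and
   temperature profile; constant traces are assigned |r| = 0 and sort last,
   ties break by cell id; rows are z-scored (constant rows map to zeros
   rather than NaN). SEM is computed across cells, matching how the mean ±
   SEM traces are displayed; per-animal aggregation is available through the
   `animal` column.

## Stimulus protocols

The eight thermal protocols are encoded bit-exactly as data
(`build_protocol()`), with two parameterisations the printed ranges leave
open, resolved as follows:

- **Rate-of-change ramps** (32→50 °C and 32→10 °C at 0.2/0.5/2 °C·s⁻¹):
  the end-temperature hold is chosen so total on-stimulus time is the same
  for all three speeds (equal to the slowest ramp: 90 s heat, 110 s cold),
  which is what makes faster ramps have longer stable plateaus.
- **End-temperature-stable ramps**: per-trial rates equalise ramp duration.
  The duration follows from the largest temperature step at the fastest
  printed rate — 28 °C at 7 °C·s⁻¹ (heat) and 32 °C at 8 °C·s⁻¹ (cold),
  i.e. 4 s — giving rate sets 7/5.75/4.5/3.25/2 and
  8/6.75/5.5/4.25/3/1.75 °C·s⁻¹, spanning exactly the printed 2–7 and
  1.7–8 ranges.
- The **baseline-variable heating** list is taken as printed
  (22, 27, 32, 34, 37 → 35, 40, 45, 47, 50 °C, all +13 °C), not as a
  uniform grid.
- The **simple cooling** series is 27, 22, 17, 12, 7, 4 °C — five 5 °C
  decrements and a final 3 °C step.
- Timelines are piecewise linear with exact segment durations |ΔT|/rate;
  the exact breakpoints are carried alongside the sampled trace, so corner
  temperatures are preserved regardless of the sampling grid. Between
  trials the program ramps directly to the next trial's baseline
  temperature and holds it for the inter-trial interval (90 s for
  fixed-baseline protocols, 120 s where the baseline varies).
- Brush, pinch and electrical stimulation are labelled events on a flat
  32 °C trace; their 5 s default duration and 3-repeat default count are
  package choices (the sources show durations only graphically).

## The synthetic population generator

The generator defines the study conditions for every simulation-based test;
its defaults are fixed once and are not tuning knobs.

**Modality mixture.** Category proportions are reconstructed exactly from
the published 139-cell cohort: pinch+cold 41, pinch+cold+heat 18, cold-only
20, pinch-only 8, heat-only 2, pinch+heat 5, cold+heat 6, non-responding 39.
The two free counts (pinch-only, heat-only) are pinned by the printed
identities (59 of 72 mechanosensitive cells also cold, 23 of 72 also heat,
30 unimodal of which 20 cold, 61% cold overall). Electrical sensitivity is
drawn independently (C-fibre strength 0.6, A-fibre 0.04) on top of
non-silent cells.

**Thermal tuning.** Cold thresholds ~ Normal(23, 5²) truncated to
[10, 31] °C; heat thresholds ~ Normal(44, 4²) truncated to [40, 50] °C. The
reported population summaries are read as the parameters of the latent
generative distribution — the simplest generative reading. Note its
consequence: the population mean of the *latent* cold threshold is 22.5
(truncation pulls it below 23), and the grid-valued estimator recovers the
grid *floor* of each latent threshold, so the expected recovered cold mean
is ≈ 20 °C even for a perfect detector. Symmetrically, heat recovery is the
2 °C-grid *ceiling* and lands near 45.5–46 °C against a latent mean of
44.6. The package reports these quantised recoveries as computed and does
not correct them back; the bias is a property of the scan design, not a
defect of the detector, and closing it would require either a sub-grid
estimator (out of scope) or reading the reported summaries as summaries of
grid values rather than distribution parameters.

**Drive model.** Per-cell activity ("drive", in steady-state ΔF/F percent):

- Cold: `gain · max(0, θ_cold − T(t)) · s(t)`, with adaptation state `s`
  resetting to 1 while temperature falls, decaying as exp(−t/τ_adapt)
  while temperature is stable (|dT/dt| < 0.05 °C·s⁻¹), and holding while
  temperature rises. This reproduces the three signature behaviours:
  end-temperature coding, decline during stable cold, and
  baseline-invariance of peak responses on end-temperature-stable cooling
  ramps (the drive always restarts from a near-zero adapted state).
- Heat: `gain · max(0, T(t) − θ_heat) · m`, with no adaptation, and a
  priming multiplier m determined by the trial's baseline (adaptation)
  temperature: m = 0 for baselines below 32 °C (responses abolished even
  for 50 °C stimuli), m = 1 + κ·(baseline − 32) otherwise (warmer baselines
  prime). Trial context switches halfway through each inter-trial baseline
  hold, so a trial's return ramp stays under its own baseline's multiplier.
- Events: a constant `event_gain` during pinch/electrical events the cell
  is sensitive to; brush drives nothing.

**Defaults with units.** `gain` = 100 %ΔF/F per °C; `tau_adapt` = 10 s;
`priming_coef` κ = 0.05 per °C; `event_gain` = 150 %ΔF/F. The gain is
deliberately high: it makes sub-degree threshold exceedances clear the 70%
criterion, so ramp-grid threshold recovery reflects the cell's tuning
rather than the gain. The cost is that simulated amplitudes at extreme
temperatures (e.g. ~1900% ΔF/F for a 23 °C-threshold cell at 4 °C) exceed
typically displayed in vivo amplitudes; threshold fidelity was prioritised
because the recovery analyses are threshold-centric. The adaptation
constant (10 s) gives near-complete decay (e⁻⁶) over a 60 s hold.

**Indicator and noise.** Fluorescence is
`F(t) = background + f_rest·(1 + α·(k ⋆ drive)(t)) + noise`, where k is a
difference-of-exponentials kernel (rise 0.2 s, decay 1.8 s —
literature-typical slow-indicator kinetics; the sources do not parameterise
them) normalised to unit peak. With `alpha = "auto"` (default) the scale is
1/(100·∫k dt), so a sustained drive of x maps to a steady-state ΔF/F of
exactly x percent — the drive is calibrated in observable units. Noise is
additive Gaussian (default SD 1.5 a.u. per sample on f_rest = 100, i.e.
1.5% ΔF/F — the "low noise" regime), with optional sinusoidal drift;
background defaults to 20 a.u. One seed controls the whole draw.

**Rendered images.** `render_dataset()` draws cells as Gaussian blobs whose
ROI-mean equals the trace value exactly (blob weights are normalised to
mean 1 over the ROI), on top of the uniform background trace, with a label
mask (one label per cell plus one background label) and a postmortem frame
in which *all* cells — including silent ones — are bright. Extraction
therefore round-trips the generator traces exactly at zero pixel noise,
which is the invariant the tests assert.

**What the generator does not emulate.** Motion and drift artifacts (data
are generated registered; drift correction was external software in the
source workflow), shot-noise scaling with intensity, overlapping or
irregular ROIs, receptive-field geometry, spike-level biophysics, and
inter-animal variability (a run is one "animal" unless the caller groups
cells). Passing tests on synthetic data therefore validate the analysis
logic — windowing, criterion arithmetic, threshold scans, aggregation — not
robustness to real-world imaging artifacts.

## Numerical choices and degenerate inputs

- Truncated normals are sampled by inverse-CDF, so populations are
  reproducible sample-by-sample for a given seed, and seeded draws
  save/restore the caller's RNG state.
- Convolution is causal and multiplied by dt, making results
  sampling-rate-stable.
- ΔF/F refuses F0 ≤ 0 naming the offending cell; background-subtracted
  negatives are preserved (and counted in a message), not clipped.
- Detection requires ≥3 baseline samples per window and errors on windows
  outside the recording; `t_cross` is NA for non-responders.
- Constant traces: |r| = 0 (ranked last, ties by cell id), z-scores of 0.
- Empty protocols render a flat baseline trace; zero-cell populations are
  legal and empty.

## Problem sizes

The test suite simulates up to 500 cells over three protocols (the
end-to-end classification check) and 220 cells per modality for threshold
recovery; the acceptance script uses 250 cells per modality at 4 Hz. These
sizes give binomial/SE margins comfortably inside the asserted tolerances
while keeping a full run in the order of minutes on one CPU.

## Known limitations

- Thermal-threshold recovery is grid-quantised, with the floor/ceiling bias
  quantified above; recovered cold means sit ≈ 3 °C below the latent mean
  under the default distribution and 5 °C cooling grid.
- The heat priming multiplier applies per trial context, not as a
  continuous function of thermal history; sub-32 °C abolition is a hard
  zero.
- The responder criterion is threshold-based; no spike inference or
  deconvolution is attempted, so response *amplitude* comparisons across
  cells inherit indicator nonlinearities that the generator does not model.
- Statistical comparisons between conditions (e.g. repeated-series effects)
  are out of scope; the package reports descriptive summaries only.
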
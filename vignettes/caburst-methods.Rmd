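---
title: "Methods: calcium-event detection, burst segmentation, and pharmacological statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-event detection, burst segmentation, and pharmacological statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caburst)
```

`caburst` quantifies in vivo frontal-cortex activity along two
complementary arms — somatic calcium imaging and single-unit
electrophysiology — and asks, for each, whether a systemically injected
drug changes activity relative to the pre-injection baseline, in control
versus disease-model animals. This vignette documents the models,
estimators, and the design decisions behind them.

## The imaging model

A soma's fluorescence is treated as

$$F(t) = F_{bg}(t) + F_{cell}(t), \qquad
  \Delta F/F(t) = \frac{(F(t) - F_{bg}(t)) - F_0}{F_0},$$

where $F_{bg}$ is a background estimate (a designated background region,
or the per-frame 10th-percentile pixel when none is supplied) and $F_0$
is the baseline fluorescence. $F_0$ is estimated as the *mean of the
lowest 10% of background-subtracted frames within the baseline window*
(`min_fraction = 0.1`, configurable). A single minimum frame would be
noise-dominated; averaging a low tail keeps the estimator stable while
still tracking the quiet floor of the recording.

### Event detection and the threshold

Calcium events are maximal contiguous runs of frames whose
$\Delta F/F$ exceeds a noise-scaled threshold. The classical phrasing —
"signal exceeds three standard deviations" — leaves two quantities
implicit: which SD, and measured from where. Our choices:

- **The SD is of baseline $\Delta F/F$**, not raw fluorescence, so the
  threshold is scale-free and the event set is invariant to detector
  gain.
- **The threshold is measured from the baseline level**, i.e.
  `noise_mean + k_sd * noise_sd` with `k_sd = 3` by default. Because
  $F_0$ is taken from the low tail of the baseline distribution, baseline
  $\Delta F/F$ has a small positive offset (about 1.8 noise SDs for
  Gaussian noise at the default 10% tail). A threshold measured from zero
  would sit *below* much of the noise band and flood the detector with
  false positives; centering on the baseline level reduces exactly to the
  textbook rule when $F_0$ equals the baseline mean.

The baseline noise statistics (`noise_mean`, `noise_sd`) are estimated
robustly: starting from the median and MAD of baseline frames, frames
more than 3 scale units above the centre are excluded as likely events
and the mean/SD re-estimated, iterating until the kept set is stable. A
single exclusion pass was tried first and stalls at a contaminated fixed
point once transients occupy more than roughly a fifth of the baseline
window; the MAD seed makes the iteration converge from above regardless
of contamination at realistic event rates.

Per event we report onset, offset (first/last supra-threshold frame),
peak time, amplitude (maximum $\Delta F/F$ in the run) and area (the
trapezoidal integral of $\Delta F/F$ over the run; a single-frame run
contributes `dff * frame_interval`). Runs cannot merge across even one
sub-threshold frame — contiguity is the definition.

Degenerate inputs: a noise SD of zero is accepted only when the baseline
segment is genuinely constant (clean synthetic traces); a zero SD with a
non-constant baseline raises an error, as does a non-positive $F_0$ or a
baseline shorter than 10 frames.

### Activity metrics

Windows of `window_s = 60` s tile the recording from its first frame; a
partial terminal window is dropped. Events are assigned to windows by
onset time (half-open intervals), and a boundary-straddling event's area
counts wholly in its onset window — the simplest convention, and an
explicitly documented one. Three metrics per window: mean event
amplitude, event frequency (events/min), and total activity (summed
event area per minute). *Total activity integrates detected events
rather than the whole trace*; the whole-trace reading is arguably also
defensible, but the event-sum keeps the metric insensitive to slow
drift, and the two coincide as the threshold goes to zero.
Normalisation reports each metric as $100 \times$ post-mean /
baseline-mean; a zero baseline flags the metric as undefined rather than
raising.

Sampling is assumed uniform at `frame_interval = 1.109` s (approximately
0.9 Hz); per-minute scaling uses the exact interval, never the rounded
rate.

## The spike-train model

### Burst segmentation

Three rules define a burst: all intra-burst inter-spike intervals are
**strictly below 15 ms**; a burst holds **at least 3 spikes** ("larger
than 2" read literally — `min_spikes` is configurable for users who
prefer the ≥2 convention common elsewhere); and bursts are **separated
by more than 100 ms**. The detector chains maximal runs of sub-15-ms
ISIs, drops runs below the count rule, and then *merges* kept runs whose
end-to-start gap is ≤ 100 ms, counting every spike inside the merged
window. Merging (rather than deleting one of the close runs) preserves
spikes and guarantees the output itself satisfies the separation rule.
The suite verifies the detector against a brute-force oracle that tests
every contiguous spike subsequence, over 10^4 random spike sets with
ISIs placed at and around both boundaries.

### Rates, classes, responses

Per half-open analysis window: mean rate (all spikes), single-spike rate
(spikes outside every burst interval), burst rate (burst starts per
second) and burst-spike rate (in-burst spikes per second). Single and
in-burst spikes partition the total in every window — a conservation
property the suite asserts on generated trains. Where a "burst spike
rate" is called for downstream, the default reading is bursts/s
(`burst_rate_kind = "bursts_per_s"`), with in-burst spikes/s exposed as
the alternative.

Units are fast-spiking when the baseline mean rate strictly exceeds
10 spikes/s (a 10.0 Hz unit is regular-spiking), the conventional
putative-interneuron cutoff at these recording sites.

The relative spike rate is $SR = 100 \times$ post/pre. Response classes:
decrease at $SR \le 80$, increase at $SR \ge 120$, no change on the open
interval between. The two boundaries belong to the outer classes — "
reduced by 20% or more" and "increase by 20% or over" both include their
boundary, so the overlap at exactly 80 and 120 is resolved outward and
the bounds are configurable. A zero pre-injection rate makes SR
undefined; such units are flagged and excluded from normalised
summaries instead of erroring.

The ephys pipeline uses a 10-min baseline before injection, consecutive
30-min post-injection bins (the 30/60/90-min reporting grid), and
evaluates the burst-rate response class over the 30–60 min post-injection
window.

## Group statistics

The unpaired t-test defaults to the pooled-variance Student form (the
convention of the era's analysis software; Welch via `var_equal =
FALSE`). Degenerate zero-variance inputs are resolved explicitly: zero
mean difference gives $t = 0, p = 1$; a non-zero constant difference
gives an infinite statistic with $p = 0$.

The two-way ANOVA fits `values ~ group * treatment` and reports
$F_{df_1, df_2}$ for both main effects and the interaction. Post-tests
are pairwise group contrasts within each treatment level using the
pooled residual mean square, Bonferroni-corrected across all contrasts
(adjusted $p$ = raw $p \times$ number of contrasts, capped at 1) — the
contrast set matching the "basal" and "with drug" comparisons reported
in this literature. An essentially-constant response (SD below
$10^{-10}$ of scale) reports $F = 0, p = 1$ for every effect rather than
0/0. Gaussianity is assumed throughout; no normality gate is applied.
The experimental unit is the soma/unit; animal-level aggregation is left
to the caller, with the usual pseudo-replication caveat.

Time courses summarise per-unit SR into group mean ± SEM per bin with
the baseline pinned at exactly 100%. Stars follow the standard
thresholds (\*, \*\*, \*\*\* at $p$ < 0.05, 0.01, 0.001).

The suite checks empirical type-I error of both tests on 2000 null
replicates (n = 30 per group) against a [3.5%, 6.5%] band at the nominal
5%, and checks the t and F statistics against hand-computed formulas to
1e-8.

## The synthetic-data generator

`sim_profile()` describes one condition: homogeneous-Poisson single
spikes superposed with Poisson-occurring bursts whose sizes are drawn as
$3 + \mathrm{Poisson}(\mu - 3)$ — so every generated burst satisfies the
count rule — at a fixed intra-burst ISI below 15 ms. After an injection
time, both process rates are scaled by the profile's drug factors,
optionally per unit class (fast vs regular). Two structural guards make
ground truth exact: generated bursts are separated by more than 110 ms,
and single spikes within 16 ms of a burst window are dropped, so the
three-rule detector recovers the generated windows by construction (the
rate lost to the keep-out margin is negligible at the rates used).

**Chance bursts are real.** At an 8 Hz single-spike rate, roughly one in
nine ISIs falls below 15 ms by chance, and runs of two such ISIs produce
genuine bursts (about 0.09/s) that are *correctly* detected yet absent
from the generated ground truth. Burst-recovery properties are therefore
tested on sparse-singles profiles (2 Hz, 3600 s), where coincidences are
negligible; at control rates the same coincidences are an expected
feature of Poisson trains, not a detector failure.

Condition parameterisation (fixed once, as the study conditions):

- **Ephys arm** — control mean rate 8 Hz vs model 20 Hz (burst processes
  identical at 0.1/s, so the contrast is carried by single spikes);
  drug condition with bidirectional modulation (single-spike rate × 0.6
  in fast-spiking units, × 1.26 in regular-spiking units; burst
  generation × 0.5); null-drug conditions with unit factors. Per-unit
  rates are lognormal with CV 0.25 (0.6 in the mixed-class drug
  conditions, so both unit classes are populated); the source studies
  report only mean ± SEM, so the across-unit CV is a free parameter set
  once at a realistic cortical value.
- **Imaging arm** — sparse events dominated by bursts at 2.06/min
  (control) vs 2.55/min (model), transient amplitude 1.55 ΔF/F at
  control (1.78 at model via the kernel), single spikes contributing
  only sub-threshold fluorescence (0.02 ΔF/F against a 0.03 threshold) —
  reflecting that slow indicators report bursts far more strongly than
  isolated spikes. Dense spiking at ephys rates would saturate a slow
  indicator into an unresolvable plateau, which is why the two arms use
  different profile sets.

Fluorescence is forward-modelled as baseline × (1 + Σ transients) +
drift + white noise: each event contributes a double-exponential kernel
(rise 0.2 s, decay 1.5 s, peak-normalised) scaled by its amplitude;
drift is a slow sinusoid (default period 300 s, random phase) that
stresses $F_0$ estimation without mimicking events; drug suppression of
transient amplitude is applied at this stage (`amp_scale_post`). Movies
render each soma as a Gaussian blob (σ = radius/2) scaled by its trace
over a constant background with pixel noise — a linear model, so ROI
means recover the generating traces exactly at zero noise.

What the generator does *not* emulate: motion artifacts, neuropil
contamination, indicator nonlinearity and saturation, electrode drift,
non-Poisson spike-train structure (refractoriness, oscillatory
coupling), and correlated noise across ROIs. Passing tests demonstrate
correctness of the estimators under the stated forward model, not
robustness to these real-data complications.

### Calibration and problem sizes

Detector calibration uses 100 traces of 600 s at the study's spontaneous
event frequency (~2/min), with transient peaks drawn uniformly between 5
and 20 baseline-noise SDs — the 5-SD floor is the hard case the
calibration targets; observed transients in this preparation are far
larger. Recall and precision are matched by onset within ±2 frames.
Population recovery uses 80 units × 600 s per condition; the null-drug
arm uses 48 units × 100 min (10 baseline + 90 post). Statistical
validity uses 2000 null replicates. These sizes give the sampling error
needed by each check at desk-scale runtimes.

## Reproducibility

Every generator and pipeline is deterministic given (inputs, config,
seed): per-unit seeds derive from the master seed, manifest paths are
relative so bundles are byte-identical across directories, and each
output table carries a provenance header with the package version, seed,
and a hash of the analysis parameters (file locations deliberately
excluded from the hash). Times are seconds; analysis intervals are
half-open `[start, end)`.

## Known limitations

- Event areas integrate only supra-threshold frames, slightly
  undercounting transient tails; at 0.9 Hz sampling a transient's rising
  frame can land below threshold, delaying detected onsets by a frame.
- A transient whose plateau rides near threshold can split into two
  detected events (contiguity is strict); at the 5-SD floor this costs a
  few percent precision, disappearing for larger events.
- The Bonferroni post-test set is fixed to group contrasts within
  treatment levels; other contrast families require the caller to adjust
  manually.
- The burst detector reports windows and counts only; within-burst
  structure (ISI trends, spike amplitudes) is out of scope, as is spike
  sorting itself — the pipeline starts from sorted spike times.
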
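---
title: "Detecting a dentate gyrus novelty signal and its CA3 consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a dentate gyrus novelty signal and its CA3 consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnovelty)
```

## The scientific problem

Dentate gyrus granule cells respond to an abrupt switch into a novel
environment ("teleportation" in virtual-reality navigation) with a small,
transient membrane-potential depolarisation: about 1 mV when averaged over
the first second, decaying within roughly 2 s, with no accompanying change in
membrane-potential variance. Because granule cells are extremely sparsely
active, even a ~1 mV population-wide depolarisation can recruit a sizeable
*relative* number of additional spiking neurons. Downstream, a transient
increase of dentate gyrus output can act as a switch for the CA3
auto-associative network: feed-forward inhibition erases the attractor state
representing the familiar map, and direct excitation ignites a weak,
not-yet-consolidated novel map.

`dgnovelty` implements this analysis chain end to end on synthetic data:

1. a generator of in-vivo-like granule-cell membrane-potential recordings
   with lap/teleportation session structure,
2. the trace-analysis pipeline (filtering, spike removal,
   teleportation-aligned averaging, nonparametric statistics, behavioural
   hit rate),
3. a bootstrap estimator of the change in the fraction of spiking granule
   cells caused by the transient,
4. a binary-unit continuous-attractor model of CA3 with clipped Hebbian
   couplings, mEC and dentate gyrus inputs, global inhibition, and a
   BCM-like plasticity rule.

## The synthetic membrane-potential generator

A synthetic cell is `baseline + noise + transients (+ spikes)`:

* **Baseline.** One value per cell from a skew-normal distribution with
  population mean −73 mV and s.d. 9 mV. The shape parameter (default 4) is
  the skew-normal *shape*, not the moment skewness: the skew-normal family
  cannot reach a moment skewness of 4, and the published in-vivo range
  (~−90 to ~−50 mV for 26 cells) is reproduced by shape 4 after the
  analytic location/scale correction that makes the first two moments exact
  (`sample_baseline_vm()`).
* **Noise.** A mean-reverting (Ornstein-Uhlenbeck) process, stationary s.d.
  2 mV, correlation time 50 ms. The true subthreshold noise spectrum of
  granule cells in vivo is not published; these values give
  realistic-looking subthreshold variance and are exposed in
  `vm_generator_spec()`.
* **Transient.** A single-exponential depolarisation added at every
  teleportation of a selected type. The peak is scaled so that the
  *discrete* mean over the first second equals `novelty_amplitude`
  (default 1.02 mV), which makes the amplitude-calibration identity exact at
  any sampling rate; the default decay constant 0.8 s leaves under 10% of
  the peak after 2 s. The transient is a deterministic additive waveform, so
  it changes window means but adds only ~0.13 mV&sup2; of within-window
  variance — under 5% of the noise variance, matching the observation that
  the depolarisation is not accompanied by a variance change.
* **Spikes.** Brief (2 ms) triangular depolarisations at Poisson times,
  present only to exercise spike removal; granule cells are modelled as
  nearly silent (default 0.02 Hz).

Sessions alternate familiar (F) and novel (N) laps; the default lap pattern
F,F,N,N,... produces all four teleportation types (FF, FN, NN, NF). One
master seed spawns an independent stream per cell
(`generate_recording_set()`), so multi-cell datasets are exactly
reproducible.

What the generator deliberately does **not** model: position-locked
subthreshold dynamics (place fields), theta-band structure, movement
artefacts, electrode drift beyond a linear trend, or any pharmacology — the
"no-novelty-signal" (atropine-like) condition is simply
`inject_novelty_on = character(0)`. Passing the recovery tests therefore
shows that the *pipeline* is unbiased and calibrated on data satisfying its
assumptions, not that real recordings satisfy them.

## The trace-analysis pipeline

* **Filtering** (`preprocess_trace()`): zero-phase 4th-order Butterworth
  low-pass (applied forward and backward), linear-interpolation resampling,
  and slow-trend removal. The trend slower than `highpass` is estimated with
  a centred running mean over `1/highpass` seconds; when that window exceeds
  the trace (always the case at the conventional 1e-5 Hz cutoff) the trend
  reduces to the best-fitting straight line. The trend's own mean is added
  back, so absolute membrane-potential levels survive detrending.
* **Spike removal** (`remove_spikes()`): threshold detection (default
  −20 mV, configurable; only "thresholding" is specified in the source
  protocol), then replacement of 2 ms before to 10–20 ms after each peak by
  a straight line between the boundary samples. Overlapping excision spans
  are merged before interpolation, so bursts become a single segment.
* **ΔVm** (`compute_delta_vm()`): per event, the mean over (0, 1 s] after
  the teleportation minus a baseline. The baseline window is not specified
  beyond "during 1 s after the teleportation"; we use the symmetric choice —
  the mean over the 1 s immediately before the event — which makes FF ΔVm
  zero by construction on stationary traces. ΔVariance is the same
  difference applied to windowed variances. Events whose windows leave the
  trace are skipped with a warning.
* **Aligned averages** (`teleportation_aligned_average()`): per-event
  baseline-subtracted windows, averaged across events, with an optional
  10 Hz zero-phase smoothing for display (the display cutoff used for the
  published averages is unstated; ours is configurable).
* **Statistics** (`run_stat()`): two-sided Wilcoxon signed-rank for paired
  data, Mann-Whitney U for unpaired data, Friedman for multiple dependent
  samples, with Bonferroni correction `min(1, p * m)`.
* **Hit rate** (`hit_rate()`): the reward zone occupies the third quarter of
  the 120-cm corridor (entry at 60 cm; the precise anticipation-zone
  geometry behind the published hit rate is not specified). A hit is at
  least one lick in the quarter of the corridor preceding reward-zone entry
  ([30, 60) cm), before the lap's reward. This operational definition is a
  documented stand-in.

The pipeline's calibration is checked by simulation: the ΔVm estimator is
unbiased over hundreds of replicate datasets, and under the null (no
injected transient) the FN-vs-FF signed-rank test rejects at its nominal 5%
rate.

## The population bootstrap

`bootstrap_spiking_fraction()` follows the published procedure: silent-cell
traces are shifted so that their first-second mean matches each of `n`
baseline values drawn from the skewed in-vivo distribution; the observed
depolarisation waveform is added starting at every sampling point (on a
configurable stride); and a spike is scored if any sample in the following
1 s exceeds the cell's action-potential threshold, with and without the
waveform. The two spiking fractions are averages of these indicators over
(trace, baseline, sampling point).

The action-potential threshold that anchors this estimate comes from an
in-vivo dataset whose numeric value is not published; the package uses a
Gaussian stand-in, mean −45 mV, s.d. 3 mV per cell, clearly labelled
synthetic. In consequence the published "~30%" population effect is
reproducible only qualitatively (tens of percent at default settings); the
package instead proves *exactness* (the vectorised evaluation equals a naive
triple loop bit for bit), monotonicity in waveform amplitude, and the
sparsity-amplification property (the farther the baseline distribution sits
from threshold, the smaller the spiking fraction and the larger the relative
increase).

The default sampling-point stride is 10 ms; exactness against the
every-sample evaluation is established on short traces, and all reported
fractions are averages, which the stride subsamples without bias.

## The CA3 network model

`ca3_config()` holds the published parameter set: n = 20,000 binary units;
place fields for 20% of units per map, centred uniformly on p = 400 track
points (0.3 cm apart, 120 cm track; field diameter 33 points = 9.9 cm);
activity patterns of 330 units per position (sparsity a = 0.0165); clipped
Hebbian couplings `J_F = min(1, sum_mu xi xi)`; a pre-map N that is either a
Beta(0.7, 1.2)-shrunk Hebbian map on a second place-cell assembly
(prewired) or unit-strength couplings with round(Normal(20, 3)) in-degree on
an assembly disjoint from F (random); a connectivity mask with exactly 1200
inputs per unit; stochastic synchronous updates through
`L(h) = atan((h - G)/T)/pi + 1/2` with G = 2.31, T = 0.1; global inhibition
`g_i * max(S_min, S)` with g_F = 0.035, g_N = 0.015, S_min = 50; mEC cues
(strength 3 toward F in F, otherwise 2; decay constant 100 steps) targeting
a random half of the current position's pattern at every position update
(one update per 5 steps); DG baseline input (2% of units, strength 2, decay
30); a teleportation-triggered DG burst (14 re-draws, 15 cues total) toward
the novel assembly; and one-shot feed-forward inhibition
`0.016 * N_inter` with Poisson(125) interneuron counts (decay 3).

Conventions the source leaves open, fixed here:

* **Update scheme**: synchronous parallel draws, matching the discrete cue
  schedule. **Self-connections**: excluded from the connectivity mask.
* **Track coordinates**: integer positions 1..p on a linear, non-wrapping
  track; fields are truncated at the ends.
* **Pattern deficits**: with the published densities the *expected*
  candidate pool per position equals the pattern size, so some positions
  lack 330 overlapping units. `generate_patterns()` by default tops up a
  deficit with the nearest-centre units outside the field window
  (deterministic given the seed); strict resampling and hard rejection are
  available.
* **Inhibition of units in both maps / neither map**: g_F. The quiescent
  balance g_F·S_min = 1.75 against the DG baseline strength 2 then holds for
  every unit outside the novel-only assembly.
* **Cue re-draws** resample their random target sets; the two maps' mEC
  target sets are drawn independently.

Construction is verified against brute-force loops at small n, and exact
count invariants (pattern weight, row degree, clipping, in-degree laws) at
scale.

## Calibrating the teleportation experiment

The published parameter set, reconstructed as above, does not produce the
described teleportation phenomenology, and the package is explicit about
this. Two quantitative obstacles appear:

* **The familiar bump is too deep for the pulse.** A settled F bump has
  ~400-500 active units; its core units receive a recurrent drive of ~25
  against global inhibition ~18, leaving persistence margins of ~4-14 above
  threshold. The feed-forward inhibition pulse has amplitude
  0.016 × 125 = 2 and decays with τ = 3 steps: it removes the weakest
  quarter of the bump for a few steps, after which the bump recovers. An
  erasure - the described outcome - requires roughly twice the printed
  amplitude.
* **The novelty burst is too sparse to ignite the novel map.** The burst
  targets 2% of the novel assembly (80 of 4000 units); its coincidence with
  the position-specific mEC cue - the only combination that exceeds
  threshold from quiescence - covers ~3 units. No coherent novel-map
  population can nucleate from that seed, with any pulse.

`fig5_ca3_config()` therefore carries the package's calibration of the
switch-governing parameters, chosen once, validated, and then frozen:
`g_N = 0.01` and `A_dg_excit = 3` (the values the model itself adopts for
its weakly coupled random-connectivity variant), a burst targeting fraction
of 0.5, and a ~15% stronger inhibition coefficient. Everything else -
thresholds, mEC strengths, timescales, coupling statistics, counts - stays
at the published values. Under this preset the three experimental contrasts
emerge at full scale: the full model erases the F bump and ignites a weak
(~40-unit), mEC-anchored novel map that tracks position (median decoding
error ~11 cm) and persists; without the burst the familiar remnant recovers
in part of the runs and no novel map forms; without the pulse the familiar
bump survives the teleportation into the novel environment and the novel
map cannot ignite against its inhibition. Outcomes are stochastic across
seeds, as expected for a noise-driven race between a recovering familiar
remnant and an igniting novel population (at full scale the unpulsed
familiar bump can still fall at a *later* lap boundary, where the position
reset itself destabilises it).

The reduced-scale preset (`scale = 0.1`: n = 2000, p = 100, pattern size 33,
S_min = 5) keeps per-unit drive ratios by holding `inputs_per_unit` at its
published value (denser mask), scaling the global-inhibition coefficients
inversely with scale, and preserving the mean interneuron count. Margins are
relatively tighter at small n, so the reduced preset needs a stronger pulse
(`inhib_coeff = 0.096`) and firmer novel-map inhibition (`g_N = 0.12`); both
were fixed by validating the same three contrasts against the full-scale
behaviour before any automated test used them. One reduced-scale limitation
is documented rather than hidden: after an erasure without the burst the
small network parks in the quiescent state instead of re-igniting the
familiar map (re-ignition is a nucleation event that needs full-scale unit
counts), so the "familiar bump returns" aspect of the no-burst ablation is a
full-scale-only observation; the contrast tests assert the switch-rate
ordering, which is clean at both scales.

The simulation tests use 1 familiar + 2 novel laps (2500 steps) per run at
the reduced scale, 25 seeds per condition.

## Plasticity

`plasticity_step()` implements the bounded Hebbian update with a BCM-like
sliding threshold literally: couplings move by
`eta * C * sigma_post %o% sigma_pre`, clipped to [0, 1];
`sigma_pre = s - mean(s over the last 22 steps)`;
`sigma_post = (h_BCM/Phi) * (h_BCM - Phi)` with `h_BCM = L(h_RC)` and
`Phi = (c/400) * sum of the last 401 squared drives` (the sum as written
runs over τ + 1 terms and is normalised by τ; a constant drive h gives
`Phi = c h^2 (τ+1)/τ`). Defaults: η = 0.1, τ_learn = 22, τ_BCM = 400,
c = 9.5, applied every 2 steps while the virtual rodent is in the novel
environment.

Numerical choices: ring buffers are zero-initialised and coupling updates
are permitted only once τ_learn steps of history exist; `sigma_post` is
defined as 0 where Phi < 1e-12 (the limit of the product form as activity
vanishes). During simulations the plastic entries are restricted to the
pairs within the map assemblies (the novel assembly only, in the random
scenario): couplings outside the assemblies start at zero, receive no
pattern support, and cannot contribute to either attractor, while tracking
them densely would cost O(n&sup2;) memory.

In the random-connectivity consolidation experiment, learning reliably
stabilises the novel representation across laps (the summed novel-assembly
coupling weight rises during consolidation, and late-lap novel-map activity
is far higher with learning than without, where the assembly decays to a
trickle). The rule as published has no weight normalisation other than
clipping, so consolidation ultimately drives the co-active assembly toward
saturated couplings; containing that growth would require the co-regulation
of inhibition that the model motivates but does not implement, and is out of
scope here. The consolidation tests therefore assert the learning/no-learning
contrast on intermediate laps rather than any long-run equilibrium.

## Problem sizes used by the automated checks

Synthetic-recording checks use 9 cells × 64 laps at 500 Hz for amplitude
recovery, 50 replicate datasets of 9 cells × 16 laps at 250 Hz for detection
rates, and 400-500 replicates of smaller sessions for null calibration and
unbiasedness. Network checks run brute-force comparisons at n = 50-100,
count invariants at full scale, and the teleportation contrasts at the
reduced scale with 25 seeds per condition. These sizes are the package's
choices, balancing statistical resolution of each assertion against
simulation cost.

## Known limitations

* The generator's noise model is a single-timescale OU process; real
  granule-cell subthreshold dynamics are richer.
* The action-potential threshold model of the bootstrap is synthetic; the
  population effect is anchored only qualitatively.
* The teleportation experiment runs on a calibrated preset because the
  published parameter set does not reproduce the described switch in this
  reconstruction; all deviations are listed above and in
  `?fig5_ca3_config`.
* Consolidation under the unmodified plasticity rule saturates the novel
  assembly's couplings; inhibitory co-plasticity is not modelled.
* The atropine condition is represented only as absence of the injected
  transient (with whatever baseline shift the user chooses), not as a
  pharmacological model.
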
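# dgnovelty

Hippocampal novelty signals, from membrane potential to network dynamics.

Dentate gyrus granule cells respond to an abrupt transition into a novel
environment with a small, transient membrane-potential depolarisation
(~1 mV averaged over the first second, decaying within ~2 s). `dgnovelty`
provides a complete, synthetic-data-driven reconstruction of the analysis
chain around that observation:

* **Synthetic recordings** — granule-cell membrane potential with a
  skew-normal baseline distribution (−73 ± 9 mV, shape 4), mean-reverting
  subthreshold noise, stereotyped spikes, lap/teleportation session
  structure (FF/FN/NN/NF transitions on a 120-cm virtual corridor), and a
  teleportation-locked exponential transient whose 1-s mean equals a chosen
  amplitude.
* **Trace analysis** — zero-phase filtering and slow-trend removal, spike
  excision by linear interpolation, teleportation-aligned averaging,
  per-event ΔVm and Δvariance in the 1-s convention, behavioural hit rate,
  and the standard nonparametric tests (Wilcoxon signed-rank,
  Mann–Whitney U, Friedman) with Bonferroni correction.
* **Population bootstrap** — the estimator of how a ~1 mV depolarising
  waveform changes the fraction of spiking granule cells: silent-cell
  traces are shifted over a skewed baseline distribution and
  threshold-crossing indicators are evaluated at every sampling point with
  and without the waveform.
* **CA3 attractor model** — 20,000 binary units, place-field activity
  patterns (sparsity 0.0165), clipped Hebbian couplings
  `J_ij = min(1, Σ_μ ξ_i^μ ξ_j^μ)` for the familiar map, a weak prewired or
  random pre-map for the novel environment, random connectivity (1200
  inputs/unit), stochastic updates through
  `L(h) = atan((h − G)/T)/π + 1/2` (G = 2.31, T = 0.1), spatially selective
  mEC cues, three dentate gyrus input streams (baseline, novelty burst,
  feed-forward inhibition), global inhibition `g_i · max(S_min, Σ s_j)`, and
  a BCM-like bounded Hebbian learning rule
  (`σ_post = (h_BCM/Φ)(h_BCM − Φ)`, sliding threshold
  `Φ = (c/τ) Σ h_BCM²`).
* **Teleportation experiments** — the full-model/no-burst/no-inhibition
  contrasts with population decoding (mean place-field centre of active
  units), bump metrics, and map-switch scoring.

## Worked example

Generate nine synthetic cells with the default 1.02 mV novelty transient on
familiar-to-novel (FN) teleportations, run the analysis pipeline, and test
FN against within-familiar (FF) teleportations:

```r
library(dgnovelty)

spec <- vm_generator_spec(sampling_rate = 500)
recs <- generate_recording_set(9, spec, n_laps = 64,
                               inject_novelty_on = "FN", seed = 1)
fn <- delta_vm_by_cell(recs, "FN")
ff <- delta_vm_by_cell(recs, "FF")
c(FN = mean(fn$delta_vm), FF = mean(ff$delta_vm))
#>         FN         FF
#>  1.0187993 -0.1358893
run_stat("wilcoxon_signed_rank", fn$delta_vm, ff$delta_vm)
#> wilcoxon_signed_rank: statistic = 45, p = 0.00391 (n = 9)
```

The pipeline recovers the injected ~1 mV FN depolarisation, reports FF ΔVm
at zero, and the paired signed-rank test detects the difference across the
nine cells.

The population bootstrap, on four silent cells and the default skewed
baseline distribution:

```r
traces <- lapply(1:4, function(k) {
  tl <- generate_session_timeline(2, c("F", "F"),
                                  lap_duration_stats = c(4, 0), seed = k)
  generate_vm_trace(vm_generator_spec(spike_rate = 0, sampling_rate = 200,
                                      seed = k),
                    tl, inject_novelty_on = character(0))
})
w <- novelty_waveform(amplitude = 1.02, decay = 0.8, sampling_rate = 200)
bootstrap_spiking_fraction(traces, w, bootstrap_config(seed = 1))
#> Spiking-fraction bootstrap (4 traces x 1000 baselines)
#>   fraction spiking: 0.0289 without vs 0.0348 with the novelty signal
#>   relative increase: 20.5%
```

A ~1 mV / 1-s waveform recruits a small absolute but large relative
number of additional spiking cells — the sparsity amplification at the heart
of the population estimate. (The action-potential threshold model is a
documented synthetic stand-in, so the relative increase is anchored only
qualitatively.)

The CA3 teleportation experiment at reduced scale (n = 2000):

```r
cfg <- fig5_ca3_config(scale = 0.1, seed = 1)
net <- build_ca3_network(cfg)
sim <- run_protocol(net, ca3_protocol(
  phases = list(list(env = "F", laps = 1), list(env = "N", laps = 2)),
  seed = 81))
bump_metrics(sim, floor = 10)
#>   phase env laps persistence_F persistence_N track_err_F_cm track_err_N_cm
#> 1     1   F    1         1.000         0.000       48.20952             NA
#> 2     2   N    2         0.001         0.229       10.16842       4.986667
#>   dominant_map
#> 1            F
#> 2            N
map_switch_success(sim)
#> [1] TRUE
```

The familiar-map bump dominates until the teleportation, is erased by the
feed-forward inhibition pulse, and a weak novel-map population ignited by
the dentate gyrus burst takes over and tracks position closely (~5 cm
median decoding error) for the remaining laps. With
`ablations = "no_dg_excit"` no novel map forms; with
`ablations = "no_dg_inhib"` the familiar bump survives the teleportation
and the novel map never ignites. See `?fig5_ca3_config` and the methods
vignette (`vignettes/novelty-signals.Rmd`) for the calibration this preset
carries and why.

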
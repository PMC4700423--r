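# statecortex

Cortical state — the difference between slow-wave–like *synchronized*
activity, with its alternation of population firing (UP states) and silence
(DOWN states), and tonic *desynchronized* activity — reshapes how the
auditory thalamocortical circuit responds to sound. `statecortex` is an R
package for analysing this state dependence in laminar silicon-probe
recordings from auditory cortex (AC) and the auditory thalamus (MGB), where
desynchronization is induced transiently by electrical stimulation of the
basal forebrain (BF). It is written for systems neurophysiologists who need
a tested, reproducible implementation of the full analysis chain, and it
ships a synthetic-session generator with known ground truth so that every
stage can be validated end to end without any recorded data.

## What the pipeline computes

* **Laminar alignment (CSD).** The current source density is the negated
  second spatial derivative of the laminar LFP,
  CSD(r, t) = −[φ(r+h) − 2φ(r) + φ(r−h)]/h², after duplicating the edge
  channels and smoothing across depth with the triangular kernel
  [φ(r−h) + 2φ(r) + φ(r+h)]/4 (h = 50 µm contact spacing). The channel with
  the largest click-evoked sink marks the thalamic recipient layer (depth
  0 µm); unit depths come from the channel of maximum trough-to-peak
  waveform amplitude.
* **Cell classification.** Cortical units are split at a trough-to-peak
  width of 0.55 ms into narrow-spiking (NS, putative fast-spiking
  interneurons) and broad-spiking (BS) cells; BS cells are binned by depth
  relative to the recipient layer into BS1 (0…200 µm), BS2 (−300…0 µm),
  BS3 (−700…−300 µm) and BS4 (−1100…−700 µm), approximating layers 2/3,
  3/4, 5 and 6.
* **State epochs and UP states.** Synchronized/desynchronized epochs are 3 s
  windows before/after each BF stimulation (the desynchronized episode lasts
  ~10 s); UP states are detected from the summed cortical multiunit activity
  (1 ms bins, 10 ms Gaussian kernel) by a geometric-mean threshold θ with a
  100 ms pre-silence criterion (< 0.2 θ) and a 200 ms above-threshold
  criterion.
* **Spectral depth profiles.** Band powers (δ 0–4, θ 4–8, α 8–12, β 12–30,
  low-γ 30–50 Hz) per channel and state, and their modulation index
  MI = (DESYNC − SYNC)/(DESYNC + SYNC).
* **Evoked reliability.** Per-trial spike counts in the 0–100 ms onset
  window give mean µ, variance σ², and Fano factor σ²/µ per state, each
  summarised as an MI; mean spike time in 80–200 ms captures the timing of
  post-onset suppression and rebound; PSTHs are peak-normalized.
* **Correlations.** Pairwise spike-count correlations (1 ms bins, 5 ms
  Gaussian kernel, Pearson r) over the spontaneous state windows.
* **Phase locking.** For 4–64 Hz click trains, spike phases within the
  inter-click interval T (excluding the first 50 ms) give the vector
  strength VS = |Σ e^{iθ}|/n, tested with the Rayleigh statistic
  Z = n·VS² (significant at p < 0.01), and summarised as VS modulation
  indices and fractions of significantly locked cells per class.

## Worked example

Simulate a default session (~12.6 simulated minutes, 60 AC + 20 MGB units,
32-channel laminar probe) and run the full pipeline:

```r
library(statecortex)
sim    <- simulate_session(sim_config(), seed = 7)
report <- run_pipeline(run_config(seed = 7), sim = sim)

report$spont_mi
#  cell_class      mean_mi  n
#         BS1 -0.425231073 10
#         BS2  0.037505590 12
#         BS3  0.029944728 14
#         BS4 -0.378622532 12
#         MGB  0.004634838 20
#          NS  0.061301926 12

report$mean_spike_time$AC
# $sync_ms: 152   $desync_ms: 125   $diff_ms: -27

report$vs
#  cell_class          mi area
#         BS1  0.33462211   AC
#         BS2  0.21430882   AC
#         BS3  0.24046617   AC
#         BS4  0.33439692   AC
#         MGB -0.02381401  MGB
#          NS  0.23477084   AC
```

Reading the output: spontaneous firing of the superficial and deep
broad-spiking classes (BS1, BS4) drops in the desynchronized state
(MI < 0) while the other classes barely change; the cortical mean spike
time in the 80–200 ms window shortens by ~27 ms (earlier rebound) with no
such shift in MGB; and click-train vector strength improves in every
cortical class (MI > 0) but not in MGB — the state dependence the synthetic
session encodes and the pipeline recovers. The run also reports band-power
MIs by depth (δ power collapses in deep channels, low-γ rises
superficially), onset-rate MIs (BS −0.11, NS +0.44), Fano-factor reductions,
pair correlations and detected UP states (44 at θ ≈ 227 Hz here).

`run_pipeline(..., out = "dir")` writes every stage table
(`units.tsv`, `epochs.tsv`, `band_power*.tsv`, `onset_stats.tsv`,
`mean_spike_time.tsv`, `correlations.tsv`, `vs*.tsv`) plus a `report.json`
stamped with the seed and a hash of the resolved configuration. A thin
command-line wrapper lives in `inst/scripts/statecortex`
(`statecortex run|simulate|print-config`).

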
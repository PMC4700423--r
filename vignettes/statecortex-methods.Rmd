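---
title: "Methods: state-dependent laminar analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent laminar analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `statecortex` implements,
the parameters that matter, the design choices that were genuinely open,
and what the synthetic-session validation does and does not establish.

## The analysis problem

A laminar silicon probe in auditory cortex (AC) and a second probe in the
auditory thalamus (MGB) record local field potentials (LFP) and
spike-sorted single units while the basal forebrain (BF) is stimulated
electrically. Each 1 s stimulation flips the cortex from a synchronized
regime — slow (≲1–2 Hz) oscillations with alternating UP/DOWN population
states, strongest in deep layers — into a desynchronized regime lasting
roughly 10 s, with suppressed low-frequency power and a superficial 30–50 Hz
component. The pipeline quantifies how this state change modulates
spontaneous firing per cell class, evoked onset reliability, response
timing, pairwise correlations, and phase locking to click trains.

All times live on one session clock in seconds (double precision); LFP
sample *k* is at `t0 + (k-1)/fs`. Channel 1 is the most superficial
contact and the index grows with depth; fixing this once avoids sign errors
in every depth computation. Analysis windows are half-open `[a, b)`
throughout so that events on shared edges are never counted twice.

## Laminar alignment

The current source density is computed from the depth-smoothed LFP as the
negated three-point second spatial difference with contact spacing
h = 50 µm. Edge channels are handled by duplicating the uppermost and
lowermost channels before both the triangular spatial smoothing
(¼, ½, ¼) and the second difference, so the output keeps the input channel
count. Conductivity is set to 1 (arbitrary units): only the *location* of
the largest click-evoked sink matters, and that is invariant to scale.
Sinks are negative by convention; the recipient channel is the argmin of
the click-triggered average CSD in a 0–50 ms post-click window (the window
is configurable; all clicks at the analysed level are pooled). Ties break
toward the superficial channel. A flat CSD (no negative excursion) is an
error, not a channel.

Unit depth is the channel of maximum trough-to-peak amplitude of the mean
waveform; relative depth is `(recipient − depth_channel) × 50 µm`, positive
toward the pia.

## Classification

The 0.55 ms trough-to-peak threshold separates narrow- from broad-spiking
cortical cells; a width of exactly 0.55 ms counts as broad-spiking (the
threshold value itself had no assigned side, so a side had to be fixed; the
choice is documented here and tested). Depth bins BS1 0…200, BS2 −300…0,
BS3 −700…−300, BS4 −1100…−700 µm are half-open with the lower edge
included in the bin it bounds below, which makes the bins a partition —
any convention with overlapping or gapping edges would let a unit land in
zero or two classes. Narrow-spiking cells keep their class at any depth
(no depth bin is defined for them), broad-spiking cells outside all bins
are `unclassified`, and thalamic units are always class `MGB`.

## UP-state detection

Multiunit activity (MUA) is the summed spike count of all cortical units in
1 ms bins, convolved with a unit-area Gaussian kernel (SD 10 ms, truncated
at ±4 SD). The detection threshold θ is the geometric mean of the smoothed
MUA over stimulus-free bins. The geometric mean is undefined over silent
bins, so it is taken over bins exceeding a positivity floor of half of a
single spike's peak kernel contribution; for a deterministic rate trace
(where that floor is meaningless) the floor is a user argument. An onset at
*t* requires (i) an upward crossing of θ, (ii) mean MUA below 0.2 θ over
the preceding 100 ms, and (iii) MUA above θ over the following 200 ms.
Criterion (iii) is read strictly by default — every bin above θ — with a
mean-above-θ alternative (`post_rule = "mean"`), since "remained above" is
ambiguous between the two. Each accepted UP state is reported as the 200 ms
window `[t, t + 0.2]`, the window also used for UP-state firing rates.

With Poisson population spiking the strict rule rejects a material fraction
of true UP states on single-bin dips, and late threshold crossings can
push early-UP spikes into the pre-silence window: on simulated sessions at
the default population size (~60 cortical units) recovery of UP states
≥ 300 ms saturates near 85–90% under the mean rule and lower under the
strict rule. On deterministic rate traces the detector recovers > 90% of
UP intervals ≥ 300 ms with median onset error near 10 ms (driven by the
smoothing kernel, which advances the crossing of a rising edge). This is a
property of the stated detector, not of the implementation.

## Spike-train statistics

The modulation index MI = (DESYNC − SYNC)/(DESYNC + SYNC) is bounded in
[−1, 1] and antisymmetric; the UP-versus-desynchronized variant
(UP − DESYNC)/(UP + DESYNC) uses the same form. When both inputs are zero
the MI is undefined and the unit is *excluded*, never scored 0 — scoring 0
would shrink class averages toward no effect.

Onset statistics use per-trial counts in `[0, 100)` ms; variance uses the
unbiased (n − 1) estimator (unspecified in the source conventions; n − 1
is the default a statistician would assume), so the Fano factor of
constant counts is exactly 0 and of Poisson counts 1. Units must spike in
the onset window in *both* states to be analysed. Mean spike time in
`[80, 200)` ms is pooled over all spikes of all trials (a per-trial variant
would weight trials equally rather than spikes; the pooled reading matches
"mean spike time" most directly and the per-trial variant can be built from
the same primitives). Normalized PSTHs use 1 ms bins over `[−50, 300)` ms,
5 ms SD Gaussian smoothing — chosen to match the correlation kernel, since
no PSTH kernel is prescribed — and division by the peak.

Spike-count correlations bin each train at 1 ms inside each 3 s state
window, smooth with a 5 ms SD Gaussian *within* the window (no leakage
across concatenation joints), concatenate windows of the same state, and
take the Pearson correlation. Zero-variance vectors yield a missing value.

## Phase locking

For a click train at *f* Hz, spikes from 50 ms after train onset (the
exclusion removes the onset transient, which would inflate locking) to the
1 s train end are mapped to phase 2π((t − onset) mod T)/T with T = 1/f.
The vector strength is the mean resultant length; the Rayleigh statistic is
Z = n·VS² with the finite-sample p approximation
`p = exp(−Z)(1 + (2Z − Z²)/(4n))`, clipped to [0, 1]. The approximation was
chosen over permutation for speed; its calibration is part of the test
suite (10,000 uniform-phase samples of n = 100: rejection at α = 0.01
within [0.007, 0.013], mean Z within [0.95, 1.05]). Phases are pooled over
presentations before computing VS. Units contribute to VS modulation
indices only when both states yield a VS; units with n ≥ 2 in a state count
in that state's significant fraction regardless.

## The synthetic-session generator

The generator exists so that every stage has a recoverable answer. Its
defaults *are* the study conditions, chosen once:

* **Block design.** Eight isolated spontaneous BF stimulations (1 s, with
  10 s desynchronized aftermath and 10 s recovery); four rounds of click
  blocks (10 no-stim + 10 stim trials each, click 0.5 s after the 1 s BF
  pulse ends in stim trials); ten presentations per state of 1 s click
  trains at 4, 8, 16, 32, 64 Hz — about 12.6 simulated minutes. Trials in
  stim blocks are desynchronized, in no-stim blocks synchronized.
* **States.** UP/DOWN durations are log-normal with medians 400/300 ms
  (SD 0.4 log units): no durations are prescribed anywhere, and these make
  UP states ≥ 300 ms — the detector's 100 ms + 200 ms windows — common,
  while keeping the alternation in the 0.5–2 Hz slow-oscillation range.
* **LFP.** 32 channels at 1 kHz: 1/f background (20 µV), a 1.2 Hz slow
  oscillation (300 µV) weighted toward deep channels in the synchronized
  state, a 40 Hz narrowband component (40 µV) decaying with depth from the
  surface in the desynchronized state, raised-cosine cross-fades at state
  boundaries, and a click-evoked sink (Gaussian in time, 12 ms latency,
  5 ms width; Gaussian across channels, SD 1.2 channels) at the recipient
  channel (default 8).
* **Rates.** Per-class spontaneous rates are order-of-magnitude choices in
  the 1–10 Hz range (absolute class rates are not published): UP/DOWN rates
  of 12/0.3 (NS), 5/0.1 (BS1), 6/0.15 (BS2), 7/0.15 (BS3), 4/0.1 (BS4) Hz
  and tonic desynchronized rates of 8, 1.2, 3.5, 4.5, 1.0 Hz respectively;
  MGB is tonic at 8 Hz in both states. BS1 and BS4 therefore *decrease*
  their average rate under desynchronization while NS, BS2, BS3 and MGB
  barely change — the directions the pipeline must recover.
* **Evoked templates.** Gaussian onset bump (15 ms latency, 6 ms SD) with
  state-dependent amplitude (BS 80→25 Hz, NS 50→80 Hz, MGB 70→60 Hz),
  multiplicative suppression of the background (×0.15) from 40 ms until
  30 ms before the rebound, and a cortical rebound bump (20 Hz, 15 ms SD)
  at 150 ms (synchronized) versus 115 ms (desynchronized). In the
  synchronized state the whole evoked response is scaled by the UP/DOWN
  gate at click time (×1 in UP, ×0.35 in DOWN), which is what makes
  synchronized trial counts over-dispersed (Fano > 1) and desynchronized
  responses more reliable. The rebound is deliberately narrow so that its
  desynchronized advance does not leak spikes into the 0–100 ms onset
  window and cancel the broad-spiking onset reduction.
* **Phase locking.** Each click evokes a Poisson number of locked spikes
  (0.45 per click in AC, 0.5 in MGB) at von Mises phases with
  concentration κ = 1.2→3.0 (AC, synchronized→desynchronized) and 3.0→3.0
  (MGB), on top of the ongoing background — so cortical vector strength
  improves with desynchronization and thalamic vector strength does not.
* **Determinism.** One top-level seed; components use fixed offsets
  (schedule +1, units +2, LFP +3, waveforms +4, unit *i* spikes +1000+i),
  so adding a unit leaves all others bit-identical.

What the generator does *not* emulate: biophysical LFP generation,
conduction delays, spike-sorting contamination and drift, rate adaptation
across a click train, level tuning, or any tonotopy. Passing tests
therefore show that the pipeline recovers known structure of the kinds
listed above at realistic magnitudes — not that it is robust to artifacts
the generator never produces.

## Spectral estimation

No estimator parameters are prescribed beyond the toolbox used, so the
package implements two and treats band-integrated quantities as the
contract: a sine-taper multitaper estimator (K = 5 tapers, the analogue of
time–bandwidth NW = 3) as default and Welch (1 s Hann windows, 50%
overlap) as alternative. Both satisfy a Parseval sanity check (total band
power within 5% of signal variance on stationary noise) in the test suite.
Preprocessing is a zero-phase Hamming-window FIR low-pass at 200 Hz
(applied in the frequency domain with group-delay removal) followed by
resampling to 1 kHz; input already at 1 kHz is filtered but not resampled.
The ≤7 Hz state index is computed on a single deep channel (default: four
channels above the deepest) — averaging across channels is a configurable
alternative, but a single deep channel is where the slow oscillation is
largest and is the cleaner visualization.

## Numerical choices and degenerate inputs

Window membership uses half-open intervals with a 1 ns guard against
floating-point round-off at exact boundaries (a spike placed exactly 50 ms
after train onset must be included). Spike times are stored as text at 15
significant digits so a written session re-validates as strictly
increasing. Coincident simulated spikes (measure zero, but guarded) are
nudged by 1 ns. CSD on affine depth profiles is asserted to vanish to
1e−9 relative; the quadratic profile must give its closed-form constant
exactly to double precision. Degenerate inputs raise errors naming the
problem: all-zero waveforms, monotone (non-biphasic) waveforms, flat CSD,
empty spontaneous masks, silent MUA, segments shorter than one PSD window.

## Problem sizes in the test suite

Module tests run on a reduced session (11 units, 4 spontaneous
stimulations, one click round, 2 train frequencies, ~3 simulated minutes),
which keeps the default test run around two to three minutes; the
directional end-to-end checks use the full default session (80 units,
~12.6 simulated minutes, seed 7) once per run. The acceptance script
re-simulates the full session at the caller's seed. Effect sizes in the
generator are large enough that the recovered directions are stable across
seeds, which is what makes a single-seed directional assertion meaningful.

## Known limitations

* The Rayleigh p-value is a first-order approximation; for n < ~10 its
  tails are inexact (the package reports it anyway, with n, so users can
  filter).
* The UP-state detector inherits the threshold-crossing latency of the
  smoothing kernel (~10 ms on rising edges) and, under the strict
  200 ms rule, misses true UP states whose Poisson MUA dips below
  threshold for a single bin.
* Isolation quality is a supplied scalar filtered at ≥ 20; the package
  does not compute isolation distance from cluster features.
* Group-level omnibus statistics (ANOVA, Kruskal–Wallis, signed-rank) are
  out of scope by design: the pipeline emits the per-unit statistics those
  tests consume, and standard R functions (`aov`, `kruskal.test`,
  `wilcox.test`) apply directly to the output tables.
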
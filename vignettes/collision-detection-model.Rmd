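---
title: "An LGMD collision detector with polarity-specific feed-forward inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LGMD collision detector with polarity-specific feed-forward inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olgmd)
```

## The model

Locusts carry a pair of wide-field visual neurons, the lobula giant movement
detectors (LGMD1 and LGMD2), that respond selectively to looming -- the
accelerating image expansion of an object on a collision course. LGMD1 fires
for both darkening and brightening approaches; LGMD2 only for dark objects
against a lighter background. This package implements a computational model
of that circuit in which the feed-forward inhibition (FFI) is carried
separately by the ON (brightening) and OFF (darkening) pathways, and doubles
as an *activation gate* that lets a quiet pathway skip its expensive spatial
processing altogether.

Per frame, the pipeline is:

1. **Photoreceptor.** `P(x,y,t) = L(x,y,t) - L(x,y,t-1) + p * P(x,y,t-1)`,
   with persistence `p = 0` by default (pure frame differencing). The first
   frame of a sequence yields `P = 0`.
2. **Polarity split.** `P_on = max(P, 0)`, `P_off = min(P, 0)`. The two maps
   reconstruct `P` exactly and are mutually exclusive per pixel.
3. **FFI per channel.** Each channel's FFI is the widefield mean of its
   rectified change, smoothed by a first-order low-pass with
   `alpha = tau_in / (tau + tau_in)`. The smoothed value drives
   (a) the adaptive inhibition weight
   `omega(t) = max(omega_base, ffi_hat(t) / omega_ffi)` and
   (b) the binary gate `beta(t) = [ffi_hat(t) > th_ffi]`.
4. **Channel stage** (only when `beta = 1`). Excitation is the biased
   rectified change; inhibition is the delayed (low-passed) change map spread
   spatially by a hollow convolution kernel;
   `S = max(E - omega(t) * I, 0)`. The summed ON + OFF map is passed through
   a grouping stage (scaling by its normalized local mean) and a decay
   threshold that discards small isolated excitation. Delay states advance
   from the raw maps every frame, gated or not, so a re-opening gate sees no
   stale transients.
5. **LGMD.** The surviving excitation is summed into `FFE(t)` and squashed to
   a membrane potential `K(t) = 1 / (1 + exp(-FFE / (R * C * alpha6)))`,
   normalized into `[0.5, 1)`. Spike-frequency adaptation passes genuine
   rises unattenuated and decays flat or falling potential toward 0.5. The
   adapted potential maps to a firing rate `exp(alpha7 * K - T_spi)`, fires a
   binary spike whenever it exceeds 0.8, and the collision flag is raised
   when at least `n_sp` spikes fall inside the trailing window of
   `n_ts + 1` frames.

## Why the selectivity works

Three mechanisms cooperate, and each handles a different distractor class:

* **The activation gate** suppresses weak widefield change outright. A
  translating object of moderate size moves too few pixels per frame to push
  the smoothed FFI over the default threshold of 1 (mean luminance-change
  units), so both channels stay closed: translation costs almost nothing and
  produces no response at all.
* **Lateral inhibition geometry** penalizes slow or self-overlapping motion.
  The default 5x5 hollow kernel has a 2-pixel reach: an edge that moves
  within that reach lands on territory still inhibited by its own recent
  history, while a looming edge in its final frames jumps several pixels per
  frame into fresh territory and escapes.
* **Spike-frequency adaptation** removes sustained responses. Drifting
  gratings drive a large but *constant* membrane potential: after two or
  three onset spikes the adapted potential decays below the 0.8 spike level
  and stays there, never accumulating the `n_sp = 5` spikes the decision
  window requires. A true approach drives a monotonically rising potential,
  which adaptation transmits unattenuated.

The presets differ only in the polarity balance of delay constants, baseline
inhibition weights and channel gains. `oLGMD2` opposes its ON channel with
fast (`tau_on = 15` ms), heavily weighted (`omega1 = 4`) inhibition and a
halved gain, so brightening input -- a light object approaching, or a dark
object receding -- is cancelled inside the channel; `reverse-oLGMD2` mirrors
the same numbers onto OFF; `oLGMD1` is symmetric (`tau = 60` ms,
`omega = 0.5`, gain 1 on both sides). The two `baseline-` presets are the
ungated twins used for efficiency comparisons: identical parameters with the
gate forced open.

```{r selectivity}
battery <- default_battery()
for (preset in c("oLGMD1", "oLGMD2", "reverse-oLGMD2"))
  print(score_suite(battery, preset))
```

## The synthetic battery

`default_battery()` renders eight noise-free 99x99, 100-frame sequences at a
30 ms frame interval: dark and light looming, receding and translating
objects, plus two drifting square-wave gratings (periods 20 and 40 px at 2
and 4 px/frame). Dark stimuli draw a level-50 object on a level-200
background; light stimuli mirror the levels. Looming half-width follows a
hyperbolic profile from 2 px to 44 px -- the image law of an approach at
constant physical speed, which accelerates sharply in the last frames -- and
receding reverses it. The collision window is the final 15% of a looming
sequence, where that acceleration concentrates the model's response; 100
frames is a typical length for one complete approach in embedded-vision
collision testing.

What the battery does *not* emulate: sensor noise (available via
`noise_sd`, but the reference battery is noise-free so pixel counts are
exact), textured backgrounds, ego-motion, lighting changes, and compression
artifacts of real video. A perfect score here demonstrates the mechanisms
above under controlled contrast and geometry, not field robustness.

## Efficiency accounting

The efficiency ratio `ER = sum(t_max - t_i) / (F * t_max)` measures the
fraction of the reference per-frame cost saved over a sequence. Tests and
reports use a deterministic cost surrogate -- the count of pixel operations
actually executed (convolution, interaction and grouping stages are charged
only when they run) -- because wall-clock timing is hardware-dependent;
`cost_ms` is still recorded in every trace for demonstration. The reference
`t_max` is the cost of a fully active frame (`frame_cost_reference()`),
which is exactly what an ungated model pays on every frame and what a gated
model pays at the peak of a collision response. Defining `t_max` this way
keeps ER comparable across thresholds: it is 0 for the ungated baselines and
non-decreasing in the activation threshold, even at extremes where every
frame is gated.

```{r sweep}
small_battery <- default_battery(n_frames = 50, resolution = c(49, 49))
threshold_sweep(small_battery, "oLGMD2", c(0, 0.5, 1, 1.75, 3))
```

Raising the threshold first trades nothing (translation and gratings are
already suppressed) while saving work; past the useful band it starts
swallowing the looming response itself and the success ratio collapses. The
default `th_ffi = 1` sits inside the high-SR, high-ER band.

## Numerical and design choices

* **Gate comparisons are strict** (`>` / `<=`) with no epsilon; the FFI
  statistics are computed every frame even when gates are closed, since they
  are cheap field means and the gate could never re-open without them.
* **The sigmoid is clamped** to the largest double below 1 when `exp()`
  underflows, preserving the analytic guarantee `K < 1` for arbitrarily
  large excitation.
* **Spike-frequency adaptation** passes a rise only when it exceeds
  `sfa_rise_tol = 0.02`. Without a tolerance, a drifting periodic pattern
  whose boundary count fluctuates by one pixel column produces tiny periodic
  rises in an otherwise saturated membrane potential, each of which would
  re-trigger the pass-through and defeat adaptation. Genuine looming rises
  near the decision point are an order of magnitude larger.
* **Spike discretization.** The exponential firing rate is continuous; the
  countable spike used by the decision window is the exceedance of the
  adapted membrane potential over 0.8 (`spike_mp_level`, configurable), and
  the window is inclusive: the current frame plus the previous `n_ts`.
  Adaptation feeds the spike test because it exists precisely to sharpen
  collision selectivity.
* **Inhibition kernel.** A 3x3 kernel (1-pixel reach) cannot null patterns
  drifting at 2+ px/frame, which realistic translation and grating speeds
  exceed; the default is therefore the 5x5 hollow inverse-square kernel,
  normalized to sum 1, with `inhibition_kernel(3)` available for the
  classical structure.
* **Gated-off frames still update delay states** (default). The alternative
  -- freezing state while gated -- makes the delayed inhibition map stale,
  so a gate re-opening onto a moved edge mistakes it for fresh excitation;
  it remains available as `update_gated_state = 0` for ablation.
* **Zero padding** for all convolutions, and binary rasterization (no
  antialiasing) in the stimulus generator, keep both stages exactly
  checkable against brute-force oracles.
* **Event scoring.** Whole sequences are scored: an alarm inside the
  collision window is the true positive; an alarm anywhere else -- including
  early on a genuine looming sequence -- counts against the model.
* **Model constants** (`alpha6 = 1.5`, `alpha7 = 10`, `T_spi = 5`,
  `n_sp = 5`, `n_ts = 9`, `omega_ffi = 20`, `sfa_tau = 270` ms and the
  preset asymmetries) were calibrated once against the default battery so
  that the documented selectivity matrix holds with zero violations, then
  frozen; they are all exposed through `olgmd_params()` overrides and the
  flat-text configuration files under `inst/extdata/presets/`.
* **Problem sizes.** Documentation examples and the test suite run the full
  99x99 x 100-frame battery where the claim is about selectivity, and
  reduced geometries (down to 8x8 maps for the convolution oracles) where
  the claim is arithmetic equivalence, which is size-independent.

## Known limitations

* Selectivity presets are calibrated for object/background contrasts of the
  order of the battery's (|150| luminance units); very low-contrast
  approaches can stay under the activation threshold (the gate trades
  sensitivity for efficiency by design -- the threshold sweep shows the
  trade).
* The translating-object suppression relies mostly on gating, so a very
  large or very fast translating object that opens the gate is handled by
  the inhibition geometry and adaptation instead; extreme speeds between the
  kernel reach and the frame width are the hardest case.
* `ER` from wall-clock time is reported but not asserted anywhere;
  vectorized execution makes per-frame timing noisy at these frame sizes.
* The model processes luminance only; color opponency and photoreceptor
  noise modeling are out of scope.
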
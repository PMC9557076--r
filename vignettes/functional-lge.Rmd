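---
title: "Methods: phase-resolved synthetic LGE from pulsed Look-Locker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-resolved synthetic LGE from pulsed Look-Locker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funlge)
```

## The model

Conventional LGE nulls healthy myocardium with a single inversion time and
therefore images a single cardiac phase. `funlge` implements the
phase-resolved alternative: sample the inversion recovery at several
inversion times *for every cardiac phase*, fit a semi-quantitative relaxation
model per voxel per phase, and synthesize the nulled contrast retrospectively.

Under a continuous train of small-flip-angle FLASH pulses (flip $\alpha$,
repetition time $TR$) the longitudinal magnetization relaxes toward a
*pulsed steady state*

$$M_{ss} = M_0\,\frac{1-E_1}{1-E_1\cos\alpha},\qquad E_1 = e^{-TR/T_1},$$

with the apparent rate

$$\frac{1}{T_1^*} = \frac{1}{T_1} - \frac{\ln\cos\alpha}{TR},$$

so $T_1^* < T_1$ whenever $\alpha>0$ (at 3T settings, $T_1=910$ ms maps to
$T_1^*\approx 728$ ms). If an inversion is applied *from* the pulsed steady
state, the readout signal follows the two-parameter model

$$S(TI) = A\,(1 - 2e^{-TI/T_1^*}),$$

which assumes complete inversion (inversion efficiency 1, configurable in
`sequence_params()` to study model mismatch). The same expression evaluated
at a virtual inversion time $T_{syn}$ synthesizes LGE contrast from the
fitted $(A, T_1^*)$ maps; $S_{syn}=0$ exactly at $T_{syn} = T_1^{*}\ln 2$ of
the tissue to be nulled. One $T_{syn}$ is shared by all phases so contrast
is comparable across the cycle.

## Timing: how each phase gets its inversion times

The acquisition is prospectively triggered. An inversion is played $t_{off}$
ms after the R-wave; the FLASH readout then covers an acquisition window
(default 90% of the R-R interval) in every beat, with dummy pulses filling
the remainder so the pulsed recovery is never interrupted. Because the
recovery spans `recovery_beats` (default 2) beats, each inversion
contributes two samples per phase, one R-R interval apart. Repeating the
experiment with `n_offsets` (default 3) different $t_{off}$ yields
$2\times3=6$ inversion times per phase.

Conventions chosen here (the sequence description leaves them open):

* **Offsets**: evenly spaced $\{0, RR/3, 2RR/3\}$ by default (maximizes TI
  spread per phase), configurable; resolved against $\min(RR)$.
* **Phase centers** at $(i+0.5)\times$`phase_duration_ms` after the R-wave;
  `n_phases = floor(f_{acq} \cdot \min(RR) / `phase_duration`)`.
* **Wrap rule**: a phase whose center precedes the inversion in the trigger
  beat is first sampled in the following beat (a phase cannot be sampled
  before its inversion),
  $TI = ((pc - t_{off}) \bmod RR) + b\,RR$, $b=0..$`recovery_beats`$-1$.
* **Variable R-R**: every offset experiment sees the same measured R-R
  sequence from its trigger beat, so the sorted TI table is invariant under
  offset permutation; each beat contributes its own duration to the $+RR$
  terms, and dummy-pulse counts vary per beat.
* Times are continuous milliseconds; TIs are not quantized to the TR grid
  (sub-TR shifts do not change the fitted model).

`plan_acquisition()` implements these rules arithmetically; the test suite
checks it against an independent brute-force event-list simulator.

## Signal simulation and what the phantom does (not) emulate

`simulate_pulse_train()` evolves $M_z$ event by event: relaxation between
pulses, $M_z \to M_z\cos\alpha$ at each FLASH pulse (readout and dummy alike,
contiguous at TR, restarting at each R-wave), $M_z \to -\eta M_z$ at
inversion. Signals are read at the exact planned phase-center times by free
relaxation from the preceding pulse, so simulated TIs equal planned TIs.

Two simulation details matter:

* **Re-drive between experiments.** With inversions every two beats, about
  $2e^{-2RR/T_1^*}\approx 13\%$ of the inversion amplitude would still be
  missing at $T_1=910$ ms, violating the complete-inversion premise and
  biasing $T_1^*$ by ~2.6%. The simulator therefore drives the magnetization
  back to the pulsed steady state (3 pre-drive beats) before each inversion,
  matching the sequence's stated "drive to steady state, invert, acquire
  until steady state is re-reached" cycle. With this, fits recover the
  closed-form $T_1^*$ to <0.1%.
* **`signal_model = "bloch"` vs `"ideal"`.** The event simulation retains
  ~0.1% deviations from the two-parameter model (the inversion occupies a
  pulse slot; sub-TR free relaxation around the inversion; beat-boundary
  gaps when RR is not a TR multiple). Tests that need *model-exact* data
  (e.g. nulling to $10^{-6}$) use the `"ideal"` model, which draws signals
  directly from $A(1-2e^{-TI/T_1^*})$ with closed-form $A$ and $T_1^*$.

The noise model adds zero-mean Gaussian noise to the signed signal and takes
the magnitude (Rician-type), because the fitting stage must exercise
polarity restoration; `baseline_snr` anchors the noise SD to the
steady-state readout signal of a named compartment (SNR 20 being the
standard simulation regime). Phantoms are single-slice 2D: a two-sphere
phantom (post-contrast $T_1$ 489/910 ms, blood/myocardium stand-ins) and a
cardiac short-axis phantom (blood pool, annulus, optional scar wedge,
optional per-phase radial contraction). Not emulated: k-space/undersampling
artifacts, coil sensitivities, $T_2^*$/off-resonance, slice profile, flow,
in-vivo motion — so a green phantom test establishes correctness of the
*processing*, not in-vivo image quality.

## Fitting: polarity restoration and solver choices

Magnitude data lose the sign of the recovery. `restore_polarity()` tries all
$k = 0..n-1$ flips of the $k$ earliest-TI samples, fits each candidate, and
keeps the smallest SSE (ties toward smaller $k$) — the standard multi-fit
approach; on noiseless data the chosen $k$ provably equals the number of TIs
below $T_1^*\ln 2$. The known cost, deliberately retained: when a sample
falls near the zero crossing, noise can flip the chosen $k$ and produce
salt-and-pepper outliers in phases whose minimum TI is near the null point.

The solver is a damped (Levenberg–Marquardt) least-squares on $(A, T_1^*)$
with analytic Jacobian. Unstated in the sequence description, chosen here:
initialization $A_0=\max|S|$, $T_{1,0}^*=TI_{\arg\min|S|}/\ln 2$ clipped to
[50, 3000] ms; convergence when the relative step or the relative SSE gain
falls below $10^{-8}$ (max 200 iterations); bounds $T_1^*\in(1,5000]$ ms and
$A\ge0$ by projection (a fit ending on the lower bound is flagged
non-converged). Gradient-only stopping was rejected: $\partial S/\partial
T_1^*$ is small in absolute terms, so an unscaled gradient test stops an
iteration early and costs ~$10^{-6}$ relative accuracy on exact data. No
spatial regularization: fits are voxel-wise by design. `fit_volume()` caches
identical signal vectors (compartment-constant noiseless stacks fit in
seconds at any grid size).

## Synthesis and metrics

`synth_time_for_null()` summarizes the ROI's $T_1^*$ with the median
(robust to edge voxels; mean by flag) before applying $\ln 2$; a manual
$T_{syn}$ override is supported (e.g. 567 ms to null a 910 ms sphere on a
scanner where the realized $T_1^*$ was longer than the nominal one).
$T_{syn}$ applies to the *apparent* $T_1^*$, never to a corrected $T_1$ —
the synthesis equation reuses the fit parameters verbatim. Output is
magnitude by default (what LGE displays); signed mode is kept for
inspection. Non-converged voxels propagate as `NA` and are excluded from
metrics.

Metrics follow the field's definitions: aCNR
$=|\mu_{Myo}-\mu_{Blood}|/\sqrt{(\sigma_{Myo}^2+\sigma_{Blood}^2)/2}$ with
within-ROI *spatial* SDs (comparable across phases of one scan, not to
literature CNR); repetition-noise CNR with per-voxel SD across repetitions,
pooled per ROI as the mean voxel SD (the pooling rule is this package's
choice, mirroring the aCNR denominator); CoV $=100\,s/\bar{x}$ with the
$n-1$ SD; linear interpolation of per-phase series onto 20 reconstruction
phases over normalized phase position $[0,1]$, endpoints to endpoints, no
extrapolation (the abscissa convention is this package's choice). Identical
repetitions give an infinite CNR sentinel rather than an error. ROI masks
may be shared or per-phase; cohort-level statistics (ANOVA) are out of
scope, the CSV/JSON report is designed to feed external stats tools.

## Known limitations and honest negatives

* The two-parameter model ignores incomplete inversion and B1+ effects; the
  package fits it regardless (that is the method), and `inv_efficiency`
  exists to study the resulting bias.
* At baseline SNR 20 with this 6-TI/two-beat scheme, the relative precision
  of $T_1^*$ is *better* at $T_1=650$ ms than at $T_1=350$ ms — both in
  Monte-Carlo CoV and in the Cramér–Rao bound of the sampling scheme. A
  reported tendency of noise susceptibility to *increase* with $T_1$ is
  therefore not reproduced by this simulation world (the corresponding
  acceptance test is intentionally left failing); what is reproduced, in
  expectation, is that the noisiest phase is the one whose minimum TI lies
  nearest the null point $T_1^*\ln 2$.
* File formats are plain-text CSV/JSON (no NIfTI/DICOM reader is available
  in the target environment); layouts are documented in `?write_stack` and
  sidecar JSONs carry shape, TI tables and provenance.
* Phase-resolved quantification of cardiac function, PSIR-style
  phase-sensitive polarity restoration, black-blood contrast and
  segmentation-based automatic $T_{syn}$ selection are out of scope.
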
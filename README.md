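# funlge — cardiac phase-resolved synthetic LGE imaging

Late gadolinium enhancement (LGE) imaging is the clinical reference for
visualizing myocardial scar: an inversion-recovery sequence is timed so the
healthy myocardium is nulled and scar appears bright. Conventional LGE is
confined to a single cardiac phase. `funlge` implements, as a simulation and
analysis toolkit, the three-step *functional LGE* approach that removes this
restriction:

1. **Phase-resolved multi-contrast acquisition.** A prospectively
   ECG-triggered, continuously running Look-Locker FLASH readout samples the
   inversion recovery for every cardiac phase. Because the recovery to the
   pulsed steady state spans two heart beats, each inversion pulse yields two
   points on the recovery curve per phase; repeating the experiment with
   three inversion-pulse offsets relative to the R-wave gives six inversion
   times TI per phase (each phase realizes a *different* TI set).
2. **Semi-quantitative T1\* mapping.** Per voxel and per phase, the
   magnitude data are polarity-restored (exhaustive early-TI sign-flip
   search) and fitted with the two-parameter inversion-recovery model

       S(TI) = A (1 − 2 exp(−TI / T1*)),

   where T1\* is the *apparent* relaxation time of the pulsed readout,
   1/T1\* = 1/T1 − ln(cos α)/TR.
3. **Contrast synthesis.** LGE contrast is synthesized voxel-by-voxel at a
   single retrospectively chosen virtual inversion time T_syn (the same for
   all phases, so contrast is comparable across the cycle):

       S_syn = A (1 − 2 exp(−T_syn / T1*)),   T_syn = T1*_ref · ln 2

   nulling a chosen reference tissue (typically remote myocardium).

The package contains the timing planner, an event-by-event Bloch-level
simulator of the pulsed magnetization on digital phantoms (two-sphere and
cardiac short-axis, optional contraction, Rician-type noise at a configurable
baseline SNR), the Levenberg–Marquardt fitting stage, the synthesis stage,
and the evaluation metrics used for this kind of sequence: apparent
contrast-to-noise ratio (aCNR), repetition-noise CNR, coefficients of
variation across phases and heart rates, and linear interpolation to 20
reconstruction phases. Everything is reachable from R and from a small CLI
(`inst/exec/funlge`) with subcommands `simulate | fit | synthesize | metrics
| run-all`, exchanging plain-text CSV/JSON files.

## Worked example

```r
library(funlge)

params <- sequence_params()                  # TR 5 ms, flip 3°, 3 offsets, 2-beat recovery
timing <- timing_from_bpm(60)                # 50 ms resolution, 90% window
plan   <- plan_acquisition(params, timing)
plan
#> <acquisition_plan>
#>   18 cardiac phases x 6 inversion times (50.0 ms resolution)
#>   offsets (ms): 0.0, 333.3, 666.7
#>   TI range: 8.3 - 1991.7 ms

spec   <- phantom_two_sphere(n = 64, radius = 10, baseline_snr = 20,
                             snr_reference = "myocardium")   # T1 489 / 910 ms
stacks <- generate_stack(spec, plan, n_repetitions = 2, seed = 42)
mask   <- spec$label_map > 0
maps   <- lapply(stacks, fit_volume, mask = mask)
maps[[1]]
#> <t1star_maps> 18 phases, 64 x 64 voxels, 100.0% converged

roi   <- phantom_masks(spec)
t_syn <- synth_time_for_null(maps = maps[[1]], null_roi = roi$myocardium)
t_syn                                        # 504.8 ms = median T1* × ln 2
synth <- lapply(maps, synthesize_lge, t_syn_ms = t_syn)

report <- contrast_report(synth[[1]], roi_pair(roi$myocardium, roi$blood),
                          repetitions = synth)
report
#> <contrast_report>
#>   18 acquired phases, t_syn = 504.8 ms
#>   aCNR: 13.68 +/- 1.42 (CoV 8.25% over 20 recon phases)
#>   repetition CNR: 17.48 +/- 1.65 (CoV 9.43%)
```

Reading the numbers: the 910 ms sphere (stand-in for healthy myocardium) is
nulled at T_syn = 504.8 ms — the apparent T1\* of 910 ms tissue under this
readout is 728 ms and 728 × ln 2 ≈ 505. The blood-pool sphere stays bright,
giving an aCNR of ~14 between the two ROIs; the CoV rows quantify how stable
that contrast is across the 18 simulated cardiac phases.

## Command line

```sh
Rscript inst/exec/funlge run-all --config config.json --out out/
```

with a JSON/YAML config mirroring the constructor arguments (see
`?read_config`, `?default_config`). Every output directory carries a
`provenance.json` with the resolved configuration and seed.

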
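# padflux

Impedance-based growth-rate monitoring for microfluidic yeast
micro-chemostats.

## The problem

In a pad-based micro-chemostat, a yeast colony grows as a monolayer
clamped under PDMS pads. Once the space under the pads is full, the
colony size stays constant: every division pushes one cell out of the
colony, into the medium flow, and over a pair of coplanar electrodes.
Each passage produces a transient peak (amplitude on the order of
10⁻³ degrees) in the phase of the impedance signal at 1.12 or 1.5 MHz.
Counting these peaks is therefore a label-free, continuous readout of
the colony's growth rate that leaves the microscope free for other
measurements. One impedance analyzer is shared across 15 analysis units
in a round-robin, so recording time is a budget to be allocated.

`padflux` turns raw phase traces into growth-rate estimates and answers
the scheduling question, and ships a synthetic-data generator (a digital
twin of the device) so that every stage can be validated against known
ground truth. It is aimed at people running such devices and at people
designing similar event-counting assays.

## The model

* **Peak detection.** The phase trace is band-pass filtered (0.1–30 Hz,
  4th-order Butterworth, forward–backward so peak times are preserved)
  and thresholded; local maxima closer than 50 ms are merged. Default
  thresholds: 4×10⁻³ ° at 1.5 MHz, 0.65×10⁻³ ° at 1.12 MHz.
* **Normalized peak rate.** Counts in 4-min windows are normalized by
  the average cell count under the pads and the window duration:
  `peak_rate_norm = count / (N̄ · Δt_h)` (events · h⁻¹ · cell⁻¹), with
  `N̄` the mean of the start- and end-of-session cell counts. This
  cancels colony size, so units with different numbers of filled pads
  are directly comparable.
* **Budding correction.** A budded cell (mother + bud) passes as one
  object and yields a single peak, so each peak carries on average
  `1 + BI` cells (`BI` = budding index, default 0.6):
  `growth_rate = peak_rate_norm · (1 + BI)`.
* **Precision.** Passages are a Poisson process with rate λ (events/s),
  so the rate estimated from total time `T = k·w` (k windows of length
  w) has `SEM = √(λ/T)` — precision depends only on the *total*
  recording time, not on how it is partitioned. Equal relative
  precision across units requires `Tᵢ = 1/(λᵢ·ρ²)`: slow colonies get
  longer windows.

## Worked example

Two analysis units carrying the same strain, with two and three filled
pads (colonies of 400 and 600 cells), per-cell peak rate 0.288 /h,
recorded for 6 h:

```r
library(padflux)
cfg <- experiment_config(list(
  seed = 101, duration = 6 * 3600, sampling_rate = 200,
  units = list(
    list(unit_id = "padsx2", growth_rate_per_cell = 0.288,
         pad_capacity = 400, pads_filled = 2, threshold = 2e-3),
    list(unit_id = "padsx3", growth_rate_per_cell = 0.288,
         pad_capacity = 600, pads_filled = 3, threshold = 2e-3))))
res <- run_pipeline(cfg)
print(res)
```

```
padflux growth-rate report
==========================

Per-condition estimates (rates in /h):

unit     condition  peakrate SEM                 n   growth SEM(growth)

padsx2   default       0.272 0.0115             89    0.435 0.0184
padsx3   default       0.285 0.0093             89    0.457 0.0148

Note: unit(s) padsx2, padsx3 had fewer than 4 filled pads; expect higher peak-rate variability.
```

Both units recover the simulated truth (0.288 /h) within two standard
errors despite their different colony sizes — the normalization cancels
colony size. The `growth` column is the budding-corrected rate
(×1.6 at the default budding index 0.6). `run_pipeline(cfg, "out/")`
additionally writes the events, window counts, per-window rates,
summaries (TSV + JSON), the simulation ground truth, and a run log.

A thin command-line front end with verbs
`simulate | detect | estimate | schedule | run` is installed at
`inst/cli/padflux` (run it with `Rscript`).

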
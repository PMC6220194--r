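---
title: "Methods: impedance peak counting as a growth-rate readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impedance peak counting as a growth-rate readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padflux)
```

## The measurement model

A yeast colony clamped in a monolayer under PDMS pads reaches a fixed
size once the pad area is full. From then on every division pushes one
cell out of the colony; the cell is entrained in the medium flow and
passes over a coplanar electrode pair, where it perturbs the
intra-electrode impedance and leaves a transient peak in the phase of
the demodulated signal. Counting peaks per unit time therefore measures
the colony's division rate without labels and without occupying the
microscope.

The chain of estimators in `padflux` is:

1. **Events.** Post-fill escape events form a Poisson process with rate
   $\lambda = r \cdot K$ (events/s after unit conversion), where $r$ is
   the per-cell peak rate (events h$^{-1}$ cell$^{-1}$) and $K$ the
   colony size.
2. **Normalized peak rate.** With $c_j$ peaks counted in window $j$ of
   length $\Delta t$ (hours) and $\bar N$ the average of the cell
   counts under the pads at the start and end of the session,
   $\hat r_j = c_j / (\bar N \Delta t)$. Colony size cancels, so units
   with different numbers of filled pads estimate the same $r$.
3. **Budding correction.** A budded mother–bud pair passes as a single
   object and yields one peak. If a fraction $BI$ of passing cells is
   budded, each peak carries $1 + BI$ cells on average, so the absolute
   growth rate is $\hat\mu = \hat r\,(1 + BI)$. The paper trail for the
   exact correction formula in the field is thin; $(1+BI)$ is this
   package's documented choice, derived from the two-cells-per-budded-
   passage argument, and is applied symmetrically to the SEM.
4. **Condition summaries.** Windows are assigned to a media condition
   only if fully contained in that condition's time segment and clear
   of any switch by a buffer (default 40 s, the duration of a medium
   exchange); the per-condition estimate is the mean of window rates
   with SEM $s/\sqrt{n}$ using the sample ($n-1$) standard deviation.
   Whether published $\pm$ values of this kind are SEMs over windows or
   SDs over replicates is often ambiguous; `padflux` reports SEM over
   windows and labels it as such.
5. **Relative change.** $100\,(\hat r_\text{other} - \hat
   r_\text{ref})/\hat r_\text{ref}$ with the slower (calcium)
   condition as reference — the convention consistent with reporting a
   recovery as a positive change.

## Precision and scheduling

For Poisson counts, the rate estimated from $k$ windows of length $w$
(as the mean of per-window rates, which for equal windows equals total
count over total time) has

$$\mathrm{SEM} = \sqrt{\lambda / (k w)}.$$

Only the product $kw$ — the total recording time — matters. This is the
basis of `poisson_sem()`, `simulate_sem()` (its Monte-Carlo twin),
`required_total_time()` ($T = \lambda/\varepsilon^2$), and
`allocate_windows()`. For multiplexed recording with one shared
analyzer, equalizing *relative* precision $\rho = \mathrm{SEM}/\lambda$
across units gives $T_i = 1/(\lambda_i \rho^2)$: slowly growing
colonies need strictly longer windows. Equal relative precision is this
package's formalization of the qualitative rule that slow units deserve
more time; any other monotone criterion could be substituted upstream
of `multiplex_schedule()`. Fractional cycle counts are floored and the
achieved (slightly worse) precision reported in a warning.

```{r precision}
poisson_sem(0.082, window_length = 60, n_cycles = 85)
required_total_time(0.082, target_sem = 0.004)
allocate_windows(c(fast = 0.1, slow = 0.05), target_relative_sem = 0.1)$entries
```

## What the synthetic-data generator emulates

`simulate_colony()` + `synthesize_trace()` form a digital twin of one
analysis unit:

* **Fill phase.** Deterministic exponential growth
  $N(t) = \min(N_0 e^{rt}, K)$ by default; a stochastic pure-birth
  model is available. Only post-fill behaviour feeds the estimator, so
  the default favours reproducibility. In media-switch scenarios units
  are configured pre-filled (`initial_cells = pad_capacity`), matching
  the experimental protocol in which recording starts only once pads
  are full.
* **Escape events.** Homogeneous Poisson with rate $rK$ after the fill
  time; zero events before. Under a media schedule the rate follows a
  piecewise-constant profile with a linear ramp of `switch_duration`
  (default 40 s) at each switch, sampled by thinning. The ramp models
  the finite medium exchange; true cellular response kinetics are not
  modelled.
* **Budding.** Each event is flagged budded with probability $BI$;
  a budded passage still produces a single peak of unchanged amplitude
  (whether budded passages are systematically larger is unknown, so the
  default assumes no effect).
* **Raw trace.** Slow sinusoidal baseline drift (amplitude 5×10⁻³ °,
  period 300 s — far below the 0.1 Hz high-pass corner), white Gaussian
  noise (SD 5×10⁻⁴ °), and one Gaussian bump per event: amplitude
  log-normal around 4×10⁻³ ° (the middle of the working threshold range
  at 1.5 MHz), width (FWHM) Gaussian around 20 ms. The true peak
  signature of a coplanar electrode pair may be bipolar and depends on
  cell size, position and speed; the unimodal default is a stated
  modelling choice, not a claim about the device, and the detector's
  merge rule is designed to be robust to mild ringing either way.
* **Multiplexing.** A round-robin schedule crops each unit's continuous
  trace into its recorded windows; gaps contain no samples and window
  boundaries are exact.

Passing tests on this generator show that the *pipeline* is unbiased
and correctly calibrated when its assumptions hold. They cannot show
that real passages are Poisson (cells leaving in bursts would
overdisperse counts), that real peaks are unimodal, or that thresholds
chosen for one medium transfer to another — those remain experimental
questions.

## Numerical choices

* **Filter.** `signal::butter(2, c(0.1, 30)/(fs/2))` applied
  forward–backward (`signal::filtfilt`), i.e. a 4th-order zero-phase
  band-pass. Zero phase preserves peak times, which windowed counting
  needs. Because `filtfilt` starts from zero state, a DC offset would
  leave an edge transient; the implementation therefore subtracts the
  segment mean and pads by odd reflection (3/`band_low` seconds per
  side) before filtering, and the first and last 1/`band_low` = 10 s of
  each contiguous segment are additionally excluded from detection.
  Counting windows are laid inside this trimmed span so the counting
  and detection spans coincide and no edge bias enters the rate.
* **Detection.** Local maxima (strict rise, non-strict fall, so a
  plateau's first sample wins) above the threshold; maxima closer than
  `min_separation` (50 ms, > 2 peak widths) merge keeping the larger.
  Width is the span above half amplitude with linear interpolation.
  The threshold defaults are the midpoints of the working ranges per
  stimulation frequency and should be overridden per unit when the
  medium changes the noise floor.
* **Windows.** Half-open `[start, end)`, trailing partial windows
  discarded; a window is dropped rather than prorated when it straddles
  a media switch (at most one window per switch, 40 s ≪ 240 s).
* **Degenerate inputs.** Empty traces yield empty event lists; an
  all-buffer schedule yields an empty series with a warning; a unit
  with zero average cell count is an error (not normalizable); a
  single-window SEM is reported as 0 and flagged undefined.
* **Determinism.** Every simulation function takes a seed and restores
  the caller's RNG state; per-unit seeds are derived from the
  experiment seed, so configs are bit-reproducible end to end.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the pipeline at 200 Hz
sampling (a 20 ms FWHM peak keeps ≥ 4 samples; the instrument
demodulator rate is higher, and 1 kHz remains the package default for
interactive use). The end-to-end scenarios are a 6 h two-unit run
(colonies of 400 and 600 cells at 0.288 events h⁻¹ cell⁻¹) and a 22 h
single-unit media-switch run (0.32 /h for 6 h, 0.196 /h for 10 h,
0.32 /h again, colony of 600 cells); Monte-Carlo properties use
200–2000 replicates at event level. These sizes give standard errors a
few percent of the estimate, tight enough that a 2-SEM recovery check
is meaningful.

## Known limitations

* Cell size, position and speed all shape the real peak; `padflux`
  neither models nor exploits peak shape, so single cells, budded cells
  and small clusters are indistinguishable (hence the budding *index*
  correction rather than per-event classification).
* The magnitude channel of the impedance signal is not processed; only
  the phase channel is.
* Counts are assumed Poisson; clustered shedding would make the
  closed-form SEM optimistic. `simulate_sem()` can be pointed at any
  empirical count stream to check.
* The media ramp is a modelling convenience; rate dynamics faster than
  the 240 s window are invisible to the estimator either way.
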
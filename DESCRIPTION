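Package: padflux
Title: Impedance-Based Growth-Rate Monitoring for Microfluidic Yeast Micro-Chemostats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free, impedance-based growth-rate
    quantification in a multiplexed microfluidic yeast micro-chemostat.
    Converts raw phase-vs-time impedance traces into cell-passage peak
    events (zero-phase bandpass filtering and threshold peak extraction),
    windowed peak counts, cell-number-normalized peak rates,
    budding-index-corrected growth rates, and per-condition summaries
    with standard errors and relative growth-rate changes. A Poisson
    counting model links measurement precision to total recording time
    and drives precision-optimal round-robin allocation of recording
    windows across analysis units. A synthetic-data module emulates the
    device (colony fill-and-shed dynamics, Poisson escape events,
    phase-peak waveforms, baseline drift and noise, media switches, and
    round-robin recording gaps) so the full pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
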
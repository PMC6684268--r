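Package: kqgate
Title: Two-Open-State Markov Gating Model and Voltage-Clamp Trace
    Analysis for KCNQ1 Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Five-state Markov model (RC, IC, AC, IO, AO) of KCNQ1
    (Kv7.1) channel gating with two open states reached at the
    intermediate and fully activated voltage-sensor conformations.
    Provides master-equation voltage-clamp simulation over
    piecewise-constant protocols (exact per-epoch matrix exponentials),
    the ML277 activator rule (halved AO exit rate with detailed-balance
    rebalancing of the cyclic scheme), mutant-variant model surgery
    (VSD-locked and coupling-ablated channels), and the standard
    electrophysiology trace-analysis toolbox: multi-exponential
    activation fits, hook-tail decomposition, G-V and F-V construction
    with Boltzmann fits, photobleach baseline correction, Rb+/K+ tail
    ratios and percent-increase measures.  A synthetic two-electrode
    voltage-clamp / voltage-clamp-fluorometry data generator with full
    ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
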
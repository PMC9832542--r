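Package: duetrhythm
Title: Rhythm, Causality and Synchrony Analysis for Duetting Animal Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporal rhythm analysis of annotated animal songs,
    built for duetting primates such as gibbons but applicable to any
    interval-annotated vocal sequence. Reads and writes Praat TextGrid
    annotations and flat onset tables; computes inter-onset intervals,
    rhythm ratios, on/off-isochrony classification, isochrony rates, call
    rates and tempo peaks from kernel density estimates; binarizes
    phonation and runs a bidirectional Granger-causality census between
    co-singers; measures phonation overlap (synchrony) and compares it to
    chunk-permutation chance distributions; and simulates coupled
    two-singer duets with known tempo, jitter, coupling and duty-cycle
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    optparse,
    jsonlite
Config/testthat/edition: 3
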
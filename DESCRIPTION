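Package: olgmd
Title: Collision-Detecting LGMD Visual Network with Polarity-Specific Feed-Forward Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an optimized lobula giant movement detector (LGMD) visual
    neural network for looming (collision) detection. Luminance change is split
    into parallel ON/OFF polarity channels; each channel carries its own
    feed-forward inhibition (FFI) statistic that both adapts the lateral
    inhibition weight and gates the channel's expensive spatial computation
    through a binary activation threshold. Remaining excitation is integrated
    into a sigmoid membrane potential with spike-frequency adaptation, an
    exponential spike-rate mapping, and a windowed spike-count collision
    decision. Ships a deterministic synthetic stimulus generator (looming,
    receding, translating, drifting gratings; dark and light contrast),
    selectivity presets (oLGMD1, oLGMD2, reverse-oLGMD2 and ungated baselines),
    efficiency-ratio / success-ratio evaluation metrics, an activation-threshold
    sweep, and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
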
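Package: rhythmioi
Title: Permutation Tests for Rhythmicity in Vocalization Onset Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonparametric detection of rhythmic structure in sequences of
    acoustic events. Adjacent inter-onset intervals (IOIs) within vocal bouts
    are summarised by the revised IOI-ratio (current interval over the sum of
    current and previous interval), and the observed ratio distribution is
    compared against a null ensemble obtained by permuting IOIs within
    exchangeability strata (individual by flanking element classes). Kernel
    density profiles on a fixed grid are reduced to a maximal normalized
    deviation test statistic with pointwise permutation confidence bands and
    local peak calling at integer-ratio rhythms such as isochrony. Includes an
    amplitude-envelope segmentation front-end for raw audio (Butterworth
    bandpass, stationary spectral gating, RMS envelope thresholding), Praat
    TextGrid and tabular annotation I/O, a synthetic rhythm simulator with
    planted integer-ratio grammars, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
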
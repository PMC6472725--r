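Package: pedalphase
Title: Phase-Space Analysis of Cyclic Pedalling Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-linear analysis of tangential pedal-force time
    series from cycling sessions. Segments a force trace into pedalling
    cycles at upward zero crossings, time-normalizes each cycle, z-scores
    per terrain sector, embeds the series in a two-dimensional delay phase
    space, and quantifies the attractor by the offset of a
    Levenberg-Marquardt regression circle (LR), the componentwise and
    geometric (L1) medians of the point cloud, the revolution-time
    coefficient of variation, and sector-mean heart rate. Includes a
    lambda-weighted planned-contrast analysis of these measures against
    terrain inclination, and a synthetic session generator emulating
    multi-sector rides for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
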
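Package: fptrials
Title: Event-Related Processing of Raw Force-Plate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes raw force-plate recordings for event-related
    (trial-based) designs in cognitive-motor research. Reads delimiter-
    separated force-plate exports, decodes parallel-port trigger pins into
    integer event codes, applies a zero-phase low-pass Butterworth filter
    with reversed-prefix padding, segments the continuous recording into
    per-trial epochs anchored on a start trigger, performs fixation-interval
    baseline correction, and computes user-defined descriptive statistics
    (mean, standard deviation, range, or custom functions) over user-defined
    time bins locked to within-trial events such as stimulus or response
    onset. Includes preparation and merging of behavioral trial tables and a
    seeded synthetic-recording generator with known ground truth so the full
    pipeline can be validated end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
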
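Package: endoskill
Title: Quantitative Assessment of Endoscopic Skills from Simulation Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of flexible-ureteroscopy training sessions
    recorded on a kidney-phantom simulator. Computes four skill metrics from
    endoscopy video and a session annotation log: Target Detection (fraction
    of placed renal calculi found), Fine Movement (frame-differencing scope
    speed held inside a calibrated coverage band), Visualization
    (centre-weighted over-exposure area as a proxy for scope-wall contact),
    and Efficiency (task time against a 5-minute budget). Includes group-level
    statistical comparison (normality screening plus unpaired two-tailed
    t-test), report and figure generation, and a fully deterministic synthetic
    endoscopy generator that emits frames together with closed-form
    ground-truth scores for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    nortest
Config/testthat/edition: 3
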
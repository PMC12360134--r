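Package: undulokin
Title: Speed-Dependent Undulatory Swimming Kinematics from Digitized Midlines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for quantifying steady undulatory swimming from
    coordinates digitized off orthogonal high-speed video: reads midline and
    landmark track files, merges dorsal and lateral views into 3-D landmark
    tracks, and computes per-trial kinematics (tail beat frequency, tail
    amplitude, traveling-wave speed and wavelength via the single-frequency
    phase gradient, midline curvature, body angle, angle of attack, fin
    effort, Reynolds and Strouhal numbers).  Cross-speed comparison uses
    assumption-gated repeated-measures or aligned-rank-transform ANOVA with
    Tukey-adjusted contrasts and compact letter displays, plus PCA with
    per-axis variable contributions.  A synthetic traveling-wave swimmer
    generator with known ground truth supports parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
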
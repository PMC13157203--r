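Package: mnphotodose
Title: Light Redistribution by Dissolving Microneedle Arrays for
    Photodynamic Therapy Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and analyses the light-redistribution behaviour of
    dissolving microneedle arrays used as optical diffusers in
    photodynamic therapy. Implements the closed-form intensity of a disk
    of isotropic emitters with Beer-Lambert attenuation together with
    independent quadrature and Monte-Carlo oracles, a directed-beam
    comparator, a seeded synthetic renderer of 8-bit RGB photographs of
    a laser-illuminated array at arbitrary camera angles, and the
    green-channel line-profile procedure (between-tip "line" and at-tip
    "MN" horizontal samples, central-window angular summaries, and a
    coefficient-of-variation isotropy index). An end-to-end pipeline
    orchestrates rendering, profile extraction, model checks and optical
    dose arithmetic with full seed bookkeeping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
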
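Package: pcnassay
Title: Tunable Plasmid Copy Number: ColE1 Replication Models and
    Pooled-Assay Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and estimators for finely tuned plasmid copy number in
    bacteria. Implements the ColE1 inhibitor-dilution replication model
    (hyperbolic and exponential inhibition limits, regime classification,
    and self-consistent coupling to growth burden), inference of
    per-construct doubling times and relative plasmid copy numbers from
    pooled serial-dilution sequencing counts, a weighted linear
    metabolic-burden fit, plate-reader growth and expression metrics with a
    fluorescence-based copy-number estimator, digital droplet PCR Poisson
    concentration and ratio estimation, and a thermodynamic occupancy model
    for CRISPRi effectors titrated by decoy ("sponge") binding sites. A
    synthetic-data generator emulates the pooled assay end to end so every
    stage can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
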
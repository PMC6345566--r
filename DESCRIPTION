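Package: crypticsplice
Title: Detection and Characterisation of Cryptic Splicing from Junction Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies splice-junction usage (PSI and delta-PSI with
    posterior-probability high-confidence calling) from STAR-style junction
    count tables, detects and classifies de-novo cryptic splicing events
    (cryptic internal exons, exitrons, alternative 5'/3' splice-site
    extensions and truncations, cryptic terminal exons coupled to
    polyadenylation signals), scores their reading-frame impact on coding
    sequences, scores splice-site strength as percentiles of a position
    weight matrix reference distribution together with exonic splicing
    enhancer density, and computes crosslink-window pentamer enrichment and
    positional motif maps from CLIP crosslink sites. Ships a seeded
    synthetic-data generator that emits genomes, annotations, junction
    counts and crosslink sites with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
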
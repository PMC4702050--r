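Package: degradomir
Title: Degradome-Guided Genome-Wide Discovery of miRNA-miRNA* Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers miRNA-miRNA* duplexes genome-wide by using degradome
    (PARE) sequencing 5'-end signatures as guideposts for Dicer/DCL1 cleavage.
    Scans 10,000-nt genome fragments (500-nt overlaps) on both strands for
    cleavage signals passing local-dominance (5x flanks) and fragment-rank
    (top-12) criteria, extracts (30+L)-nt precursor candidates around each
    signal, folds them (RNAfold or a built-in base-pair-maximization engine)
    and retains hairpin-plausible candidates by a 30-nt stem-complementarity
    filter (default > 70%). Small-RNA reads are then clustered into isomiR
    clouds on each candidate and mature/star pairs are called by the 2-nt 3'
    overhang rule with an isomiR* fallback, optionally filtered for AGO
    enrichment (1 RPM, 3x control). Includes a degradome end-support profiler
    for known precursors, a seeded synthetic-data generator (planted hairpins,
    Dicer-end scars, isomiR clouds, AGO/control pairs), and a checkpointed,
    resumable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
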
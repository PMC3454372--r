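Package: orfstat
Title: Analytical ORF Length Statistics for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Models the length distribution of open reading frames (ORFs) in
    bacterial genomes as a six-component geometric mixture whose parameters
    are derived analytically from codon usage. Per-reading-frame start and
    stop codon probabilities are obtained directly from the usage for the
    annotated frame and its antiparallel in-register frame, and from the
    stationary distributions of 64-state frame-shift Markov chains for the
    remaining four frames. Includes a six-frame ORF scanner under the
    longest-ORF-per-stop definition, an IID-codon random genome simulator
    ('Rcodon'), survival probabilities for exceptionally long ORFs, predicted
    gene counts, and a screening pipeline for overlapping ('shadow') gene
    candidates in alternative reading frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
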
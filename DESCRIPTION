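Package: wwpcr
Title: Wristwatch PCR Genome Walking: Primer Design and In Silico Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wristwatch PCR (WW-PCR) genome walking. Designs and
    validates sets of wristwatch primers (25-nt walking primers sharing a
    12-nt 5' part and a 3-nt 3' part around mutually mismatched 10-nt
    spacers) together with nested gene-specific primers, using
    nearest-neighbor melting-temperature thermodynamics with an
    internal-loop model for the bipartite "wristwatch" duplex. Simulates
    the three-round staged-stringency walking PCR on arbitrary templates,
    enumerating the single-stranded and double-stranded product species,
    classifying them as target or type I/II/III background, and predicting
    the final band pattern. Includes a seeded synthetic-fixture generator
    with planted annealing sites and ground-truth amplicons, FASTA/TSV/BED
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
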
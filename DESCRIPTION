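Package: blastxy
Title: Project and Visualize Large-Scale BLAST Results on a Fixed 0-360 Replicon Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects BLAST hits against multi-replicon bacterial and archaeal
    genomes onto a fixed 0-360 relative-coordinate axis (one horizontal track
    per replicon) so that very large result sets can be browsed at once.
    Parses standard BLAST tabular output (outfmt 6/7) and GFF3 annotation,
    encodes gene origin, transcription sense, gene length, aligned span and
    bit score graphically, supports spreadsheet-style sorting, substring
    filtering, display and export caps, and proximity clustering for
    gene-cluster browsing. Includes a deterministic synthetic genome and hit
    simulator for fixtures, static SVG and self-contained interactive HTML
    renderers, and a job runner that writes the full output bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
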
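Package: spellpeg
Title: Prime Editing pegRNA Design with Reduced Spacer-PBS Complementarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation toolkit for prime editing guide RNAs
    (pegRNAs) that weaken the inhibitory intramolecular complementarity
    between the spacer and the primer binding site (PBS). Implements the
    SPELL strategy (a fixed 17-20 nt PBS carrying a single-nucleotide
    deletion), spacer and PBS mismatch/deletion/scramble variant
    generation with an explicit complementarity register model,
    nearest-neighbor PBS:non-target-strand duplex thermodynamics, Golden
    Gate linker and T7 in vitro transcription oligo design, a
    deterministic synthetic amplicon read simulator, and windowed
    edit/indel quantification of amplicon sequencing reads with
    background subtraction, transfection normalization and gene-specific
    demultiplexing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
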
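Package: phagesift
Title: Subtractive Recovery of Viral Sequences from Mixed Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-stage subtractive pipeline for pulling covert viral
    reads out of mixed (host + virus) whole-genome sequencing datasets.
    Stage 1 builds a "background genome" from annotated non-target genomes,
    replacing coding regions annotated as phage or viral in origin with Ns so
    that prophage sequence cannot absorb viral reads. Stage 2 maps reads to
    the background with a mismatch-tolerant seed-and-extend mapper (or
    imports verdicts from an external mapper via SAM) and discards reads that
    resemble the background, at pair or single-read granularity. Stage 3
    assembles the surviving reads with a de Bruijn assembler and reports
    contig statistics (count, maximum length, N50, total bp). Includes a
    seeded simulator that generates a host genome carrying an annotated
    prophage plus a free phage, with truth-labelled error-bearing paired-end
    reads, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
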
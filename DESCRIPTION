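Package: spba
Title: Statistical Principle-Based Recognition and Normalization of
    microRNA Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognizes microRNA (miRNA) mentions in scientific text and
    grounds them to Rfam family accessions using a statistical
    principle-based approach. Slot-sequence "principles" describing miRNA
    surface forms are induced from a span-annotated corpus and summarized
    with a greedy dominating-set approximation; candidate spans are scored
    with an insertion/deletion-tolerant alignment whose matched-slot gains
    and insertion/deletion penalties are estimated from corpus statistics;
    accepted mentions are normalized through a slot-indexed lexicon
    compiled from the Rfam family table. Includes a synthetic corpus
    generator, standoff and BioC corpus readers, strict-span
    micro-averaged evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
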
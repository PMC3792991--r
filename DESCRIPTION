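Package: sdabkit
Title: Design and Quality Control of Synthetic Single-Domain Antibody
    Phage-Display Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering the coding sequence of a single-domain
    antibody (dAb) scaffold with silent (synonymous) unique restriction
    sites, designing per-position amino-acid frequency tables for
    trinucleotide ("trimer") CDR randomization, computing combinatorial
    library statistics (clone probabilities, theoretical diversity,
    coverage, functional library size, display level, absorbance-based
    phage titer), simulating library construction, QC sequencing and
    panning enrichment, and fitting circular-dichroism thermal melts and
    1:1 isothermal titration calorimetry binding isotherms.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
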
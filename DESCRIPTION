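Package: siRNAscreen
Title: Simulation and Profiling of dsRNA-Derived siRNA Libraries with
    Screens for Secondary Amplification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing small interfering RNAs (siRNAs)
    produced from an injected double-stranded RNA trigger in small-RNA
    sequencing libraries. Reads are collapsed, length-filtered and
    assigned by exact matching to spike-ins, mature miRNAs, a genome
    proxy and the target transgene in a genome-subtractive order;
    per-library metrics include spike-in and RPM normalization, size
    distributions, strand-resolved coverage, Dicer phasing registers
    modulo 20/21 and positional nucleotide composition. Three screens
    test for secondary-siRNA amplification (upstream-mapping reads from
    a half-length trigger, a 5'-triphosphate RppH library contrast, and
    a size-distribution shift) plus an Argonaute-loading enrichment
    comparison. A parametric dicing simulator generates replicate
    libraries with per-read ground truth (hotspot initiation, strand
    selection, optional phased processing, optional triphosphate
    secondary species, miRNA background, spike-ins, decoy noise and
    multinomial sequencing) so every stage is verifiable. Companion
    quantitative analyses cover comparative-Ct (2^-ddCt) fold changes,
    western-band double normalization, fluorescence summaries, a miRNA
    count filter, and the associated statistical test battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
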
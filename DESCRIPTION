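Package: asmrescue
Title: Assembly Completeness Forensics and Targeted Correction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diagnostic and corrective toolkit for de novo genome assemblies
    built from short reads, long reads, or both. Cross-tabulates BUSCO
    (Benchmarking Universal Single-Copy Ortholog) classifications across
    alternative assemblies of the same genome, identifies fragmented genes
    that are complete elsewhere, and translocates the complete copies into a
    focal assembly by unique, collinear k-mer anchoring of donor flanking
    sequence, replacing the enclosing contig(s). Also provides seeded,
    length-windowed subsampling of long reads to a target coverage;
    overlap/non-overlap (OVL/n-OVL) merge-decision diagnostics for hybrid
    assembly merging, including detection of BUSCO duplications caused by
    merge failure; classification of scaffold gap fates (closed, partially
    filled, overfilled, unresolved) after long-read gap filling; scaffold
    segmentation, splitting and contiguity statistics (N50, Ns per 100 kb);
    and a fully seeded synthetic-data generator producing toy genomes with
    repeat families, assembly pairs with planted rescuable genes, planted
    gap fates, merge/duplication scenarios and simulated long reads with
    ground-truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
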
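Package: genecap
Title: Gene Model Reconstruction from Targeted Sequence Capture Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs exon/intron gene models for species without a reference
    genome from assemblies of hybridization-capture sequencing data. Contigs are
    aligned to full-length seed transcripts (cDNAs), assigned to genes, clustered,
    and tiled into candidate gene models that are scored by recovery percentage,
    exon-level overlap and fragmentation index; the best model per gene is selected
    and exported as GFF3 with per-contig evidence features. Companion tools design
    120-mer capture probes with denser tiling over the first third of each
    transcript, extract promoter-proximal upstream sequence carried by contigs that
    reach past the first exon, annotate exon/intron structure of genomic sequence
    by spliced comparison against its transcript, and compare structures across
    genes and species. A deterministic simulator generates synthetic multi-exon
    genes and capture contigs (exon fragments, junction-spanning fragments,
    intronless pseudogene copies, tandem repeats, upstream flanks) with full ground
    truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
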
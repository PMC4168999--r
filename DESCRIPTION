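Package: ciliaprint
Title: Ciliary Motility Fingerprints, Splice-Acceptor Consequences and
    Orthologue Co-Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating and interpreting candidate motile-cilia
    genes. Scans upstream regulatory regions for the degenerate RFX (X-box)
    and forkhead (FOX) consensus motifs that mark the ciliary motility
    transcriptional programme, including two-half-site motifs with a
    variable-length spacer, and summarises their conservation across
    orthologous promoters. Predicts the transcript- and protein-level
    consequence of splice-acceptor substitutions via cryptic-acceptor usage,
    with HGVS frameshift nomenclature and predicted mass shifts. Profiles
    gene/marker co-conservation across proteomes by reciprocal-best-hit
    orthology, and provides the supporting exact statistics (two-sided
    Fisher exact tests on 2x2 ultrastructure counts, rare-allele exclusion
    power). Seeded generators produce synthetic promoter sets, mini-genes,
    proteomes and count tables with machine-readable ground truth so every
    stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
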
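Package: elfscan
Title: Motif Scanning and Interface Analysis for Miro ELF-Pocket Client Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization pipeline for client proteins that bind
    the conserved hydrophobic ELF pocket of the mitochondrial Miro GTPases.
    Provides proteome scanning for short F/L-anchored binding motifs with
    sequence-context classification (nearby acidic residue, preceding glycine,
    predicted disorder), per-residue conservation scoring from multiple sequence
    alignments with top-N homolog selection and presence/absence co-occurrence
    statistics, geometric featurization of predicted two-chain complexes
    (side-chain burial by solvent-accessible surface area, side-chain and
    backbone-oxygen salt bridges, inter-chain beta-strand pairing, hydrophobicity
    and per-residue confidence tracks, Ramachandran region classification),
    quantification statistics for two-channel fluorescence images (mitochondrial
    enrichment ratio, punctum enrichment, crop coefficient of variation) and
    fluorescence yeast-two-hybrid plates, plus ground-truthed synthetic-data
    generators for every stage and a tiered candidate-ranking step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
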
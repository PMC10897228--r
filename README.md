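# elfscan

Miro GTPases (MIRO1/2 in human, Gem1 in yeast) sit on the outer
mitochondrial membrane and recruit a remarkably diverse set of client
proteins — trafficking adaptors (Trak1/2, CENPF, MYO19), lipid-transport
machinery (Mdm34 of ERMES, VPS13D), morphology factors (MTFR1/2/1L) and the
mitophagy ligase Parkin — through a single conserved hydrophobic pocket
(the **ELF pocket**) in Miro's first EF-hand/LM domain. Clients contribute a
phenylalanine or leucine from a short motif in a disordered loop; binding is
often reinforced by a salt bridge to a conserved arginine and by a client
β-strand pairing antiparallel with Miro's first GTPase domain.

`elfscan` is the computational pipeline for discovering and characterizing
such clients, for structural bioinformaticians and cell biologists working
on mitochondrial homeostasis:

* **Motif scanning** — literal (e.g. `FADI`) or F/L-anchored scans of a
  proteome FASTA, each hit classified against the binding-motif criteria:
  acidic residue within ±5 of the anchor, preceding glycine, anchor in
  predicted disorder (pLDDT < 50).
* **Conservation** — per-residue Jensen–Shannon conservation of a reference
  sequence from an MSA (top-1000-homolog selection supported), normalized to
  [0, 1]; plus the presence/absence co-occurrence statistic (agreement
  fraction and φ) used to argue co-evolution of motif modules across species.
* **Interface featurization** — from a predicted two-chain complex (PDB or
  mmCIF, pLDDT in the B-factor field): side-chain burial by Shrake–Rupley
  SASA with `inserted = ΔSASA_rel ≥ 0.7`, side-chain and backbone-oxygen
  salt bridges (N–O ≤ 4 Å), geometric inter-chain β-ladders (N···O ≤ 3.5 Å,
  Cα–Cα ≤ 5.5 Å, consecutive registry), Kyte–Doolittle hydrophobicity,
  low-confidence flags, Ramachandran region labels.
* **Validation statistics** — mitochondrial enrichment ratio
  (mean on-mask / mean rest-of-cell), punctum enrichment (integrated density
  fraction), 8 μm² crop coefficient of variation, and f-Y2H plate
  normalization `(raw − empty) / mean(background-subtracted wells)`.
* **Synthetic generators** — proteomes with planted motifs, MSAs with
  controlled per-column substitution rates, idealized complexes with planted
  bridges/ladders/insertions, two-channel cell images with known enrichment,
  and f-Y2H plates — each returning its ground truth, so every detector is
  tested against construction.
* **Ranking** — tier A (conserved + disordered anchor), B (one extra
  criterion), C (motif only); no invented composite score.

## Worked example

```r
library(elfscan)

# a 100-protein synthetic proteome with 5 planted FADI motifs
g <- gen_proteome(100, "FADI", 5, seed = 1)
hits <- scan_proteome(g$records, motif_pattern(literal = "FADI"))
head(hits, 2)
#>   protein_id anchor_pos anchor_res     context acidic_nearby acidic_pos gly_preceding disordered
#> 1   prot0007        100          F QITPQFADITC          TRUE        102         FALSE         NA
#> 2   prot0020        283          F CTVNMFADIWN          TRUE        285         FALSE         NA
n_proteins_hit(hits)
#> [1] 5
```

Each row is one candidate anchor: `acidic_pos = anchor + 2` is the aspartate
of the FADx motif; `disordered` stays `NA` until a disorder track is
attached. All five planted proteins (and no decoys) are recovered.

```r
# a toy complex with a planted salt bridge, antiparallel ladder and insertion
fx <- gen_complex_fixture(c("salt_bridge", "beta_antiparallel", "insertion"),
                          seed = 1)
interface_report(fx$model, "B", "A")
#> <interface_report> client B vs receptor A
#>   contact residues: 6 client / 81 receptor
#>   inserted side chains: 1; salt bridges: 1; beta pairings: 1
```

The report finds exactly the planted features: an Arg–Asp side-chain bridge
at 2.98 Å, one antiparallel β-ladder with the constructed registry, and the
caged Phe side chain called inserted (side-chain SASA 173.6 Å² alone →
16.2 Å² in complex).

```r
# imaging: planted 3-fold mitochondrial enrichment, Poisson noise
img <- gen_cell_image(enrichment = 3, noise = "poisson", seed = 1)
mito_enrichment_ratio(img$client, img$mito_mask, img$cell_mask)
#> <mito_enrichment_ratio> value = 3.0023 (on: 300.7, off: 100.1)

# f-Y2H normalization, worked plate: raw [4, 6], empty 2
p <- plate_table(c("ev", "a", "a"), c(1, 1, 2), c(2, 4, 6),
                 c(TRUE, FALSE, FALSE))
round(normalize_fy2h(p)$wells$normalized, 3)
#> [1] 0.000 0.667 1.333
```

The enrichment estimate recovers the planted factor within noise; the plate
normalization maps the empty-vector well to 0 and fixes the mean of
non-empty wells at 1.

To scan a real proteome (e.g. the MitoCarta3.0 inventory), point the scanner
at its FASTA:

```r
prots <- read_proteins("Human.MitoCarta3.0.fasta")
hits <- scan_proteome(prots, motif_pattern(literal = "FADI"))
n_proteins_hit(hits)   # distinct proteins carrying the motif
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end-to-end on seed-derived
synthetic inputs — proteome scan and ranking, graded-rate conservation,
interface featurization of a planted complex, imaging enrichment recovery,
and plate normalization — logging each stage's result, and writes the JSON
report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/motif.R`, `R/proteins.R` — records, FASTA/disorder I/O, scanning.
* `R/conservation.R` — alignments, JSD conservation, co-occurrence.
* `R/structure-io.R`, `R/sasa.R`, `R/interface.R`, `R/ramachandran.R` —
  structure parsing/writing and interface featurization.
* `R/imaging.R`, `R/y2h.R` — image and plate statistics.
* `R/synthetic.R` — ground-truthed generators.
* `R/rank.R` — tiered candidate table.
* `vignettes/elf-pocket-pipeline.Rmd` — the model, parameter choices and
  their rationale, what the synthetic world does and does not establish.
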
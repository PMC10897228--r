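---
title: "Discovering Miro ELF-pocket clients: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Miro ELF-pocket clients: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elfscan)
```

## The biological problem

Miro proteins (MIRO1/2 in human, Gem1 in budding yeast) are outer-
mitochondrial-membrane Ca^2+^-binding GTPases that recruit functionally
diverse client proteins — cytoskeletal adaptors (Trak1/2, CENPF, MYO19),
lipid-transport machinery (the yeast ERMES subunit Mdm34, metazoan VPS13D),
mitochondrial-morphology factors (MTFR1/2/1L) and the mitophagy E3 ligase
Parkin. These clients share one binding mechanism: a short linear motif in a
disordered region contributes a phenylalanine or leucine side chain that
inserts into a conserved hydrophobic pocket in Miro's first EF-hand/LM
domain (the *ELF pocket*), often accompanied by a salt bridge to a conserved
arginine and by a client β-strand that pairs antiparallel with a strand of
Miro's first GTPase domain.

`elfscan` implements the computational side of discovering and
characterizing such clients:

1. **Motif scanning** of a proteome for F/L-anchored candidate motifs, with
   context classification (nearby acidic residue, preceding glycine,
   predicted disorder).
2. **Conservation mapping** from a multiple sequence alignment, with
   top-N homolog selection and a presence/absence co-occurrence statistic.
3. **Structural interface featurization** of predicted two-chain complexes:
   side-chain burial by solvent-accessible surface area (SASA), side-chain
   and backbone-oxygen salt bridges, inter-chain β-ladders, hydrophobicity
   and per-residue confidence tracks, Ramachandran classification.
4. **Quantification statistics** for validation experiments: mitochondrial
   enrichment ratio, punctum enrichment, crop coefficient of variation, and
   fluorescence-Y2H plate normalization.
5. **Synthetic-data generators** with recorded ground truth for every stage,
   so each detector can be tested against construction rather than against
   itself.
6. **Tiered candidate ranking** combining the evidence.

## Motif model

The binding-motif criteria are deliberately weak — the motif is short and
divergent, and a literal search is neither sensitive nor specific. The
scanner therefore reports *candidates with evidence flags*, not calls:

* **Anchor** (`anchor_set`, default `F`,`L`): the residue that inserts into
  the pocket. `X` and non-standard letters never match.
* **Acidic context** (`window`, default ±5 residues): a D/E near the anchor.
  The default window covers the aspartate two residues downstream in
  FADx-type motifs and a glutamate six residues downstream of the anchor in
  MYO19-type motifs. Nearest-acidic ties break downstream (C-terminal) —
  a documented, biologically arbitrary choice.
* **Preceding glycine**: glycine immediately N-terminal of the anchor;
  glycine's unique backbone freedom matters for entering/exiting the pocket
  in some clients.
* **Disorder** (`disorder_threshold`, default 50): anchors in predicted
  disordered loops. Scores follow the pLDDT convention (0–100, low =
  disordered), so AlphaFold per-residue confidence can be used directly.

Coordinates are 1-based residue indices throughout, so reported positions
read like the literature (F2989, L2554, L119). Whether a scanned proteome
contains canonical or isoform-inclusive sequences is the caller's choice —
the scanner takes whatever FASTA it is given.

## Conservation scoring

No published scheme is attached to the conservation surfaces this package
emulates, so a standard, bounded, symmetric choice is used: per alignment
column, the Jensen–Shannon divergence between the column's residue
distribution and a background distribution (uniform by default, BLOSUM62
marginals optional), normalized by the largest divergence achievable by a
single-residue column. Under the uniform background a fully conserved
column scores exactly 1 and a background-like column 0; under non-uniform
backgrounds fully conserved columns of common residues can score slightly
below 1 (documented behaviour of the normalization).

Gaps are excluded from column distributions; columns with gap fraction
above 0.5 are flagged low-coverage; columns where the reference row is
gapped are skipped so the track aligns 1:1 with the ungapped reference.
Duplicate rows count — no reweighting is attempted.

`select_top_homologs()` mirrors conservation mapping over the "top 1000"
homologs of a human reference: rows are ranked by percent identity to the
reference over mutually ungapped columns (the ranking metric is
configurable, since the original is unstated), ties at the cutoff break by
input order, and the function warns rather than errors when fewer rows are
available. Whether redundant sequences should be collapsed first is
likewise unstated in the original procedure; the function does not collapse
and says so here rather than guessing.

`cooccurrence()` quantifies the co-evolution argument — two motif modules
being present/absent simultaneously across species — as the agreement
fraction (equal to 1 − normalized Hamming distance, which the tests verify
against that oracle) plus the φ coefficient of the 2×2 table, reported as
undefined when a margin is zero.

## Interface featurization

* **SASA** is Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (960 points per atom by default, probe 1.4 Å), Bondi van-der-Waals radii,
  waters and hetero records excluded. The single-sphere case is exact
  (every lattice point accessible gives 4π(r+p)² identically); overlapping
  cases converge at the ~0.1% level against the analytic two-sphere area.
  Because the lattice is fixed in the laboratory frame, areas are
  rotation-invariant only up to sampling error; boolean calls derived from
  them (insertion) are far from their thresholds on real margins and are
  tested to be isometry-stable.
* **Insertion** (`delta_sasa_insertion()`): side-chain SASA of a client
  residue with its own chain alone versus in complex. The relative burial
  divides the drop by a maximal-exposure reference per residue type (a
  published theoretical maximum-ASA table with the glycine value subtracted
  as a backbone proxy — approximate, clamped to [0, 1]). "Inserted" means
  relative burial ≥ 0.7: an operationalization of "inserts extensively",
  flagged as such since the original call was visual. Glycine itself has no
  side chain; its Cα is used as a proxy and the result flagged.
* **Salt bridges** (`detect_salt_bridges()`): Arg NH1/NH2/NE or Lys NZ
  within 4.0 Å of Asp/Glu carboxylate oxygens (side-chain kind) or of a
  backbone carbonyl O (backbone-oxygen kind) across the chain pair. The
  cutoff is a common structural-biology convention — none is stated in the
  source observations. Histidine is excluded by default (protonation
  unknown); both are configurable. Results deduplicate per residue pair and
  kind, keep the minimum distance, and are symmetric in chain order.
* **β-ladders** (`detect_interchain_beta_pairs()`): a purely geometric
  criterion rather than DSSP energetics, because it is fully specified and
  oracle-testable: backbone N···O ≤ 3.5 Å with the donor nitrogen on the
  carbonyl side (C–O···N angle ≥ 90°), paired Cα–Cα ≤ 5.5 Å, runs of
  consecutive pairs stepping (i+1, j∓1), minimum run length 2. Orientation
  comes from the strand direction vectors taken along each chain's own
  residue order (negative dot product = antiparallel).
* **Confidence**: per-residue pLDDT is read from the B-factor field
  (AlphaFold convention); interface residues below 70 are flagged
  low-confidence. The threshold mirrors the usual AlphaFold
  confident/low-confidence boundary since the original figures color by
  confidence without stating a cutoff.
* **Ramachandran classes**: the published high-resolution density tables
  are not redistributable with this package, so classification uses a
  *synthetic stand-in density* — mixtures of wrapped Gaussians on the
  canonical basins per residue class (general, glycine, proline,
  pre-proline), thresholded at fixed fractions of the peak. It reproduces
  the qualitative behaviour the labels are used for (α and β cores favored;
  the left-handed region tolerated by glycine but an outlier for general
  residues) and is documented as synthetic wherever it appears.

Structure I/O is a minimal hand-rolled PDB/mmCIF reader-writer pair
(no installed R package parses these formats): fixed-column PDB and
`_atom_site` mmCIF, author numbering preserved, highest-occupancy altloc
kept, all-zero-coordinate atoms parsed but flagged. The two dialects are
tested to parse to field-identical models.

## Imaging statistics

All three statistics operate on plain numeric matrices with a pixel size in
μm/pixel (no TIFF reader exists in this R environment; a TSV text format is
provided for exchange, and the generators return matrices directly).

* **Mitochondrial enrichment**: mean client intensity over a thresholded
  marker mask divided by the mean over the rest of the cell. The marker
  mask always comes from the marker channel, never the client channel
  (avoids circularity). Otsu is the default threshold; constant images
  error with a pointer to manual thresholds.
* **Punctum enrichment**: integrated client density over puncta divided by
  integrated density over the whole cell — a fraction in [0, 1] that equals
  the punctum area fraction for uniform signal.
* **Crop CoV heterogeneity**: population standard deviation over mean in a
  square crop of fixed physical area (default 8 μm²). Population (N) SD is
  used so toy examples are exact; the crop side is
  `floor(sqrt(area)/pixel_size)` pixels (minimum 2) since the original
  fixes the area but not the pixel rounding. Crops are explicit caller
  inputs — the original's manual exclusion of perinuclear signal is a crop
  choice, not an algorithm, and is not automated here. No background
  subtraction is applied by default.

## f-Y2H normalization

Per well: raw fluorescence minus the mean empty-vector signal, divided by a
plate mean. The stated formula ("divided by mean signal over all wells")
is ambiguous about whether empty-vector wells enter the divisor; the
default here divides by the mean background-subtracted *non-empty* well,
which makes the statistic dimensionless, maps empty wells to ≈0 and fixes
the mean of normalized non-empty wells at exactly 1 (a tested identity).
The literal all-wells divisor is available via `divisor = "all"`.
Replicate summaries report mean ± SEM with n−1 SD over clones (n = 3 in the
emulated design). A plate whose wells are indistinguishable from the
empty-vector control fails with a diagnostic rather than returning noise.

## The synthetic world

The generators state the world the tests live in; their defaults are fixed
choices, not dials:

* `gen_proteome()`: 100 proteins of 300–600 residues from a uniform residue
  background (Swiss-Prot-like frequencies optional), literal motifs
  rejected from decoys by resampling, 5 planted carriers by default —
  mirroring the five-candidate scale of the original proteome scan.
* `gen_msa()`: homologs are the reference with i.i.d. per-column
  substitutions at stated rates, replacement uniform over all 20 residues
  (so rate 1 is exactly background), no indels by default.
* `gen_complex_fixture()`: idealized internal-coordinate geometry (bond
  lengths 1.33–1.52 Å, planted N–O distances, β-ladders built so every
  intended backbone hydrogen bond is at 2.90 Å and no unintended pair is
  within the cutoff), one feature per isolated 40 Å block, pLDDT written to
  the B-factor field, a seed-derived global rigid transform plus ±0.05 Å
  jitter. No energy minimization — the detectors are geometric, so
  idealized geometry is sufficient and keeps ground truth exact.
* `gen_cell_image()`: tubular mitochondria as dilated random-walk curves
  (or yeast-style punctum disks), client = baseline × enrichment on the
  structure with Poisson counting noise at a baseline of 100 counts;
  128×128 px at 0.1 μm/px, a typical 100×/EM-CCD scale.
* `gen_plate()`: Gaussian well noise (SD 20 on effects of ~100–1250) around
  a charge-swap design preset (wild-type pair high, single charge mutants
  low, double swap rescued).

Every generator is a pure function of its parameters and seed: reruns are
byte-identical and the caller's RNG stream is untouched.

What a green test does *not* establish: the generators do not mimic real
AlphaFold error modes, microscope point-spread functions, segmentation
error, or alignment uncertainty. Detector correctness is established
against constructed ground truth; performance on real models and images
inherits those upstream uncertainties.

## Candidate ranking

Tiers express the evidence honestly without inventing weights the source
does not provide: tier A = anchor conserved (score ≥ 0.8, i.e.
near-invariant) *and* disordered; tier B = at least one extra criterion
(conserved, disordered, or a structural insertion) but not both of the
first two; tier C = motif only. Adding evidence can only raise a tier
(a tested monotonicity property). Ordering is (tier, anchor conservation
descending, protein id) — a total order, so reruns are identical. The
final triage of candidates (which ones a structure predictor supports) is
left human-in-the-loop, as in the original study.

## Known limitations

* The burial reference table is a side-chain proxy (total minus glycine);
  relative burial is comparable within the package, not against other
  SASA software.
* The Ramachandran density is a synthetic stand-in, not the published
  empirical tables; region labels agree qualitatively, contour levels do
  not correspond to the published 98%/99.95% coverage definitions.
* The β-ladder criterion requires consecutive registry steps and complete
  N/Cα/C/O backbones; sheets with β-bulges or missing atoms are reported
  as split or shorter runs.
* The MitoCarta3.0 scan itself needs the external FASTA inventory; the
  package ships the scanner and the test, not the database.
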
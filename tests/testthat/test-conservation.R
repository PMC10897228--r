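test_that("fully conserved columns score 1, background-like columns 0", {
  aln <- msa_alignment(c("REF", "h1", "h2"),
                       rep(strrep("F", 10), 3), "REF")
  tr <- column_conservation(aln)
  expect_equal(tr$score, rep(1, 10))
  expect_equal(tr$ref_res, rep("F", 10))

  # column distribution exactly uniform over the 20 residues -> score 0
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aln2 <- msa_alignment(c("REF", paste0("h", 1:19)), aas, "REF")
  tr2 <- column_conservation(aln2)
  expect_lt(abs(tr2$score), 1e-12)
})

test_that("reference-gap columns are skipped; gaps excluded from distributions", {
  aln <- msa_alignment(c("REF", "h1", "h2", "h3"),
                       c("A-CD", "AAC-", "A-CD", "A---"), "REF")
  tr <- column_conservation(aln)
  expect_equal(nrow(tr), 3L)                # ref has 3 ungapped positions
  expect_equal(tr$ref_res, c("A", "C", "D"))
  expect_equal(tr$score[1], 1)              # all-A column
  # column 4 (ref D): rows D, -, D, - -> gap fraction 0.5, all-D among observed
  expect_equal(tr$gap_fraction[3], 0.5)
  expect_equal(tr$score[3], 1)
  expect_false(tr$low_coverage[3])          # flagged only above 0.5
  expect_error(column_conservation(msa_alignment("R", "", "R")), "empty")
})

test_that("conservation is a column-wise statistic, invariant to row order", {
  g <- gen_msa(strrep("ACDEFGHIKL", 4), n_rows = 30,
               per_column_rate = runif(40), seed = 5)
  aln <- g$alignment
  tr <- column_conservation(aln)
  perm <- sample(length(aln$ids))
  tr2 <- column_conservation(msa_alignment(aln$ids[perm], aln$seqs[perm],
                                           "REF"))
  expect_equal(tr2$score, tr$score)
  # shuffling residues within each column leaves scores unchanged
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  ref_i <- match("REF", aln$ids)
  set.seed(1)
  for (j in seq_len(ncol(m))) {
    others <- setdiff(seq_len(nrow(m)), ref_i)
    m[others, j] <- sample(m[others, j])
  }
  shuf <- msa_alignment(aln$ids, apply(m, 1, paste, collapse = ""), "REF")
  expect_equal(column_conservation(shuf)$score, tr$score)
})

test_that("conservation decreases with planted substitution rate", {
  g <- gen_msa(paste(rep("A", 120), collapse = ""), n_rows = 150,
               per_column_rate = seq(0, 0.9, length.out = 120), seed = 7)
  tr <- column_conservation(g$alignment)
  rho <- cor(g$ground_truth$per_column_rate, tr$score, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("map_to_reference bounds-checks 1-based positions", {
  g <- gen_msa(strrep("ACDEFGHIKL", 1), n_rows = 5, per_column_rate = 0,
               seed = 1)
  tr <- column_conservation(g$alignment)
  expect_equal(map_to_reference(tr, 1), tr$score[1])
  expect_equal(map_to_reference(tr, 10), tr$score[10])
  expect_error(map_to_reference(tr, 0), "range")
  expect_error(map_to_reference(tr, 11), "range")
})

test_that("top-homolog selection ranks by identity to the reference", {
  ref <- strrep("A", 20)
  near <- paste(c(rep("A", 18), "C", "C"), collapse = "")
  mid <- paste(c(rep("A", 10), rep("C", 10)), collapse = "")
  far <- strrep("C", 20)
  aln <- msa_alignment(c("REF", "far", "near", "mid"),
                       c(ref, far, near, mid), "REF")
  sel <- select_top_homologs(aln, 2)
  expect_equal(sel$ids, c("REF", "near", "mid"))
  # clamp + warning when fewer homologs than requested
  expect_warning(sel2 <- select_top_homologs(aln, 1000), "only 3")
  expect_equal(length(sel2$ids), 4L)
  # ties at the cutoff broken by input order
  aln3 <- msa_alignment(c("REF", "t1", "t2"), c(ref, near, near), "REF")
  expect_equal(select_top_homologs(aln3, 1)$ids, c("REF", "t1"))
  expect_error(select_top_homologs(aln, 0), "positive")
})

test_that("alignment readers handle aligned FASTA and Stockholm", {
  f <- tmp_file(".fasta")
  writeLines(c(">REF", "AC-D", ">h1", "ACAD"), f)
  a <- read_alignment(f, "REF")
  expect_equal(a$seqs, c("AC-D", "ACAD"))
  s <- tmp_file(".sto")
  writeLines(c("# STOCKHOLM 1.0", "REF AC-D", "h1  ACAD", "", "REF AAAA",
               "h1  AA-A", "//"), s)
  b <- read_alignment(s)
  expect_equal(b$ids, c("REF", "h1"))
  expect_equal(b$seqs, c("AC-DAAAA", "ACADAA-A"))
})

test_that("co-occurrence agreement equals 1 - normalized Hamming distance", {
  expect_equal(cooccurrence(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))$agreement, 1)
  anti <- cooccurrence(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE))
  expect_equal(anti$agreement, 0)
  expect_equal(anti$phi, -1)
  set.seed(42)
  for (i in 1:20) {
    a <- runif(50) > runif(1, 0.2, 0.8)
    b <- runif(50) > runif(1, 0.2, 0.8)
    cc <- cooccurrence(a, b)
    expect_equal(cc$agreement, 1 - mean(a != b))
  }
  # zero margin: phi undefined but reported as such
  cc0 <- cooccurrence(c(TRUE, TRUE), c(TRUE, FALSE))
  expect_false(cc0$phi_defined)
  expect_true(is.na(cc0$phi))
  expect_error(cooccurrence(TRUE, TRUE), "2 species")
  expect_error(cooccurrence(c(TRUE, TRUE), TRUE), "length")
})

test_that("conservation TSV writer emits per-residue tracks", {
  g <- gen_msa("ACDEF", n_rows = 4, per_column_rate = 0, seed = 2)
  tr <- column_conservation(g$alignment)
  f <- tmp_file(".tsv"); att <- tmp_file(".txt")
  write_conservation_tsv(tr, f, att)
  back <- read.delim(f)
  expect_equal(back$pos, 1:5)
  expect_equal(nrow(back), length(readLines(att)))
})
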
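test_that("literal scan reports every (overlapping) occurrence with 1-based anchors", {
  rec <- protein_record("p", "FADIFADI")
  h <- scan_literal(rec, "FADI")
  expect_equal(h$anchor_pos, c(1L, 5L))
  expect_equal(unique(h$anchor_res), "F")

  expect_equal(nrow(scan_literal(protein_record("q", "AAAA"), "FADI")), 0L)

  one <- scan_literal(protein_record("m", "GGFADIKK"), "FADI")
  expect_equal(one$anchor_pos, 3L)
  expect_equal(one$anchor_res, "F")

  # self-overlapping literal
  h2 <- scan_literal(protein_record("r", "AAAA"), "AA")
  expect_equal(h2$anchor_pos, 1:3)

  expect_error(scan_literal(rec, ""), "non-empty")
})

test_that("literal scan count equals a brute-force substring count", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "F", "D", "I", "L"), 60, replace = TRUE),
               collapse = "")
    for (lit in c("FADI", "FA", "LL", "ADI")) {
      expect_equal(nrow(scan_literal(protein_record("x", s), lit)),
                   brute_count_substr(s, lit), info = paste(s, lit))
    }
  }
})

test_that("anchored scan returns one hit per anchor-set residue", {
  expect_equal(scan_anchored(protein_record("p", "GFADI"))$anchor_pos, 2L)
  expect_equal(nrow(scan_anchored(protein_record("p", "LLLL"))), 4L)
  expect_equal(nrow(scan_anchored(protein_record("p", "GGAADD"))), 0L)
  # property: |hits| == number of residues in anchor set; X never matches
  set.seed(3)
  for (i in 1:15) {
    s <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"),
                      80, replace = TRUE), collapse = "")
    h <- scan_anchored(protein_record("x", s))
    chars <- strsplit(s, "")[[1]]
    expect_equal(nrow(h), sum(chars %in% c("F", "L")))
    expect_true(all(h$anchor_res %in% c("F", "L")))
  }
})

test_that("context classification flags acidic neighbours, glycine, disorder", {
  rec <- protein_record("p", "GGFADIKK")
  h <- classify_context(scan_literal(rec, "FADI"), rec)
  expect_true(h$acidic_nearby)
  expect_equal(h$acidic_pos, h$anchor_pos + 2L)   # the D of FADI
  expect_true(h$gly_preceding)
  expect_true(is.na(h$disordered))                # no disorder track

  # anchor at position 1: no preceding residue
  rec1 <- protein_record("q", "FADI")
  h1 <- classify_context(scan_anchored(rec1), rec1)
  expect_false(h1$gly_preceding[1])

  # no acidic residue within the window
  rec2 <- protein_record("r", "AAFAA")
  h2 <- classify_context(scan_anchored(rec2, motif_pattern(window = 2L)), rec2,
                         motif_pattern(window = 2L))
  expect_false(h2$acidic_nearby)
  expect_true(is.na(h2$acidic_pos))

  # nearest-acidic tie broken downstream; anchor itself excluded
  rec3 <- protein_record("s", "ADFADA")  # D at -1 and +2; E/D tie at same |d|?
  h3 <- classify_context(scan_anchored(rec3), rec3)
  expect_equal(h3$acidic_pos, 2L)        # D at distance 1 upstream is nearest
  rec4 <- protein_record("t", "DFDAA")   # D at -1 and +1: tie -> downstream
  h4 <- classify_context(scan_anchored(rec4), rec4)
  expect_equal(h4$acidic_pos, 3L)

  # disorder threshold: pLDDT < 50 means disordered
  rec5 <- protein_record("u", "AAFAA", disorder = c(90, 90, 30, 90, 90))
  h5 <- classify_context(scan_anchored(rec5), rec5)
  expect_true(h5$disordered)
  rec6 <- protein_record("v", "AAFAA", disorder = rep(80, 5))
  expect_false(classify_context(scan_anchored(rec6), rec6)$disordered)

  # idempotent
  expect_equal(classify_context(h, rec), h)

  # inconsistent anchor errors
  bad <- h; bad$anchor_pos <- 99L
  expect_error(classify_context(bad, rec), "range")
})

test_that("proteome scan concatenates per-protein hits and counts distinct proteins", {
  prots <- list(protein_record("a", "MGSFADIK"),
                protein_record("b", "MKKK"),
                protein_record("c", "MPLQR"))
  h <- scan_proteome(prots, motif_pattern(literal = "FADI"))
  expect_equal(n_proteins_hit(h), 1L)
  expect_equal(h$protein_id, "a")

  # deterministic order: input order then position
  prots2 <- list(protein_record("z", "FADIXXFADI"), protein_record("a", "FADI"))
  h2 <- scan_proteome(prots2, motif_pattern(literal = "FADI"))
  expect_equal(h2$protein_id, c("z", "z", "a"))
  expect_equal(h2$anchor_pos, c(1L, 7L, 1L))

  dup <- list(protein_record("a", "FADI"), protein_record("a", "LADI"))
  expect_error(scan_proteome(dup, motif_pattern(literal = "FADI")), "duplicate.*a")
  expect_error(scan_proteome(list(), motif_pattern()), "non-empty")
})

test_that("hit tables round-trip through TSV", {
  prots <- list(protein_record("a", "MGSFADIK"))
  h <- scan_proteome(prots, motif_pattern(literal = "FADI"))
  f <- tmp_file(".tsv")
  write_hits_tsv(h, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$protein_id, h$protein_id)
  expect_equal(back$anchor_pos, h$anchor_pos)
  expect_equal(back$acidic_pos, h$acidic_pos)
})

test_that("FASTA and disorder TSV I/O preserve records", {
  recs <- list(protein_record("p1", strrep("ACDEFGHIKL", 13)),
               protein_record("p2", "MFADI"))
  f <- tmp_file(".fasta")
  write_proteins(recs, f)
  back <- read_proteins(f)
  expect_equal(names(back), c("p1", "p2"))
  expect_equal(back$p1$sequence, recs[[1]]$sequence)

  d <- tmp_file(".tsv")
  writeLines(c("key\tscore", sprintf("p2:%d\t%d", 1:5, c(90, 30, 30, 20, 90))), d)
  tab <- read_disorder_tsv(d)
  expect_equal(tab$position, 1:5)
  withd <- attach_disorder(back, tab)
  expect_equal(withd$p2$disorder, c(90, 30, 30, 20, 90))
  h <- classify_context(scan_literal(withd$p2, "FADI"), withd$p2)
  expect_true(h$disordered)  # anchor at position 2, pLDDT 30 < 50
})
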
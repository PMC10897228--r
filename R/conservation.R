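# MSA conservation: alignment I/O, top-N homolog selection, per-column
# Jensen-Shannon conservation mapped onto the reference sequence, and the
# presence/absence co-occurrence statistic for motif modules across species.

#' Construct an alignment object
#'
#' @param ids Character vector of row ids.
#' @param seqs Character vector of aligned sequences (gap character `-`),
#'   all the same length.
#' @param reference_id Id of the reference (e.g. human) row; must be present.
#' @return Object of class `msa_alignment`.
#' @export
msa_alignment <- function(ids, seqs, reference_id) {
  if (length(ids) != length(seqs)) stop_invalid("ids and seqs differ in length")
  if (!length(ids)) stop_invalid("empty alignment")
  seqs <- unname(toupper(as.character(seqs)))
  ids <- unname(as.character(ids))
  if (length(unique(nchar(seqs))) != 1L)
    stop_invalid("aligned sequences must all have equal length")
  if (!reference_id %in% ids)
    stop_invalid("reference id '%s' not found among alignment rows", reference_id)
  structure(list(ids = ids, seqs = seqs,
                 reference_id = reference_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d rows x %d columns (reference: %s)\n",
              length(x$ids), nchar(x$seqs[1]), x$reference_id))
  invisible(x)
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' Format is chosen by inspection: files starting with `# STOCKHOLM` use a
#' minimal Stockholm reader, everything else goes through
#' [Biostrings::readAAStringSet()].
#'
#' @param path Alignment file path.
#' @param reference_id Reference row id; defaults to the first row.
#' @return An [msa_alignment].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*STOCKHOLM", first)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(toks, `[[`, character(1), 1L)
    seqs <- vapply(toks, `[[`, character(1), 2L)
    # interleaved Stockholm: concatenate blocks per id, preserving first-seen order
    agg <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
    ids <- names(agg); seqs <- unname(agg)
  } else {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
    seqs <- as.character(aa)
  }
  seqs <- chartr(".", "-", seqs)
  msa_alignment(ids, seqs, reference_id %||% ids[[1L]])
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

#' Percent identity of each row to the reference
#'
#' Identity over columns where both row and reference are ungapped.
#' @param aln An [msa_alignment].
#' @return Numeric vector, one value in `[0, 1]` per row (reference = 1).
#' @export
percent_identity <- function(aln) {
  m <- aln_matrix(aln)
  ref <- m[match(aln$reference_id, aln$ids), ]
  apply(m, 1L, function(row) {
    both <- row != "-" & ref != "-"
    if (!any(both)) return(0)
    mean(row[both] == ref[both])
  })
}

#' Select the top-N homologs most similar to the reference
#'
#' Mirrors conservation mapping done on the "top 1000" homologs of the human
#' protein: rows are ranked by percent identity to the reference (or by a
#' supplied ranking) and the best `n` are kept alongside the reference.
#' Ties at the cutoff are broken by input order (stable sort).
#'
#' @param aln An [msa_alignment].
#' @param n Positive number of homologs to keep (default 1000).
#' @param ranks Optional externally supplied ranking metric (higher = better),
#'   one value per row; defaults to [percent_identity()].
#' @return An [msa_alignment] with the reference first, then the selected
#'   rows. Warns when fewer than `n` homologs are available.
#' @export
select_top_homologs <- function(aln, n = 1000L, ranks = NULL) {
  stopifnot(inherits(aln, "msa_alignment"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop_invalid("n must be a positive integer")
  is_ref <- aln$ids == aln$reference_id
  ranks <- ranks %||% percent_identity(aln)
  if (length(ranks) != length(aln$ids))
    stop_invalid("ranks must have one value per alignment row")
  cand <- which(!is_ref)
  ord <- cand[order(-ranks[cand])]  # stable: ties keep input order
  if (length(ord) < n)
    warning(sprintf("only %d homologs available (requested %d)", length(ord), n))
  keep <- ord[seq_len(min(n, length(ord)))]
  sel <- sort(keep)  # keep input order among the selected rows
  msa_alignment(c(aln$reference_id, aln$ids[sel]),
                c(aln$seqs[is_ref][1L], aln$seqs[sel]),
                aln$reference_id)
}

js_divergence <- function(p, q) {
  # Jensen-Shannon divergence in bits; 0 <= JSD <= 1
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Background residue distributions
#'
#' `"uniform"` is flat over the 20 standard residues; `"blosum62"` uses the
#' marginal residue frequencies underlying the BLOSUM62 matrix (Henikoff &
#' Henikoff 1992).
#' @param name `"uniform"` or `"blosum62"`, or a named numeric vector summing
#'   to 1 over the 20 residues.
#' @return Named probability vector over [AA_ALPHABET].
#' @export
aa_background <- function(name = c("uniform", "blosum62")) {
  if (is.numeric(name)) {
    p <- name[AA_ALPHABET]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-6)
      stop_invalid("custom background must cover all 20 residues and sum to 1")
    return(p)
  }
  name <- match.arg(name)
  if (name == "uniform")
    return(stats::setNames(rep(1 / 20, 20), AA_ALPHABET))
  b <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  (b / sum(b))[AA_ALPHABET]
}

#' Per-residue conservation of the reference sequence
#'
#' For every alignment column where the reference row is ungapped, scores the
#' column's residue distribution (gaps and non-standard letters excluded)
#' against a background distribution using Jensen-Shannon divergence,
#' normalized so a fully conserved column scores 1 under the uniform
#' background; a column indistinguishable from background scores 0.
#' Duplicate rows count (no reweighting). Columns with gap fraction above
#' `low_coverage` are flagged.
#'
#' @param aln An [msa_alignment].
#' @param background See [aa_background()].
#' @param low_coverage Gap-fraction threshold for the low-coverage flag
#'   (default 0.5).
#' @return Object of class `conservation_track`: data.frame with columns
#'   `pos` (1-based ungapped reference position), `ref_res`, `score`,
#'   `gap_fraction`, `low_coverage`, plus attribute `reference_id`.
#' @export
column_conservation <- function(aln, background = "uniform", low_coverage = 0.5) {
  stopifnot(inherits(aln, "msa_alignment"))
  m <- aln_matrix(aln)
  if (!nrow(m) || !ncol(m)) stop_invalid("empty alignment")
  bg <- aa_background(background)
  # normalizer: largest JSD achievable by a single-residue column
  jsd_max <- max(vapply(AA_ALPHABET, function(a) {
    p <- stats::setNames(numeric(20), AA_ALPHABET); p[a] <- 1
    js_divergence(p, bg)
  }, numeric(1)))
  ref_row <- m[match(aln$reference_id, aln$ids), ]
  cols <- which(ref_row != "-")
  res <- vapply(cols, function(j) {
    col <- m[, j]
    gap_frac <- mean(col == "-")
    obs <- col[col %in% AA_ALPHABET]
    if (!length(obs)) return(c(0, gap_frac))
    p <- stats::setNames(numeric(20), AA_ALPHABET)
    tab <- table(obs)
    p[names(tab)] <- as.numeric(tab) / length(obs)
    c(js_divergence(p, bg) / jsd_max, gap_frac)
  }, numeric(2))
  out <- data.frame(pos = seq_along(cols), ref_res = ref_row[cols],
                    score = pmin(1, pmax(0, res[1L, ])),
                    gap_fraction = res[2L, ],
                    low_coverage = res[2L, ] > low_coverage,
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- aln$reference_id
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Look up the conservation score at a reference position
#'
#' @param track A `conservation_track` from [column_conservation()].
#' @param pos 1-based position in the ungapped reference sequence.
#' @return The score at `pos`.
#' @export
map_to_reference <- function(track, pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > nrow(track)))
    stop_invalid("position out of range [1, %d]", nrow(track))
  track$score[pos]
}

#' Write a conservation track as TSV (plus viewer attribute file)
#'
#' @param track A `conservation_track`.
#' @param path Output TSV path. When `attribute_path` is given, a plain
#'   one-value-per-line list consumable by molecular viewers is also written.
#' @param attribute_path Optional path for the per-residue value list.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(track, path, attribute_path = NULL) {
  utils::write.table(as.data.frame(track)[, c("pos", "ref_res", "score", "gap_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(attribute_path))
    writeLines(formatC(track$score, format = "f", digits = 6), attribute_path)
  invisible(path)
}

#' Co-occurrence of two motif modules across species
#'
#' Quantifies whether two features (e.g. a trans-beta-strand and the
#' ELF-binding motif) are present/absent simultaneously in the same species:
#' the agreement fraction (equal to one minus the normalized Hamming distance
#' between the two presence vectors) and the phi coefficient of the 2x2 table.
#' Phi is undefined (NA, with a note) when any margin of the table is zero.
#'
#' @param module_a,module_b Logical presence vectors, one entry per species.
#' @param species Optional species ids (used only for validation/reporting).
#' @return List with `n`, `agreement`, `phi`, `table` (the 2x2 table) and
#'   `phi_defined`.
#' @export
cooccurrence <- function(module_a, module_b, species = NULL) {
  a <- as.logical(module_a); b <- as.logical(module_b)
  if (length(a) != length(b)) stop_invalid("presence vectors differ in length")
  if (!is.null(species) && length(species) != length(a))
    stop_invalid("species ids differ in length from presence vectors")
  if (length(a) < 2L) stop_invalid("need at least 2 species")
  if (anyNA(a) || anyNA(b)) stop_invalid("presence vectors must not contain NA")
  n11 <- sum(a & b); n00 <- sum(!a & !b)
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  tab <- matrix(c(n11, n01, n10, n00), 2L, 2L,
                dimnames = list(a = c("present", "absent"),
                                b = c("present", "absent")))
  marg <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  phi_ok <- all(marg > 0)
  phi <- if (phi_ok)
    (n11 * n00 - n10 * n01) / sqrt(prod(as.numeric(marg))) else NA_real_
  list(n = length(a), agreement = (n11 + n00) / length(a),
       phi = phi, phi_defined = phi_ok, table = tab)
}

#' Read a presence/absence CSV for co-occurrence analysis
#'
#' Expected columns: `species`, `module_a`, `module_b` (logical or 0/1).
#' @param path CSV path.
#' @return data.frame.
#' @export
read_presence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("species", "module_a", "module_b")
  df$module_a <- as.logical(df$module_a)
  df$module_b <- as.logical(df$module_b)
  df
}
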
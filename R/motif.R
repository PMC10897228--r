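# Motif scanning: literal and anchored scans for candidate ELF-pocket binding
# motifs, plus sequence-context classification of each hit.
#
# The binding-motif criteria operationalized here: (i) an F or L anchor that
# inserts into the hydrophobic ELF pocket; (ii) an acidic residue (D/E) near
# the anchor; (iii) the anchor lies in a disordered stretch. A preceding
# glycine is reported as an additional context flag.

#' Describe a motif search pattern
#'
#' @param anchor_set Allowed anchor residues; default `c("F", "L")`, the two
#'   residues observed inserting into the ELF pocket.
#' @param window Half-width (residues) of the context window used for the
#'   acidic-residue check. Default 5, which covers the D at anchor+2 seen in
#'   FADx-type motifs and an E as far as anchor+6.
#' @param literal Optional exact substring to search for instead of single
#'   anchors (e.g. `"FADI"`).
#' @param disorder_threshold Anchors with a disorder/confidence score below
#'   this value (pLDDT scale) are flagged disordered. Default 50.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(anchor_set = c("F", "L"), window = 5L,
                          literal = NULL, disorder_threshold = 50) {
  anchor_set <- toupper(anchor_set)
  if (!all(anchor_set %in% AA_ALPHABET))
    stop_invalid("anchor_set must be standard amino-acid letters")
  window <- as.integer(window)
  if (is.na(window) || window < 0L)
    stop_invalid("window must be a non-negative integer")
  if (!is.null(literal)) {
    literal <- toupper(literal)
    if (!nzchar(literal) || !all(strsplit(literal, "")[[1]] %in% AA_ALPHABET))
      stop_invalid("literal must be a non-empty string of amino-acid letters")
  }
  structure(list(anchor_set = anchor_set, window = window, literal = literal,
                 disorder_threshold = disorder_threshold),
            class = "motif_pattern")
}

empty_hits <- function() {
  data.frame(protein_id = character(), anchor_pos = integer(),
             anchor_res = character(), context = character(),
             acidic_nearby = logical(), acidic_pos = integer(),
             gly_preceding = logical(), disordered = logical(),
             stringsAsFactors = FALSE)
}

context_window <- function(chars, pos, window) {
  lo <- max(1L, pos - window)
  hi <- min(length(chars), pos + window)
  paste(chars[lo:hi], collapse = "")
}

#' Scan a sequence for an exact literal motif
#'
#' Reports every (possibly overlapping) occurrence of `literal`; the anchor is
#' the first literal character, using 1-based residue coordinates throughout.
#'
#' @param rec A [protein_record].
#' @param literal Exact motif string, e.g. `"FADI"`.
#' @param window Context half-width carried into the reported context column.
#' @return data.frame of hits (possibly 0-row) with columns `protein_id`,
#'   `anchor_pos`, `anchor_res`, `context`.
#' @export
#' @examples
#' scan_literal(protein_record("p", "GSFADIAAR"), "FADI")
scan_literal <- function(rec, literal, window = 5L) {
  stopifnot(inherits(rec, "protein_record"))
  if (!is.character(literal) || length(literal) != 1L || !nzchar(literal))
    stop_invalid("literal must be a non-empty string")
  literal <- toupper(literal)
  if (!nzchar(rec$sequence)) stop_invalid("empty sequence for '%s'", rec$id)
  chars <- seq_chars(rec)
  n <- length(chars); k <- nchar(literal)
  if (k > n) pos <- integer() else {
    # overlapping occurrences: test every start position
    starts <- seq_len(n - k + 1L)
    pos <- starts[vapply(starts, function(i)
      substr(rec$sequence, i, i + k - 1L) == literal, logical(1))]
  }
  if (!length(pos)) return(empty_hits()[, 1:4])
  data.frame(protein_id = rec$id, anchor_pos = as.integer(pos),
             anchor_res = chars[pos],
             context = vapply(pos, function(p)
               context_window(chars, p, window), character(1)),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for anchor residues
#'
#' One hit per residue belonging to the pattern's anchor set (default F/L).
#' Context flags are left unset; use [classify_context()] to fill them.
#'
#' @inheritParams scan_literal
#' @param pattern A [motif_pattern].
#' @return data.frame of hits with unset context flags.
#' @export
scan_anchored <- function(rec, pattern = motif_pattern()) {
  stopifnot(inherits(rec, "protein_record"), inherits(pattern, "motif_pattern"))
  if (!nzchar(rec$sequence)) stop_invalid("empty sequence for '%s'", rec$id)
  chars <- seq_chars(rec)
  pos <- which(chars %in% pattern$anchor_set)
  if (!length(pos)) return(empty_hits()[, 1:4])
  data.frame(protein_id = rec$id, anchor_pos = as.integer(pos),
             anchor_res = chars[pos],
             context = vapply(pos, function(p)
               context_window(chars, p, pattern$window), character(1)),
             stringsAsFactors = FALSE)
}

#' Classify the sequence context of motif hits
#'
#' Fills the binding-motif context flags for each hit row:
#' \describe{
#'   \item{acidic_nearby}{a D or E lies within `window` residues of the anchor
#'     (anchor itself excluded); `acidic_pos` is the nearest such position,
#'     ties broken downstream (C-terminal).}
#'   \item{gly_preceding}{the residue immediately before the anchor is G.}
#'   \item{disordered}{set only when the record carries a disorder track:
#'     `TRUE` iff the score at the anchor is below the pattern's
#'     `disorder_threshold` (pLDDT convention: low = disordered).}
#' }
#' The operation is idempotent and per-hit independent.
#'
#' @param hits data.frame from [scan_literal()] or [scan_anchored()].
#' @param rec The [protein_record] the hits belong to.
#' @param pattern A [motif_pattern] supplying `window` and
#'   `disorder_threshold`.
#' @return The hits with context columns filled.
#' @export
classify_context <- function(hits, rec, pattern = motif_pattern()) {
  stopifnot(inherits(rec, "protein_record"), inherits(pattern, "motif_pattern"))
  if (!nrow(hits)) return(cbind(hits[, 1:4], empty_hits()[, 5:8]))
  if (any(hits$protein_id != rec$id))
    stop_invalid("hits do not belong to record '%s'", rec$id)
  chars <- seq_chars(rec)
  n <- length(chars)
  if (any(hits$anchor_pos < 1L | hits$anchor_pos > n))
    stop_invalid("anchor position out of range for '%s'", rec$id)
  w <- pattern$window
  res <- lapply(hits$anchor_pos, function(p) {
    lo <- max(1L, p - w); hi <- min(n, p + w)
    idx <- setdiff(lo:hi, p)
    acid <- idx[chars[idx] %in% ACIDIC_RESIDUES]
    if (length(acid)) {
      d <- abs(acid - p)
      cand <- acid[d == min(d)]
      apos <- if (length(cand) > 1L) max(cand) else cand  # downstream wins
    } else apos <- NA_integer_
    dis <- if (is.null(rec$disorder)) NA else
      rec$disorder[p] < pattern$disorder_threshold
    list(acidic_nearby = length(acid) > 0L, acidic_pos = as.integer(apos),
         gly_preceding = p > 1L && chars[p - 1L] == "G", disordered = dis)
  })
  hits$acidic_nearby <- vapply(res, `[[`, logical(1), "acidic_nearby")
  hits$acidic_pos <- vapply(res, `[[`, integer(1), "acidic_pos")
  hits$gly_preceding <- vapply(res, `[[`, logical(1), "gly_preceding")
  hits$disordered <- vapply(res, `[[`, logical(1), "disordered")
  hits
}

#' Scan a proteome for candidate ELF-binding motifs
#'
#' Runs the literal scan when `pattern$literal` is set, otherwise the anchored
#' scan followed by context classification, over every record. Output order is
#' deterministic: input record order, then anchor position.
#'
#' @param proteome Non-empty list of [protein_record]s (e.g. from
#'   [read_proteins()]).
#' @param pattern A [motif_pattern].
#' @return data.frame of classified hits with attribute `n_proteins_hit`, the
#'   number of distinct proteins carrying at least one hit (also available via
#'   [n_proteins_hit()]).
#' @export
#' @examples
#' prots <- list(protein_record("a", "MGSFADIK"), protein_record("b", "MKKK"))
#' h <- scan_proteome(prots, motif_pattern(literal = "FADI"))
#' n_proteins_hit(h)  # 1
scan_proteome <- function(proteome, pattern = motif_pattern()) {
  if (!length(proteome)) stop_invalid("proteome must be non-empty")
  ids <- vapply(proteome, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_invalid("duplicate protein id(s): %s", paste(unique(dup), collapse = ", "))
  per <- lapply(proteome, function(rec) {
    h <- if (!is.null(pattern$literal))
      scan_literal(rec, pattern$literal, pattern$window)
    else scan_anchored(rec, pattern)
    classify_context(h, rec, pattern)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  attr(out, "n_proteins_hit") <- length(unique(out$protein_id))
  out
}

#' Number of distinct proteins with at least one motif hit
#' @param hits A hit table from [scan_proteome()].
#' @return Integer count.
#' @export
n_proteins_hit <- function(hits) {
  attr(hits, "n_proteins_hit") %||% length(unique(hits$protein_id))
}

#' Write a motif hit table as TSV
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
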
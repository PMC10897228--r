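# Protein records and sequence I/O.

#' Create a protein record
#'
#' A `protein_record` is the unit the motif scanner works on: a named
#' amino-acid sequence with an optional per-residue disorder/confidence track
#' on the 0-100 pLDDT scale (low values correlate with disorder).
#'
#' @param id Sequence identifier (non-empty string).
#' @param sequence Amino-acid sequence over the 20-letter alphabet; `X` is
#'   tolerated but never matches an anchor or an acidic-context check.
#' @param disorder Optional numeric vector of per-residue scores in
#'   `[0, 100]`, same length as `sequence`.
#' @return An object of class `protein_record`.
#' @export
#' @examples
#' protein_record("CENPF_frag", "GSFADIAAR")
protein_record <- function(id, sequence, disorder = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_invalid("'id' must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_invalid("'sequence' must be a single string")
  sequence <- toupper(sequence)
  if (!is.null(disorder)) {
    disorder <- as.numeric(disorder)
    if (length(disorder) != nchar(sequence))
      stop_invalid("disorder track length (%d) != sequence length (%d) for '%s'",
                   length(disorder), nchar(sequence), id)
    if (anyNA(disorder) || any(disorder < 0 | disorder > 100))
      stop_invalid("disorder scores must lie in [0, 100]")
  }
  structure(list(id = id, sequence = sequence, disorder = disorder),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa%s)\n", x$id, nchar(x$sequence),
              if (is.null(x$disorder)) "" else ", disorder track"))
  invisible(x)
}

seq_chars <- function(rec) strsplit(rec$sequence, "", fixed = TRUE)[[1]]

#' Read a protein FASTA into a list of records
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. The first whitespace
#' token of each header is used as the record id.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named list of [protein_record] objects.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  recs <- lapply(seq_along(aa), function(i)
    protein_record(ids[[i]], as.character(aa[[i]])))
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' Deterministic writer (60-column wrap) so generated proteomes are
#' byte-identical across reruns with the same seed.
#'
#' @param records List of [protein_record] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf(">%s", rec$id), con, sep = "\n")
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con, sep = "\n")
  }
  invisible(path)
}

#' Read a per-residue disorder table
#'
#' Two-column TSV (`id:position`, `score`) or three-column (`id`, `position`,
#' `score`); scores on the 0-100 pLDDT-style scale.
#'
#' @param path TSV path.
#' @return data.frame with columns `id`, `position`, `score`.
#' @export
read_disorder_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) == 2L) {
    key <- strsplit(df[[1L]], ":", fixed = TRUE)
    df <- data.frame(id = vapply(key, `[[`, character(1), 1L),
                     position = as.integer(vapply(key, `[[`, character(1), 2L)),
                     score = as.numeric(df[[2L]]),
                     stringsAsFactors = FALSE)
  } else {
    names(df)[1:3] <- c("id", "position", "score")
    df$position <- as.integer(df$position)
    df$score <- as.numeric(df$score)
  }
  df
}

#' Attach a disorder track to protein records
#'
#' @param records Named list of [protein_record]s.
#' @param disorder data.frame as returned by [read_disorder_tsv()].
#' @return The records with disorder tracks filled in where available.
#' @export
attach_disorder <- function(records, disorder) {
  for (id in intersect(names(records), unique(disorder$id))) {
    sub <- disorder[disorder$id == id, ]
    trk <- rep(NA_real_, nchar(records[[id]]$sequence))
    trk[sub$position] <- sub$score
    if (anyNA(trk))
      stop_invalid("incomplete disorder track for '%s'", id)
    records[[id]] <- protein_record(id, records[[id]]$sequence, trk)
  }
  records
}
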
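# Tiered candidate ranking: combine motif hits with conservation, disorder
# and optional structural evidence into an ordered candidate-client table.
#
# Tiers express the binding-motif criteria without inventing weights:
#   A - anchor is both conserved and disordered (structural evidence noted);
#   B - anchor satisfies at least one extra criterion (conserved, disordered,
#       or structural insertion) but not both of the first two;
#   C - motif hit only.
# Adding evidence can only raise a candidate (monotone).

#' Rank candidate ELF-pocket clients
#'
#' @param hits Hit table from [scan_proteome()].
#' @param conservation Named list of `conservation_track`s (or numeric
#'   per-residue score vectors), keyed by protein id. May omit proteins.
#' @param disorder Optional named list of per-residue disorder scores (0-100
#'   pLDDT scale), keyed by protein id; anchors below
#'   `disorder_threshold` count as disordered. Hits whose `disordered`
#'   column is already set are used as-is.
#' @param reports Optional named list of [interface_report()] objects (or
#'   anything with a `burials` element), keyed by protein id; a report with
#'   at least one inserted residue counts as structural evidence.
#' @param conservation_threshold Anchor conservation score required for the
#'   "conserved" criterion (default 0.8: near-invariant).
#' @param disorder_threshold pLDDT-style cutoff (default 50).
#' @return data.frame of class `candidate_table`, one row per protein,
#'   ordered by (tier, anchor conservation desc, protein id): columns
#'   `protein_id`, `anchor_pos`, `anchor_res`, `context`, `conservation`,
#'   `conserved`, `disordered`, `structural`, `tier`.
#' @export
rank_candidates <- function(hits, conservation = list(), disorder = list(),
                            reports = list(),
                            conservation_threshold = 0.8,
                            disorder_threshold = 50) {
  if (!nrow(hits)) {
    out <- data.frame(protein_id = character(), anchor_pos = integer(),
                      anchor_res = character(), context = character(),
                      conservation = numeric(), conserved = logical(),
                      disordered = logical(), structural = logical(),
                      tier = character(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    return(out)
  }
  for (ev in list(conservation, disorder, reports)) {
    if (length(ev) && is.null(names(ev)))
      stop_invalid("evidence lists must be named by protein id")
  }
  score_at <- function(track, pos) {
    if (is.null(track)) return(NA_real_)
    if (inherits(track, "conservation_track") || is.data.frame(track)) {
      if (pos >= 1L && pos <= nrow(track)) track$score[pos] else NA_real_
    } else if (pos >= 1L && pos <= length(track)) track[pos] else NA_real_
  }
  disorder_at <- function(trk, pos) {
    if (is.null(trk) || pos < 1L || pos > length(trk)) return(NA)
    trk[pos] < disorder_threshold
  }
  has_structure <- function(rep) {
    if (is.null(rep)) return(FALSE)
    any(vapply(rep$burials, `[[`, logical(1), "inserted"))
  }
  per <- lapply(split(hits, hits$protein_id), function(h) {
    id <- h$protein_id[1L]
    cons <- vapply(h$anchor_pos, function(p)
      score_at(conservation[[id]], p), numeric(1))
    best <- if (all(is.na(cons))) 1L else which.max(cons)
    row <- h[best, , drop = FALSE]
    dis <- if (!is.null(row$disordered) && !is.na(row$disordered))
      row$disordered else disorder_at(disorder[[id]], row$anchor_pos)
    data.frame(protein_id = id, anchor_pos = row$anchor_pos,
               anchor_res = row$anchor_res, context = row$context,
               conservation = cons[best],
               conserved = !is.na(cons[best]) &&
                 cons[best] >= conservation_threshold,
               disordered = isTRUE(dis),
               structural = has_structure(reports[[id]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out$tier <- with(out, ifelse(conserved & disordered, "A",
                        ifelse(conserved | disordered | structural, "B", "C")))
  cons_key <- ifelse(is.na(out$conservation), -Inf, out$conservation)
  out <- out[order(out$tier, -cons_key, out$protein_id), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Write a candidate table (TSV + JSON summary)
#' @param candidates A `candidate_table`.
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON summary path (tier counts and top ids).
#' @return `tsv_path`, invisibly.
#' @export
write_candidates <- function(candidates, tsv_path, json_path = NULL) {
  utils::write.table(as.data.frame(candidates), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(
      n = nrow(candidates),
      tiers = as.list(table(candidates$tier)),
      top = utils::head(candidates$protein_id, 10L)
    )
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE)
  }
  invisible(tsv_path)
}
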
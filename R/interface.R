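# Interface featurization of two-chain complexes: side-chain burial
# ("insertion" into the hydrophobic pocket), side-chain and backbone-oxygen
# salt bridges, inter-chain beta-strand pairing, hydrophobicity and
# confidence tracks, and the aggregated interface report.

BASIC_SIDECHAIN_N <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")
ACIDIC_SIDECHAIN_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Side-chain burial of a client residue on complexation
#'
#' Computes the side-chain SASA of the residue with the client chain alone and
#' in the two-chain complex; the relative burial is the drop normalized by a
#' maximal-exposure reference for that residue type (clamped to `[0, 1]`).
#' `inserted` flags near-complete burial, the operational reading of a side
#' chain inserting extensively into the receptor pocket.
#'
#' Glycine has no side chain: its C-alpha is used as a proxy and the result is
#' flagged (`gly_proxy`).
#'
#' @param model A [structure_model].
#' @param client_chain,receptor_chain Chain ids.
#' @param res_seq Author residue number on the client chain.
#' @param insertion_threshold Relative burial at or above which the residue
#'   counts as inserted (default 0.7).
#' @param probe,n_points SASA parameters, see [sasa()].
#' @return List of class `burial_result`: `res_seq`, `res_name`,
#'   `sasa_isolated`, `sasa_complex`, `relative_burial`, `inserted`,
#'   `gly_proxy`.
#' @export
delta_sasa_insertion <- function(model, client_chain, receptor_chain, res_seq,
                                 insertion_threshold = 0.7,
                                 probe = 1.4, n_points = 960L) {
  client <- atoms_of(model, client_chain)
  if (!nrow(client)) stop_invalid("client chain '%s' absent", client_chain)
  sel <- client$res_seq == res_seq
  if (!any(sel)) stop_invalid("residue %d not on chain '%s'", res_seq, client_chain)
  res_name <- client$res_name[sel][1L]
  gly <- res_name == "GLY"
  side_names <- if (gly) "CA" else
    setdiff(client$atom_name[sel], BACKBONE_ATOMS)
  if (!length(side_names))
    stop_invalid("residue %s%d has no side-chain atoms", res_name, res_seq)
  pick <- function(atoms) which(atoms$chain == client_chain &
                                  atoms$res_seq == res_seq &
                                  atoms$atom_name %in% side_names)
  iso <- sasa(client, probe = probe, n_points = n_points,
              atom_subset = pick(client))
  both <- atoms_of(model, c(client_chain, receptor_chain))
  cpx <- sasa(both, probe = probe, n_points = n_points,
              atom_subset = pick(both))
  s_iso <- attr(iso, "total"); s_cpx <- attr(cpx, "total")
  res1 <- AA3_TO_1[res_name]
  ref <- if (is.na(res1)) max(s_iso, 1) else max_sidechain_asa(unname(res1))
  rel <- min(1, max(0, (s_iso - s_cpx) / ref))
  structure(list(chain = client_chain, res_seq = as.integer(res_seq),
                 res_name = res_name,
                 sasa_isolated = s_iso, sasa_complex = s_cpx,
                 relative_burial = rel,
                 inserted = rel >= insertion_threshold,
                 gly_proxy = gly),
            class = "burial_result")
}

#' @export
print.burial_result <- function(x, ...) {
  cat(sprintf("<burial> %s%d (%s): iso %.1f A^2 -> complex %.1f A^2, rel %.2f%s\n",
              x$res_name, x$res_seq, x$chain, x$sasa_isolated, x$sasa_complex,
              x$relative_burial, if (x$inserted) " [inserted]" else ""))
  invisible(x)
}

#' Detect inter-chain salt bridges
#'
#' A side-chain bridge is called when a guanidinium/amino nitrogen of Arg
#' (`NH1`/`NH2`/`NE`) or Lys (`NZ`) lies within `cutoff` of a carboxylate
#' oxygen of Asp/Glu (`OD1`/`OD2`/`OE1`/`OE2`) on the other chain; a
#' backbone-oxygen bridge when such a nitrogen is within `cutoff` of a
#' backbone `O`. Histidine is excluded by default (protonation unknown).
#' One row per residue pair and kind, with the minimum N-O distance;
#' symmetric in chain order up to the basic/acidic role labels.
#'
#' @param model A [structure_model].
#' @param chain_a,chain_b Chain ids.
#' @param cutoff N-O distance cutoff in Angstrom (default 4.0).
#' @param include_his Treat His `ND1`/`NE2` as basic nitrogens (default FALSE).
#' @return data.frame, one row per bridge: `basic_chain`, `basic_res_seq`,
#'   `basic_res_name`, `basic_atom`, `partner_chain`, `partner_res_seq`,
#'   `partner_res_name`, `partner_atom`, `kind`
#'   (`"side-chain"`/`"backbone-oxygen"`), `min_distance`.
#' @export
detect_salt_bridges <- function(model, chain_a, chain_b, cutoff = 4.0,
                                include_his = FALSE) {
  basic_map <- BASIC_SIDECHAIN_N
  if (include_his) basic_map$HIS <- c("ND1", "NE2")
  out <- list()
  for (chains in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    ba <- atoms_of(model, chains[1L])
    pa <- atoms_of(model, chains[2L])
    if (!nrow(ba) || !nrow(pa))
      stop_invalid("chain '%s' absent", chains[which(!c(nrow(ba), nrow(pa)))[1L]])
    bn <- ba[mapply(function(rn, an) rn %in% names(basic_map) &&
                      an %in% basic_map[[rn]],
                    ba$res_name, ba$atom_name), , drop = FALSE]
    if (!nrow(bn)) next
    sc_o <- pa[mapply(function(rn, an) rn %in% names(ACIDIC_SIDECHAIN_O) &&
                        an %in% ACIDIC_SIDECHAIN_O[[rn]],
                      pa$res_name, pa$atom_name), , drop = FALSE]
    bb_o <- pa[pa$atom_name == "O", , drop = FALSE]
    for (targets in list(list(sc_o, "side-chain"),
                         list(bb_o, "backbone-oxygen"))) {
      tg <- targets[[1L]]; kind <- targets[[2L]]
      if (!nrow(tg)) next
      d <- sqrt(outer(bn$x, tg$x, `-`)^2 + outer(bn$y, tg$y, `-`)^2 +
                  outer(bn$z, tg$z, `-`)^2)
      hit <- which(d <= cutoff, arr.ind = TRUE)
      if (!nrow(hit)) next
      df <- data.frame(
        basic_chain = bn$chain[hit[, 1L]],
        basic_res_seq = bn$res_seq[hit[, 1L]],
        basic_res_name = bn$res_name[hit[, 1L]],
        basic_atom = bn$atom_name[hit[, 1L]],
        partner_chain = tg$chain[hit[, 2L]],
        partner_res_seq = tg$res_seq[hit[, 2L]],
        partner_res_name = tg$res_name[hit[, 2L]],
        partner_atom = tg$atom_name[hit[, 2L]],
        kind = kind,
        min_distance = d[hit],
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out))
    return(data.frame(basic_chain = character(), basic_res_seq = integer(),
                      basic_res_name = character(), basic_atom = character(),
                      partner_chain = character(), partner_res_seq = integer(),
                      partner_res_name = character(), partner_atom = character(),
                      kind = character(), min_distance = numeric(),
                      stringsAsFactors = FALSE))
  all <- do.call(rbind, out)
  # deduplicate per (residue pair, kind): keep the minimum distance,
  # remembering the participating atoms of the closest contact
  key <- paste(all$basic_chain, all$basic_res_seq, all$partner_chain,
               all$partner_res_seq, all$kind, sep = "|")
  ord <- order(key, all$min_distance)
  all <- all[ord, ][!duplicated(key[ord]), ]
  all <- all[order(all$basic_chain, all$basic_res_seq,
                   all$partner_res_seq, all$kind), ]
  rownames(all) <- NULL
  all
}

backbone_table <- function(model, chain) {
  res <- chain_residues(model, chain)
  atoms <- atoms_of(model, chain)
  get <- function(rs, nm) get_atom_xyz(atoms, chain, rs, nm)
  bb <- lapply(res$res_seq, function(rs) {
    l <- list(N = get(rs, "N"), CA = get(rs, "CA"),
              C = get(rs, "C"), O = get(rs, "O"))
    n_missing <- sum(vapply(l, is.null, logical(1)))
    if (n_missing) structure(list(), n_missing = n_missing) else l
  })
  ok <- lengths(bb) == 4L
  # residues with a *partial* backbone are suspicious and worth a warning;
  # residues with no backbone at all (ligand-like) are skipped silently
  partial <- sum(vapply(bb[!ok], function(b)
    attr(b, "n_missing") < 4L, logical(1)))
  if (partial)
    warning(sprintf("chain %s: %d residue(s) with incomplete backbone skipped",
                    chain, partial))
  list(res_seq = res$res_seq[ok], bb = bb[ok])
}

angle_deg <- function(a, vertex, b) {
  u <- a - vertex; v <- b - vertex
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect inter-chain beta-strand pairings
#'
#' Geometric beta-ladder criterion (no DSSP energy): residues i (chain A) and
#' j (chain B) are paired when a backbone hydrogen bond links them
#' (N...O <= `hbond_cutoff` in either direction, with the donor nitrogen
#' roughly along the carbonyl: angle C-O...N >= `min_angle`) and their
#' C-alpha atoms are within `ca_cutoff`. Consecutive pairs stepping
#' (i+1, j-1) form antiparallel runs, (i+1, j+1) parallel runs; runs shorter
#' than `min_pair_length` are dropped. Orientation is confirmed by the strand
#' direction vectors (negative dot product = antiparallel).
#'
#' @param model A [structure_model].
#' @param chain_a,chain_b Chain ids (inter-chain only: identical ids give an
#'   empty result).
#' @param hbond_cutoff N...O cutoff in Angstrom (default 3.5).
#' @param ca_cutoff C-alpha pair cutoff (default 5.5).
#' @param min_pair_length Minimum residues per ladder (default 2).
#' @param min_angle Minimum C-O...N angle in degrees (default 90).
#' @return List of pairings; each has `strand_a`, `strand_b` (residue number
#'   vectors), `orientation`, and `registry` (data.frame `res_a`, `res_b`).
#' @export
detect_interchain_beta_pairs <- function(model, chain_a, chain_b,
                                         hbond_cutoff = 3.5, ca_cutoff = 5.5,
                                         min_pair_length = 2L,
                                         min_angle = 90) {
  if (identical(chain_a, chain_b)) return(list())
  A <- backbone_table(model, chain_a)
  B <- backbone_table(model, chain_b)
  if (!length(A$res_seq) || !length(B$res_seq)) return(list())
  dist3 <- function(p, q) sqrt(sum((p - q)^2))
  hbond <- function(donor, acceptor) {
    # donor N, acceptor residue's O (C=O); angular check at the oxygen
    d <- dist3(donor$N, acceptor$O)
    d <= hbond_cutoff && angle_deg(acceptor$C, acceptor$O, donor$N) >= min_angle
  }
  pairs <- list()
  for (i in seq_along(A$res_seq)) for (j in seq_along(B$res_seq)) {
    ai <- A$bb[[i]]; bj <- B$bb[[j]]
    if (dist3(ai$CA, bj$CA) > ca_cutoff) next
    if (hbond(ai, bj) || hbond(bj, ai))
      pairs[[length(pairs) + 1L]] <- c(i = i, j = j)
  }
  if (!length(pairs)) return(list())
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, "i"], pm[, "j"]), , drop = FALSE]
  used <- rep(FALSE, nrow(pm))
  runs <- list()
  for (s in seq_len(nrow(pm))) {
    if (used[s]) next
    run <- pm[s, , drop = FALSE]
    used[s] <- TRUE
    for (step_j in c(-1L, 1L)) {
      if (nrow(run) > 1L) break
      repeat {
        last <- run[nrow(run), ]
        nxt <- which(!used & pm[, "i"] == last["i"] + 1L &
                       pm[, "j"] == last["j"] + step_j)
        if (!length(nxt)) break
        run <- rbind(run, pm[nxt[1L], ])
        used[nxt[1L]] <- TRUE
      }
    }
    if (nrow(run) < min_pair_length) next
    ia <- run[, "i"]; jb <- run[, "j"]
    # strand direction vectors follow each chain's own residue order
    dirA <- A$bb[[max(ia)]]$CA - A$bb[[min(ia)]]$CA
    dirB <- B$bb[[max(jb)]]$CA - B$bb[[min(jb)]]$CA
    orientation <- if (sum(dirA * dirB) < 0) "antiparallel" else "parallel"
    runs[[length(runs) + 1L]] <- list(
      strand_a = A$res_seq[ia],
      strand_b = B$res_seq[jb],
      orientation = orientation,
      registry = data.frame(res_a = A$res_seq[ia], res_b = B$res_seq[jb])
    )
  }
  runs
}

#' Kyte-Doolittle hydrophobicity per residue of a chain
#'
#' @param model A [structure_model].
#' @param chain Chain id.
#' @return data.frame `res_seq`, `res_name`, `hydrophobicity`; non-standard
#'   residues get the neutral value 0 with a warning.
#' @export
hydrophobicity_map <- function(model, chain) {
  res <- chain_residues(model, chain)
  h <- unname(kyte_doolittle[res$res1])
  ns <- is.na(h)
  if (any(ns)) {
    warning(sprintf("%d non-standard residue(s) on chain %s assigned neutral hydrophobicity",
                    sum(ns), chain))
    h[ns] <- 0
  }
  data.frame(res_seq = res$res_seq, res_name = res$res_name,
             hydrophobicity = h, stringsAsFactors = FALSE)
}

#' Aggregate interface report for a two-chain complex
#'
#' Burial results for every client residue with an atom within
#' `contact_distance` of the receptor, salt bridges, beta pairings,
#' low-confidence flags (residues of either chain at the interface whose
#' pLDDT-style confidence is below `plddt_threshold`), a Kyte-Doolittle
#' hydrophobicity track for the receptor, and an optional conservation
#' overlay (track positions are taken as the receptor's author numbering).
#'
#' @param model A [structure_model].
#' @param client_chain,receptor_chain Chain ids.
#' @param conservation Optional `conservation_track` for the receptor.
#' @param contact_distance Interface contact cutoff in Angstrom (default 5).
#' @param plddt_threshold Confidence flag threshold (default 70).
#' @param insertion_threshold,probe,n_points Passed to
#'   [delta_sasa_insertion()].
#' @param ... Additional arguments for [detect_salt_bridges()] /
#'   [detect_interchain_beta_pairs()].
#' @return List of class `interface_report`; JSON-serializable via
#'   [write_interface_json()].
#' @export
interface_report <- function(model, client_chain, receptor_chain,
                             conservation = NULL, contact_distance = 5.0,
                             plddt_threshold = 70, insertion_threshold = 0.7,
                             probe = 1.4, n_points = 960L, ...) {
  ca <- atoms_of(model, client_chain)
  ra <- atoms_of(model, receptor_chain)
  if (!nrow(ca)) stop_invalid("client chain '%s' absent", client_chain)
  if (!nrow(ra)) stop_invalid("receptor chain '%s' absent", receptor_chain)
  d2 <- outer(ca$x, ra$x, `-`)^2 + outer(ca$y, ra$y, `-`)^2 +
    outer(ca$z, ra$z, `-`)^2
  in_contact <- d2 <= contact_distance^2
  contact_client <- sort(unique(ca$res_seq[rowSums(in_contact) > 0]))
  contact_receptor <- sort(unique(ra$res_seq[colSums(in_contact) > 0]))
  burials <- lapply(contact_client, function(rs)
    delta_sasa_insertion(model, client_chain, receptor_chain, rs,
                         insertion_threshold = insertion_threshold,
                         probe = probe, n_points = n_points))
  bridges <- detect_salt_bridges(model, client_chain, receptor_chain, ...)
  pairings <- detect_interchain_beta_pairs(model, client_chain, receptor_chain)
  resc <- chain_residues(model, client_chain)
  resr <- chain_residues(model, receptor_chain)
  lowc <- rbind(
    data.frame(chain = client_chain,
               res_seq = resc$res_seq, confidence = resc$confidence)[
                 resc$res_seq %in% contact_client &
                   resc$confidence < plddt_threshold, ],
    data.frame(chain = receptor_chain,
               res_seq = resr$res_seq, confidence = resr$confidence)[
                 resr$res_seq %in% contact_receptor &
                   resr$confidence < plddt_threshold, ])
  rownames(lowc) <- NULL
  hyd <- hydrophobicity_map(model, receptor_chain)
  if (!is.null(conservation)) {
    ok <- resr$res_seq >= 1L & resr$res_seq <= nrow(conservation)
    cons <- data.frame(res_seq = resr$res_seq[ok],
                       score = map_to_reference(conservation, resr$res_seq[ok]))
  } else cons <- NULL
  structure(list(client_chain = client_chain, receptor_chain = receptor_chain,
                 contact_client_residues = contact_client,
                 contact_receptor_residues = contact_receptor,
                 burials = burials, salt_bridges = bridges,
                 beta_pairings = pairings, low_confidence_flags = lowc,
                 hydrophobicity = hyd, conservation = cons),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> client %s vs receptor %s\n",
              x$client_chain, x$receptor_chain))
  ins <- sum(vapply(x$burials, `[[`, logical(1), "inserted"))
  cat(sprintf("  contact residues: %d client / %d receptor\n",
              length(x$contact_client_residues), length(x$contact_receptor_residues)))
  cat(sprintf("  inserted side chains: %d; salt bridges: %d; beta pairings: %d\n",
              ins, nrow(x$salt_bridges), length(x$beta_pairings)))
  if (nrow(x$low_confidence_flags))
    cat(sprintf("  low-confidence interface residues: %d\n",
                nrow(x$low_confidence_flags)))
  invisible(x)
}

#' Write an interface report as JSON
#' @param report An [interface_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interface_json <- function(report, path) {
  x <- unclass(report)
  x$burials <- lapply(x$burials, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
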
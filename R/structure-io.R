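# Minimal PDB / mmCIF structure I/O.
#
# Models follow the AlphaFold convention: per-residue confidence (pLDDT,
# 0-100) stored in the B-factor field. Author residue numbering (auth_seq)
# is preserved and used in every report so outputs read like the figures
# (R263, F2989, ...). No installed R package parses these formats, hence the
# hand-rolled readers; they cover the records AlphaFold-style model files use.

#' Build a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `res_seq` (author numbering),
#'   `res_name` (3-letter), `atom_name`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `bfactor`, and optionally `altloc`, `hetero`.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "res_seq", "res_name", "atom_name", "element",
            "x", "y", "z", "occupancy", "bfactor")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_invalid("atom table missing column(s): %s",
                                 paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop_invalid("structure has no atoms")
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop_invalid("non-finite atom coordinates")
  atoms$res_seq <- as.integer(atoms$res_seq)
  # altloc resolution: keep the highest-occupancy conformer per atom
  if (any(nzchar(atoms$altloc))) {
    key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name, sep = "|")
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  }
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$res_seq), ]
  rownames(atoms) <- NULL
  flagged <- atoms$x == 0 & atoms$y == 0 & atoms$z == 0
  structure(list(atoms = atoms,
                 zero_coord_atoms = which(flagged)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- model_chains(x)
  cat(sprintf("<structure_model> %d atoms, %d chain(s): %s\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ", ")))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of chain ids.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Residue table of one chain
#'
#' One row per residue: `res_seq`, `res_name`, `res1` (one-letter, `X` for
#' non-standard), `confidence` (mean B-factor over the residue's atoms).
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param include_hetero Keep hetero/water residues (default FALSE).
#' @return data.frame, residues in numbering order.
#' @export
chain_residues <- function(model, chain, include_hetero = FALSE) {
  a <- model$atoms[model$atoms$chain == chain, ]
  if (!include_hetero) a <- a[!a$hetero & a$res_name != "HOH", ]
  if (!nrow(a)) stop_invalid("chain '%s' not present (or empty)", chain)
  sp <- split(a, a$res_seq)
  ord <- order(as.integer(names(sp)))
  sp <- sp[ord]
  data.frame(
    res_seq = as.integer(names(sp)),
    res_name = vapply(sp, function(r) r$res_name[1L], character(1)),
    res1 = vapply(sp, function(r) {
      v <- AA3_TO_1[r$res_name[1L]]
      if (is.na(v)) "X" else unname(v)
    }, character(1)),
    confidence = vapply(sp, function(r) mean(r$bfactor), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-letter sequence of a chain
#' @inheritParams chain_residues
#' @return Single string (non-standard residues as `X`).
#' @export
chain_sequence <- function(model, chain) {
  paste(chain_residues(model, chain)$res1, collapse = "")
}

atoms_of <- function(model, chain = NULL, include_hetero = FALSE) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  if (!include_hetero) a <- a[!a$hetero & a$res_name != "HOH", ]
  a
}

get_atom_xyz <- function(atoms, chain, res_seq, atom_name) {
  i <- which(atoms$chain == chain & atoms$res_seq == res_seq &
               atoms$atom_name == atom_name)
  if (!length(i)) return(NULL)
  as.numeric(atoms[i[1L], c("x", "y", "z")])
}

#' Parse a PDB or mmCIF structure file
#'
#' Format is chosen from content (`_atom_site` loop implies mmCIF). Per-residue
#' confidence is read from the B-factor column; author chain ids and residue
#' numbers are kept. The highest-occupancy altloc conformer is retained.
#' Atoms with all-zero coordinates are parsed but flagged
#' (`model$zero_coord_atoms`).
#'
#' @param path File path (`.pdb`, `.cif`, or content-sniffed).
#' @return A [structure_model].
#' @export
parse_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*_atom_site\\.", lines))) parse_mmcif_lines(lines, path)
  else parse_pdb_lines(lines, path)
}

parse_pdb_lines <- function(lines, path = "<pdb>") {
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop_invalid("no ATOM/HETATM records in '%s'", path)
  ln <- lines[keep]
  num <- function(s, what, idx) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop_invalid("malformed %s field at line %d of '%s'",
                   what, keep[bad[1L]], path)
    v
  }
  atoms <- data.frame(
    chain = trimws(substr(ln, 22, 22)),
    res_seq = as.integer(num(trimws(substr(ln, 23, 26)), "resSeq", keep)),
    res_name = trimws(substr(ln, 18, 20)),
    atom_name = trimws(substr(ln, 13, 16)),
    element = trimws(substr(ln, 77, 78)),
    x = num(trimws(substr(ln, 31, 38)), "x", keep),
    y = num(trimws(substr(ln, 39, 46)), "y", keep),
    z = num(trimws(substr(ln, 47, 54)), "z", keep),
    occupancy = suppressWarnings(as.numeric(trimws(substr(ln, 55, 60)))),
    bfactor = suppressWarnings(as.numeric(trimws(substr(ln, 61, 66)))),
    altloc = trimws(substr(ln, 17, 17)),
    hetero = rec[keep] == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  no_el <- !nzchar(atoms$element)
  atoms$element[no_el] <- substr(gsub("[0-9]", "", atoms$atom_name[no_el]), 1, 1)
  structure_model(atoms)
}

parse_mmcif_lines <- function(lines, path = "<cif>") {
  hdr_idx <- grep("^\\s*_atom_site\\.", lines)
  if (!length(hdr_idx)) stop_invalid("no _atom_site loop in '%s'", path)
  fields <- sub("^\\s*_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- character()
  i <- max(hdr_idx) + 1L
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || grepl("^(#|loop_|_)", l) || l == ";") break
    body <- c(body, l)
    i <- i + 1L
  }
  toks <- strsplit(body, "\\s+")
  bad <- which(lengths(toks) != length(fields))
  if (length(bad))
    stop_invalid("mmCIF row %d of '%s' has %d tokens (expected %d)",
                 bad[1L], path, lengths(toks)[bad[1L]], length(fields))
  tab <- do.call(rbind, toks)
  colnames(tab) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[, f])
    rep(NA_character_, nrow(tab))
  }
  grp <- pick("group_PDB")
  atoms <- data.frame(
    chain = pick("auth_asym_id", "label_asym_id"),
    res_seq = as.integer(pick("auth_seq_id", "label_seq_id")),
    res_name = pick("auth_comp_id", "label_comp_id"),
    atom_name = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
    element = pick("type_symbol"),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    occupancy = suppressWarnings(as.numeric(pick("occupancy"))),
    bfactor = suppressWarnings(as.numeric(pick("B_iso_or_equiv"))),
    altloc = gsub("[.?]", "", pick("label_alt_id")),
    hetero = !is.na(grp) & grp == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  if (anyNA(atoms$x) || anyNA(atoms$res_seq))
    stop_invalid("malformed _atom_site values in '%s'", path)
  structure_model(atoms)
}

#' Write a model as PDB
#' @param model A [structure_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  name_fmt <- ifelse(nchar(a$atom_name) < 4L,
                     sprintf(" %-3s", a$atom_name), a$atom_name)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)), name_fmt, "",
    a$res_name, a$chain, a$res_seq, a$x, a$y, a$z,
    a$occupancy, a$bfactor, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a model as mmCIF
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(model, path) {
  a <- model$atoms
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id")))
  rows <- sprintf("%s %d %s %s . %s %s %d %.3f %.3f %.3f %.2f %.2f %d %s %s %s",
                  ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
                  a$element, a$atom_name, a$res_name, a$chain, a$res_seq,
                  a$x, a$y, a$z, a$occupancy, a$bfactor,
                  a$res_seq, a$res_name, a$chain, a$atom_name)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
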
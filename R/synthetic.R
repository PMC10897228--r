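# Ground-truthed synthetic data for every pipeline stage: proteomes with
# planted motifs, MSAs with controlled per-column substitution rates, toy
# two-chain complexes with planted interface features, two-channel cell
# images with known enrichment, and f-Y2H plate tables.
#
# Every generator is a pure function of its parameters and seed (the RNG
# state is saved and restored), and returns the artifact together with a
# `ground_truth` list that fully determines what the corresponding detector
# should find.

#' Generate a decoy proteome with planted literal motifs
#'
#' Decoy sequences are drawn from a background residue distribution with the
#' motif literal rejected by resampling, so a decoy can never contain it;
#' planted proteins carry the literal at a recorded position.
#'
#' @param n_proteins Number of proteins.
#' @param motif_literal Planted literal (default `"FADI"`).
#' @param n_planted Number of proteins carrying the literal
#'   (`<= n_proteins`).
#' @param seed Integer seed.
#' @param length_range Min/max decoy length (default 300-600).
#' @param background `"uniform"` or a named residue probability vector; every
#'   literal letter must have positive background probability.
#' @param fasta Optional path: write the proteome as FASTA.
#' @return List with `records` (named list of [protein_record]s) and
#'   `ground_truth` (`planted`: data.frame `protein_id`, `anchor_pos`).
#' @export
gen_proteome <- function(n_proteins = 100L, motif_literal = "FADI",
                         n_planted = 5L, seed = 1L,
                         length_range = c(300L, 600L),
                         background = "uniform", fasta = NULL) {
  if (n_planted > n_proteins)
    stop_invalid("n_planted (%d) exceeds n_proteins (%d)", n_planted, n_proteins)
  motif_literal <- toupper(motif_literal)
  lit <- strsplit(motif_literal, "")[[1]]
  bg <- if (is.character(background) && identical(background, "uniform"))
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET) else aa_background(background)
  if (any(bg[lit] <= 0) || anyNA(bg[lit]))
    stop_invalid("literal '%s' uses residues absent from the background; rejection sampling cannot terminate",
                 motif_literal)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins, replace = TRUE)
    ids <- sprintf("prot%04d", seq_len(n_proteins))
    planted_idx <- sort(sample(n_proteins, n_planted))
    seqs <- vapply(seq_len(n_proteins), function(i) {
      repeat {
        s <- paste(sample(AA_ALPHABET, lens[i], replace = TRUE, prob = bg),
                   collapse = "")
        if (!grepl(motif_literal, s, fixed = TRUE)) return(s)
      }
    }, character(1))
    anchor <- integer(0)
    for (i in planted_idx) {
      k <- nchar(motif_literal)
      pos <- sample(seq(10L, lens[i] - k - 10L), 1L)
      substr(seqs[i], pos, pos + k - 1L) <- motif_literal
      anchor <- c(anchor, pos)
    }
    records <- lapply(seq_len(n_proteins), function(i)
      protein_record(ids[i], seqs[i]))
    names(records) <- ids
    if (!is.null(fasta)) write_proteins(records, fasta)
    list(records = records,
         ground_truth = list(
           generator = "gen_proteome", seed = seed,
           motif_literal = motif_literal,
           planted = data.frame(protein_id = ids[planted_idx],
                                anchor_pos = anchor,
                                stringsAsFactors = FALSE)))
  })
}

#' Generate an MSA with controlled per-column substitution rates
#'
#' Each homolog row is the reference with i.i.d. per-column substitutions:
#' with probability `per_column_rate[j]`, column j is replaced by a residue
#' drawn uniformly from the 20-letter alphabet (so rate 1 gives a
#' background-uniform column and conservation ~ 0). No indels.
#'
#' @param ref_seq Reference sequence string.
#' @param n_rows Number of homolog rows (reference row is added on top).
#' @param per_column_rate Substitution probability per column; scalar or
#'   vector recycled to the reference length, values in `[0, 1]`.
#' @param seed Integer seed.
#' @param ref_id Reference row id (default `"REF"`).
#' @return List with `alignment` (an [msa_alignment], reference first) and
#'   `ground_truth` (the per-column rates).
#' @export
gen_msa <- function(ref_seq, n_rows = 100L, per_column_rate = 0.1,
                    seed = 1L, ref_id = "REF") {
  ref_seq <- toupper(ref_seq)
  L <- nchar(ref_seq)
  if (!L) stop_invalid("empty reference sequence")
  rate <- rep_len(as.numeric(per_column_rate), L)
  if (any(rate < 0 | rate > 1)) stop_invalid("rates must lie in [0, 1]")
  refc <- strsplit(ref_seq, "")[[1]]
  with_seed(seed, {
    rows <- vapply(seq_len(n_rows), function(r) {
      mut <- stats::runif(L) < rate
      out <- refc
      if (any(mut))
        out[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
      paste(out, collapse = "")
    }, character(1))
    aln <- msa_alignment(c(ref_id, sprintf("hom%04d", seq_len(n_rows))),
                         c(ref_seq, rows), ref_id)
    list(alignment = aln,
         ground_truth = list(generator = "gen_msa", seed = seed,
                             per_column_rate = rate))
  })
}

# ---- idealized complex geometry ---------------------------------------------

atom_rows <- function(chain, res_seq, res_name, names, elements, xyz, bfactor) {
  data.frame(chain = chain, res_seq = as.integer(res_seq),
             res_name = res_name, atom_name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bfactor = bfactor,
             altloc = "", hetero = FALSE, stringsAsFactors = FALSE)
}

# extended-strand backbone template; per residue k (1-based), +x direction:
#   N (3.63k, 0, 0), CA (+1.12, 0, -0.94), C (+2.29, 0, 0.03), O = C + o_off
strand_residue <- function(k, o_off = c(0, 1.23, 0)) {
  base <- c(3.63 * k, 0, 0)
  rbind(N = base,
        CA = base + c(1.12, 0, -0.94),
        C = base + c(2.29, 0, 0.03),
        O = base + c(2.29, 0, 0.03) + o_off)
}

build_strand <- function(chain, start_res, n, origin, bfactor = 90,
                         o_off = c(0, 1.23, 0), res_name = "GLY") {
  do.call(rbind, lapply(seq_len(n), function(k) {
    xyz <- sweep(strand_residue(k, o_off), 2L, origin, `+`)
    atom_rows(chain, start_res + k - 1L, res_name,
              rownames(xyz), c("N", "C", "C", "O"), xyz, bfactor)
  }))
}

# antiparallel partner of build_strand(A): residue j pairs with A residue
# k = n+1-j; every pair carries both backbone H-bonds at 2.90 A
build_antiparallel_partner <- function(chain, start_res, n, origin,
                                       bfactor = 90) {
  do.call(rbind, lapply(seq_len(n), function(j) {
    k <- n + 1L - j
    N  <- c(3.63 * k + 2.29, 4.13, 0)
    CA <- c(3.63 * k + 1.17, 4.13, -0.94)
    C  <- c(3.63 * k, 4.13, 0.03)
    O  <- C + c(0, -1.23, 0)
    xyz <- sweep(rbind(N = N, CA = CA, C = C, O = O), 2L, origin, `+`)
    atom_rows(chain, start_res + j - 1L, "GLY",
              rownames(xyz), c("N", "C", "C", "O"), xyz, bfactor)
  }))
}

# parallel partner: carbonyls tilted (+0.6 x) so only the in-register
# N_j(A)...O_j(B) bond satisfies the 3.5 A cutoff
build_parallel_pair <- function(chain_a, chain_b, start_a, start_b, n, origin,
                                bfactor = 90) {
  a <- do.call(rbind, lapply(seq_len(n), function(k) {
    xyz <- sweep(strand_residue(k, o_off = c(0.6, 1.07, 0)), 2L, origin, `+`)
    atom_rows(chain_a, start_a + k - 1L, "GLY",
              rownames(xyz), c("N", "C", "C", "O"), xyz, bfactor)
  }))
  b <- do.call(rbind, lapply(seq_len(n), function(j) {
    xyz <- sweep(strand_residue(j, o_off = c(0.6, -1.07, 0)), 2L,
                 origin + c(-2.89, 4.13, 0), `+`)
    atom_rows(chain_b, start_b + j - 1L, "GLY",
              rownames(xyz), c("N", "C", "C", "O"), xyz, bfactor)
  }))
  rbind(a, b)
}

build_arg <- function(chain, res_seq, origin, bfactor = 90) {
  xyz <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.51, 0, 0),
               O = c(1.51, -1.23, 0),
               CB = c(0, 1.40, 0.60), CG = c(0, 2.80, 0.90),
               CD = c(0, 4.20, 0.60), NE = c(0, 5.40, 0.90),
               CZ = c(0, 6.60, 0.60), NH1 = c(0, 7.80, 0.90),
               NH2 = c(-1.20, 6.90, 0.30))
  xyz <- sweep(xyz, 2L, origin, `+`)
  atom_rows(chain, res_seq, "ARG", rownames(xyz),
            c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N"),
            xyz, bfactor)
}

# Asp posed with OD1 exactly `dist` above the acceptor point `nh1`
build_asp <- function(chain, res_seq, nh1, dist, bfactor = 90) {
  od1 <- nh1 + c(0, dist, 0)
  xyz <- rbind(OD1 = od1,
               CG = od1 + c(0, 1.25, 0),
               OD2 = od1 + c(1.10, 1.85, 0),
               CB = od1 + c(0, 2.75, 0),
               CA = od1 + c(0, 4.25, 0),
               N = od1 + c(-1.46, 4.25, 0),
               C = od1 + c(1.51, 4.25, 0),
               O = od1 + c(1.51, 5.48, 0))
  atom_rows(chain, res_seq, "ASP", rownames(xyz),
            c("O", "C", "O", "C", "C", "N", "C", "O"), xyz, bfactor)
}

# backbone-only Gly whose carbonyl O sits `dist` above the acceptor point
build_gly_backbone_o <- function(chain, res_seq, nh1, dist, bfactor = 90) {
  o <- nh1 + c(0, dist, 0)
  xyz <- rbind(O = o, C = o + c(0, 1.23, 0), CA = o + c(-1.51, 1.23, 0),
               N = o + c(-2.97, 1.23, 0))
  atom_rows(chain, res_seq, "GLY", rownames(xyz),
            c("O", "C", "C", "N"), xyz, bfactor)
}

build_phe <- function(chain, res_seq, origin, bfactor = 90) {
  xyz <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(1.51, 0, 0),
               O = c(1.51, -1.23, 0),
               CB = c(0, 1.40, 0.60), CG = c(0, 2.90, 0.60),
               CD1 = c(1.20, 3.60, 0.60), CD2 = c(-1.20, 3.60, 0.60),
               CE1 = c(1.20, 5.00, 0.60), CE2 = c(-1.20, 5.00, 0.60),
               CZ = c(0, 5.70, 0.60))
  xyz <- sweep(xyz, 2L, origin, `+`)
  atom_rows(chain, res_seq, "PHE", rownames(xyz),
            c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C"),
            xyz, bfactor)
}

# single-atom pseudo-residue cage enclosing a point cloud: Fibonacci shell,
# holes punched where the client chain passes through
build_cage <- function(chain, start_res, center, client_xyz, radius = 6.5,
                       n_atoms = 250L, clearance = 3.0, bfactor = 90) {
  pts <- sweep(fibonacci_sphere(n_atoms) * radius, 2L, center, `+`)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (client_xyz[, 1] - pts[i, 1])^2 + (client_xyz[, 2] - pts[i, 2])^2 +
      (client_xyz[, 3] - pts[i, 3])^2
    all(d2 > clearance^2)
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    atom_rows(chain, start_res + i - 1L, "ALA", "CB", "C",
              pts[i, , drop = FALSE], bfactor)))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3L)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Apply a rigid-body isometry to a structure model
#'
#' @param model A [structure_model].
#' @param rotation 3x3 rotation matrix (default: random, uses the caller's
#'   RNG stream).
#' @param translation Length-3 translation vector.
#' @return The transformed [structure_model].
#' @export
transform_model <- function(model, rotation = NULL, translation = c(0, 0, 0)) {
  rotation <- rotation %||% random_rotation()
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(rotation)
  a <- model$atoms
  a$x <- xyz[, 1] + translation[1]
  a$y <- xyz[, 2] + translation[2]
  a$z <- xyz[, 3] + translation[3]
  structure_model(a)
}

#' Generate a toy two-chain complex with planted interface features
#'
#' Builds idealized peptide geometry for a receptor chain `A` and client
#' chain `B`, one isolated feature block per requested feature (blocks are
#' spaced 40 A apart so they cannot interact), then applies a seed-derived
#' rigid-body transform plus a small coordinate jitter. Supported features:
#' \describe{
#'   \item{`"salt_bridge"`}{Arg (A) posed with NH1 at `bridge_distance` from
#'     Asp OD1 (B): one side-chain bridge.}
#'   \item{`"salt_bridge_backbone"`}{Arg NH1 at `bridge_distance` from a
#'     client backbone O: one backbone-oxygen bridge.}
#'   \item{`"beta_antiparallel"` / `"beta_parallel"`}{Inter-chain beta ladder
#'     of `beta_length` residues with known registry.}
#'   \item{`"helix_contact"`}{Two alpha-helices in contact: no pairing.}
#'   \item{`"insertion"`}{Phe side chain (B) enclosed in a receptor atom
#'     cage: one inserted residue.}
#'   \item{`"apart"`}{Two strands 20 A apart: no features.}
#' }
#'
#' @param features Character vector of feature names (see above).
#' @param seed Integer seed (drives the rigid transform and jitter only; the
#'   planted features are deterministic).
#' @param bridge_distance N-O distance for planted bridges (default 3.0).
#' @param beta_length Ladder length in residues (default 4).
#' @param jitter Uniform coordinate jitter half-width in Angstrom
#'   (default 0.05; small against all detection margins).
#' @param plddt Per-residue confidence written to the B-factor field
#'   (default 90).
#' @param pdb,mmcif Optional output paths; when given the model is written in
#'   that format.
#' @return List with `model` (a [structure_model]) and `ground_truth`
#'   (planted `salt_bridges` data.frame, `pairings` list, `insertions`
#'   data.frame, plus `client_chain = "B"`, `receptor_chain = "A"`).
#' @export
gen_complex_fixture <- function(features = c("salt_bridge", "beta_antiparallel",
                                             "insertion"),
                                seed = 1L, bridge_distance = 3.0,
                                beta_length = 4L, jitter = 0.05,
                                plddt = 90, pdb = NULL, mmcif = NULL) {
  blocks <- list()
  truth <- list(salt_bridges = NULL, pairings = list(),
                insertions = NULL, client_chain = "B", receptor_chain = "A")
  resA <- 1L; resB <- 1L
  off <- 0
  for (f in features) {
    origin <- c(off, 0, 0)
    if (f == "salt_bridge") {
      arg <- build_arg("A", resA, origin, plddt)
      nh1 <- as.numeric(arg[arg$atom_name == "NH1", c("x", "y", "z")])
      asp <- build_asp("B", resB, nh1, bridge_distance, plddt)
      blocks <- c(blocks, list(arg, asp))
      truth$salt_bridges <- rbind(truth$salt_bridges, data.frame(
        basic_chain = "A", basic_res_seq = resA,
        partner_chain = "B", partner_res_seq = resB,
        kind = "side-chain", stringsAsFactors = FALSE))
      resA <- resA + 1L; resB <- resB + 1L
    } else if (f == "salt_bridge_backbone") {
      arg <- build_arg("A", resA, origin, plddt)
      nh1 <- as.numeric(arg[arg$atom_name == "NH1", c("x", "y", "z")])
      gly <- build_gly_backbone_o("B", resB, nh1, bridge_distance, plddt)
      blocks <- c(blocks, list(arg, gly))
      truth$salt_bridges <- rbind(truth$salt_bridges, data.frame(
        basic_chain = "A", basic_res_seq = resA,
        partner_chain = "B", partner_res_seq = resB,
        kind = "backbone-oxygen", stringsAsFactors = FALSE))
      resA <- resA + 1L; resB <- resB + 1L
    } else if (f == "beta_antiparallel") {
      n <- as.integer(beta_length)
      a <- build_strand("A", resA, n, origin, plddt)
      b <- build_antiparallel_partner("B", resB, n, origin, plddt)
      blocks <- c(blocks, list(a, b))
      truth$pairings <- c(truth$pairings, list(list(
        orientation = "antiparallel",
        registry = data.frame(res_a = resA:(resA + n - 1L),
                              res_b = (resB + n - 1L):resB))))
      resA <- resA + n; resB <- resB + n
    } else if (f == "beta_parallel") {
      n <- as.integer(beta_length)
      ab <- build_parallel_pair("A", "B", resA, resB, n, origin, plddt)
      blocks <- c(blocks, list(ab))
      truth$pairings <- c(truth$pairings, list(list(
        orientation = "parallel",
        registry = data.frame(res_a = resA:(resA + n - 1L),
                              res_b = resB:(resB + n - 1L)))))
      resA <- resA + n; resB <- resB + n
    } else if (f == "helix_contact") {
      n <- 8L
      hel <- function(chain, start, cx) {
        do.call(rbind, lapply(seq_len(n), function(t) {
          th <- (100 * t) * pi / 180
          ca <- c(cx + 2.3 * cos(th), 2.3 * sin(th), 1.5 * t)
          nn <- c(cx + 1.5 * cos(th - 0.47), 1.5 * sin(th - 0.47), 1.5 * t - 0.8)
          cc <- c(cx + 1.6 * cos(th + 0.45), 1.6 * sin(th + 0.45), 1.5 * t + 0.4)
          oo <- cc + c(0, 0, 1.23)
          xyz <- sweep(rbind(N = nn, CA = ca, C = cc, O = oo), 2L, origin, `+`)
          atom_rows(chain, start + t - 1L, "ALA", rownames(xyz),
                    c("N", "C", "C", "O"), xyz, plddt)
        }))
      }
      blocks <- c(blocks, list(hel("A", resA, 0), hel("B", resB, 9.5)))
      resA <- resA + n; resB <- resB + n
    } else if (f == "insertion") {
      phe <- build_phe("B", resB, origin + c(0, 0, 0), plddt)
      side <- as.matrix(phe[!phe$atom_name %in% BACKBONE_ATOMS,
                            c("x", "y", "z")])
      cage <- build_cage("A", resA, colMeans(side),
                         as.matrix(phe[, c("x", "y", "z")]),
                         bfactor = plddt)
      blocks <- c(blocks, list(phe, cage))
      truth$insertions <- rbind(truth$insertions, data.frame(
        chain = "B", res_seq = resB, stringsAsFactors = FALSE))
      resB <- resB + 1L
      resA <- resA + length(unique(cage$res_seq))
    } else if (f == "apart") {
      a <- build_strand("A", resA, 3L, origin, plddt)
      b <- build_strand("B", resB, 3L, origin + c(0, 20, 0), plddt)
      blocks <- c(blocks, list(a, b))
      resA <- resA + 3L; resB <- resB + 3L
    } else stop_invalid("unknown feature '%s'", f)
    off <- off + 40
  }
  atoms <- do.call(rbind, blocks)
  model <- with_seed(seed, {
    atoms$x <- atoms$x + stats::runif(nrow(atoms), -jitter, jitter)
    atoms$y <- atoms$y + stats::runif(nrow(atoms), -jitter, jitter)
    atoms$z <- atoms$z + stats::runif(nrow(atoms), -jitter, jitter)
    transform_model(structure_model(atoms),
                    translation = stats::runif(3, -20, 20))
  })
  if (!is.null(pdb)) write_pdb(model, pdb)
  if (!is.null(mmcif)) write_mmcif(model, mmcif)
  truth$generator <- "gen_complex_fixture"
  truth$seed <- seed
  truth$features <- features
  list(model = model, ground_truth = truth)
}

# ---- imaging ----------------------------------------------------------------

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c_ <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  (r - center[1L])^2 + (c_ - center[2L])^2 <= radius^2
}

dilate_points <- function(shape, rows, cols, radius) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  for (k in seq_len(nrow(offs))) {
    rr <- rows + offs$dr[k]; cc <- cols + offs$dc[k]
    ok <- rr >= 1L & rr <= shape[1L] & cc >= 1L & cc <= shape[2L]
    m[cbind(rr[ok], cc[ok])] <- TRUE
  }
  m
}

#' Generate a synthetic two-channel cell image with known enrichment
#'
#' The marker channel carries the structure (tubular mitochondria drawn as
#' dilated random-walk curves, or yeast-style puncta); the client channel is
#' `baseline` on the cell body and `baseline * enrichment` on the structure
#' (mito mode), or carries a planted punctate intensity fraction `f`
#' (puncta mode), with optional Poisson noise. Masks are returned alongside,
#' so every statistic has a closed-form expected value.
#'
#' @param shape Image dimensions in pixels (default 128 x 128).
#' @param mode `"mito"` (tubular structures, enrichment ratio ground truth)
#'   or `"puncta"` (punctum enrichment ground truth).
#' @param enrichment Planted on/off mean ratio E (mito mode).
#' @param punctate_fraction Planted integrated-density fraction f in puncta
#'   (puncta mode), in (0, 1).
#' @param baseline Mean off-structure intensity in counts (default 100).
#' @param noise `"poisson"` or `"none"`.
#' @param pixel_size Micrometres per pixel (default 0.1, a typical
#'   100x/oil EM-CCD scale).
#' @param seed Integer seed.
#' @return List: `marker`, `client` ([image_channel]s), `mito_mask`,
#'   `cell_mask`, `punctum_mask` ([region_mask]s or NULL), `ground_truth`.
#' @export
gen_cell_image <- function(shape = c(128L, 128L), mode = c("mito", "puncta"),
                           enrichment = 3, punctate_fraction = 0.5,
                           baseline = 100, noise = c("poisson", "none"),
                           pixel_size = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  with_seed(seed, {
    cell <- disk_mask(shape, shape / 2, 0.42 * min(shape))
    if (mode == "mito") {
      rows <- cols <- integer(0)
      for (s in 1:3) {
        r <- shape[1L] / 2 + stats::runif(1, -15, 15)
        c_ <- shape[2L] / 2 + stats::runif(1, -15, 15)
        th <- stats::runif(1, 0, 2 * pi)
        for (t in 1:80) {
          th <- th + stats::rnorm(1, 0, 0.25)
          r <- r + sin(th); c_ <- c_ + cos(th)
          rows <- c(rows, round(r)); cols <- c(cols, round(c_))
        }
      }
      struct <- dilate_points(shape, rows, cols, 2L) & cell
      marker_int <- ifelse(struct, 200, ifelse(cell, 20, 2))
      client_int <- ifelse(struct, baseline * enrichment,
                           ifelse(cell, baseline, 0))
      punctum <- NULL
      gt_value <- enrichment
    } else {
      struct <- matrix(FALSE, shape[1L], shape[2L])
      for (k in 1:6) {
        ctr <- shape / 2 + stats::runif(2, -0.25 * min(shape), 0.25 * min(shape))
        struct <- struct | disk_mask(shape, ctr, 2.2)
      }
      struct <- struct & cell
      n_on <- sum(struct); n_off <- sum(cell & !struct)
      f <- punctate_fraction
      a <- f * baseline * n_off / ((1 - f) * n_on)  # per-pixel punctum intensity
      marker_int <- ifelse(struct, 200, ifelse(cell, 10, 1))
      client_int <- ifelse(struct, a, ifelse(cell, baseline, 0))
      punctum <- region_mask(struct, "punctum")
      gt_value <- f
    }
    noisy <- function(m) if (noise == "poisson")
      matrix(stats::rpois(length(m), m), nrow(m)) else m
    list(marker = image_channel(noisy(marker_int), pixel_size),
         client = image_channel(noisy(client_int), pixel_size),
         mito_mask = region_mask(struct, "mitochondria"),
         cell_mask = region_mask(cell, "cell"),
         punctum_mask = punctum,
         ground_truth = list(generator = "gen_cell_image", seed = seed,
                             mode = mode, value = gt_value,
                             baseline = baseline, noise = noise))
  })
}

# ---- plates -----------------------------------------------------------------

#' Charge-swap f-Y2H effect preset
#'
#' Qualitative wild-type/point-mutant design: WT x WT interacts strongly,
#' either single charge mutant loses the interaction, the double swap
#' restores it.
#' @return Named effect vector (fluorescence above empty-vector background).
#' @export
fy2h_charge_swap_effects <- function() {
  c(WT_WT = 1000, RD_WT = 120, WT_ER = 150, RD_ER = 1250)
}

#' Generate an f-Y2H plate table
#'
#' `raw = empty_signal + effect + Gaussian noise` per well; `n_clones`
#' replicate wells per sample plus `n_empty` empty-vector wells at
#' `empty_signal`.
#'
#' @param effects Named numeric vector of per-sample effects (default the
#'   charge-swap preset).
#' @param empty_signal Empty-vector fluorescence (default 50).
#' @param noise_sd Gaussian noise SD (default 20).
#' @param n_clones Replicate clones per sample (default 3).
#' @param n_empty Empty-vector wells (default 3).
#' @param seed Integer seed.
#' @param csv Optional path: write the plate as CSV.
#' @return List with `plate` (a [plate_table]) and `ground_truth`.
#' @export
gen_plate <- function(effects = fy2h_charge_swap_effects(), empty_signal = 50,
                      noise_sd = 20, n_clones = 3L, n_empty = 3L, seed = 1L,
                      csv = NULL) {
  if (is.null(names(effects))) stop_invalid("effects must be named by sample")
  with_seed(seed, {
    sample_col <- c(rep("empty_vector", n_empty),
                    rep(names(effects), each = n_clones))
    clone_col <- c(seq_len(n_empty), rep(seq_len(n_clones), length(effects)))
    mu <- c(rep(empty_signal, n_empty),
            rep(empty_signal + effects, each = n_clones))
    raw <- mu + stats::rnorm(length(mu), 0, noise_sd)
    plate <- plate_table(sample_col, clone_col, raw,
                         sample_col == "empty_vector")
    if (!is.null(csv))
      utils::write.csv(plate, csv, row.names = FALSE, quote = FALSE)
    list(plate = plate,
         ground_truth = list(generator = "gen_plate", seed = seed,
                             effects = effects, empty_signal = empty_signal,
                             noise_sd = noise_sd))
  })
}
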
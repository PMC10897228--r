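# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic Fibonacci-lattice sphere sampling; per-atom radii by element
# (Bondi values), probe 1.4 A, 960 points by default. Waters and hetero atoms
# are excluded. The sampling point set is fixed in the lab frame, so areas are
# rotation-invariant only up to sampling error — tests treat them as such.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

element_radius <- function(element) {
  el <- toupper(element)
  r <- VDW_RADII[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default vdW radius %.2f A",
                    paste(unique(el[unknown]), collapse = ", "), VDW_DEFAULT))
    r[unknown] <- VDW_DEFAULT
  }
  unname(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param model A [structure_model] or a plain atom data.frame with `element`,
#'   `x`, `y`, `z` columns.
#' @param chains Optional chain subset; only these atoms form the occluding
#'   context (and are scored).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @param atom_subset Optional integer indices (into the retained atom table)
#'   of atoms whose areas are wanted; all retained atoms still occlude. Saves
#'   work when only a few side-chain atoms matter.
#' @return data.frame of the scored atoms with an `area` column (A^2);
#'   attribute `total` holds the summed area.
#' @export
sasa <- function(model, chains = NULL, probe = 1.4, n_points = 960L,
                 atom_subset = NULL) {
  atoms <- if (inherits(model, "structure_model"))
    atoms_of(model, chains) else as.data.frame(model)
  if (!nrow(atoms)) stop_invalid("no atoms to compute SASA for")
  radii <- element_radius(atoms$element) + probe
  pts <- fibonacci_sphere(as.integer(n_points))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  idx <- atom_subset %||% seq_len(nrow(atoms))
  area <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    ri <- radii[i]
    ci <- xyz[i, ]
    # neighbours whose probe-inflated spheres can intersect atom i's
    d2 <- (xyz[, 1] - ci[1])^2 + (xyz[, 2] - ci[2])^2 + (xyz[, 3] - ci[3])^2
    nb <- which(d2 < (ri + radii)^2 & d2 > 1e-12)
    if (!length(nb)) {
      area[k] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2L, ci, `+`)          # n_points x 3 surface points
    acc <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (sp[acc, 1] - xyz[j, 1])^2 + (sp[acc, 2] - xyz[j, 2])^2 +
             (sp[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= radii[j]^2
    }
    area[k] <- 4 * pi * ri^2 * mean(acc)
  }
  out <- atoms[idx, , drop = FALSE]
  out$area <- area
  attr(out, "total") <- sum(area)
  out
}

#' Total SASA of a model or chain subset
#' @inheritParams sasa
#' @return Single numeric total in A^2.
#' @export
sasa_total <- function(model, chains = NULL, probe = 1.4, n_points = 960L) {
  attr(sasa(model, chains, probe, n_points), "total")
}
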
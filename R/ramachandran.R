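# Ramachandran region classification.
#
# The published high-resolution density tables are not redistributable here,
# so the packaged density is a SYNTHETIC stand-in: a mixture of wrapped 2-D
# Gaussians centred on the canonical basins of each residue class (beta/PPII,
# right-handed alpha, left-handed alpha, and the glycine-specific mirror
# basins). Classification thresholds are fractions of the mixture evaluated
# at the query angle. The stand-in reproduces the canonical qualitative
# behaviour (alpha and beta cores favored for general residues; the
# left-handed region accessible to glycine but an outlier for general
# residues), which is what region labels are used for downstream.

RAMA_BASINS <- list(
  general = data.frame(
    phi = c(-118, -63, 57),
    psi = c( 132, -43, 42),
    sphi = c(38, 22, 13), spsi = c(38, 22, 13),
    w = c(0.45, 0.50, 0.05)),
  glycine = data.frame(
    phi = c(-85, 85, -63, 63, -170, 170),
    psi = c(170, -170, -41, 41, 170, -170),
    sphi = c(35, 35, 28, 28, 30, 30), spsi = c(30, 30, 28, 28, 30, 30),
    w = c(0.25, 0.25, 0.17, 0.17, 0.08, 0.08)),
  proline = data.frame(
    phi = c(-63, -63),
    psi = c(150, -30),
    sphi = c(15, 15), spsi = c(30, 25),
    w = c(0.55, 0.45)),
  `pre-proline` = data.frame(
    phi = c(-120, -63, 50),
    psi = c( 135, -35, 40),
    sphi = c(35, 20, 12), spsi = c(35, 22, 12),
    w = c(0.55, 0.40, 0.05))
)

# favored/allowed thresholds on the mixture density, per class; fractions of
# the densest basin peak so the labels behave like contour levels
RAMA_THRESHOLDS <- list(
  general = c(favored = 0.12, allowed = 0.005),
  glycine = c(favored = 0.10, allowed = 0.005),
  proline = c(favored = 0.12, allowed = 0.005),
  `pre-proline` = c(favored = 0.12, allowed = 0.005)
)

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

rama_density <- function(phi, psi, residue_class) {
  b <- RAMA_BASINS[[residue_class]]
  dens <- 0
  for (k in seq_len(nrow(b))) {
    dphi <- ang_diff(phi, b$phi[k]) / b$sphi[k]
    dpsi <- ang_diff(psi, b$psi[k]) / b$spsi[k]
    dens <- dens + b$w[k] * exp(-0.5 * (dphi^2 + dpsi^2)) /
      (2 * pi * b$sphi[k] * b$spsi[k])
  }
  dens
}

rama_peak <- function(residue_class) {
  b <- RAMA_BASINS[[residue_class]]
  max(vapply(seq_len(nrow(b)), function(k)
    rama_density(b$phi[k], b$psi[k], residue_class), numeric(1)))
}

#' Classify a backbone conformation on the Ramachandran map
#'
#' @param phi,psi Backbone dihedrals in degrees; values outside `(-180, 180]`
#'   are wrapped into range.
#' @param residue_class One of `"general"`, `"glycine"`, `"proline"`,
#'   `"pre-proline"`.
#' @return `"favored"`, `"allowed"` or `"outlier"` (vectorized over
#'   `phi`/`psi`).
#' @export
#' @examples
#' ramachandran_class(-63, -43)            # alpha core: favored
#' ramachandran_class(-139, 135)           # beta core: favored
#' ramachandran_class(75, 5)               # general: outlier
#' ramachandran_class(75, 5, "glycine")    # glycine tolerates it
ramachandran_class <- function(phi, psi,
                               residue_class = c("general", "glycine",
                                                 "proline", "pre-proline")) {
  residue_class <- match.arg(residue_class)
  phi <- wrap_angle(as.numeric(phi))
  psi <- wrap_angle(as.numeric(psi))
  dens <- rama_density(phi, psi, residue_class)
  peak <- rama_peak(residue_class)
  thr <- RAMA_THRESHOLDS[[residue_class]]
  ifelse(dens >= thr[["favored"]] * peak, "favored",
         ifelse(dens >= thr[["allowed"]] * peak, "allowed", "outlier"))
}

#' Backbone dihedral angles of a chain
#'
#' Computes phi/psi from the model's backbone atoms (NA at chain termini) so
#' parsed structures can be classified directly.
#'
#' @param model A [structure_model].
#' @param chain Chain id.
#' @return data.frame `res_seq`, `res_name`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(model, chain) {
  bt <- backbone_table(model, chain)
  n <- length(bt$res_seq)
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- bt$bb[[i]]
    if (i > 1L && bt$res_seq[i - 1L] == bt$res_seq[i] - 1L) {
      prev <- bt$bb[[i - 1L]]
      phi[i] <- dihedral(prev$C, b$N, b$CA, b$C)
    }
    if (i < n && bt$res_seq[i + 1L] == bt$res_seq[i] + 1L) {
      nxt <- bt$bb[[i + 1L]]
      psi[i] <- dihedral(b$N, b$CA, b$C, nxt$N)
    }
  }
  res <- chain_residues(model, chain)
  keep <- match(bt$res_seq, res$res_seq)
  data.frame(res_seq = bt$res_seq, res_name = res$res_name[keep],
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}
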
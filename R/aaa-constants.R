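# Shared constants: amino-acid alphabet, hydrophobicity scale, atomic radii,
# side-chain exposure references. Kept in one place so every module agrees.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ACIDIC_RESIDUES <- c("D", "E")

AA3_TO_1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)

#' Kyte-Doolittle hydropathy scale
#'
#' Published per-residue hydropathy values (positive = hydrophobic), used to
#' annotate receptor surfaces the way interface figures color them.
#'
#' @format Named numeric vector over the 20 standard one-letter codes.
#' @references Kyte J, Doolittle RF (1982) J Mol Biol 157:105-132.
#' @export
kyte_doolittle <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Van der Waals radii by element (Bondi 1964 values for the elements that
# occur in protein models); unknown elements fall back to carbon with a warning.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, SE = 1.90, F = 1.47, CL = 1.75
)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface area per residue (Tien et al. 2013,
# PLoS ONE 8:e80635, "theoretical" column). The side-chain reference used for
# relative burial subtracts the glycine value as a backbone proxy; approximate
# by construction, and burial fractions are clamped to [0, 1].
MAX_ASA_TOTAL <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0
)

max_sidechain_asa <- function(res1) {
  ref <- MAX_ASA_TOTAL[res1] - MAX_ASA_TOTAL[["G"]]
  # glycine: Calpha proxy side chain, small reference
  ref[res1 == "G"] <- 25.0
  unname(ref)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# ---- small shared helpers ----------------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of their
#' seed argument and never disturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
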
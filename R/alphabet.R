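#' The standard amino-acid alphabet
#'
#' One-letter codes for the 20 standard amino acids in the fixed order
#' A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V. All column-count vectors,
#' PSSM columns and generator draws index this order, so results are
#' deterministic across platforms.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# one-letter <-> three-letter residue names (PDB convention)
AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# residues treated as nonstandard in alignment columns (never counted
# as one of the 20)
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O", "J", "*")

#' Hydropathy classification schemes
#'
#' Returns the residue classification used for hydrophobic-surface and
#' interface analysis. The default `"phi"` scheme follows the convention
#' used for phycobilisome binding-surface annotation: the hydrophobic set
#' \eqn{\phi} = \{A, V, L, I, M, F, W, C, Y\} with the aromatic subset
#' \eqn{\Omega} = \{Y, F, W\}. The `"kd"` alternative classifies residues
#' with positive Kyte–Doolittle hydropathy as hydrophobic.
#'
#' @param name Scheme id, `"phi"` (default) or `"kd"`.
#' @return A tibble with columns `residue` (one-letter code), `class`
#'   (`"hydrophobic"` or `"other"`) and `aromatic` (logical).
#' @examples
#' hydropathy_scheme("phi")
#' @export
hydropathy_scheme <- function(name = c("phi", "kd")) {
  name <- match.arg(name)
  hydro <- switch(name,
    phi = c("A", "V", "L", "I", "M", "F", "W", "C", "Y"),
    kd  = c("I", "V", "L", "F", "C", "M", "A")
  )
  tibble::tibble(
    residue = AA_ALPHABET,
    class = ifelse(AA_ALPHABET %in% hydro, "hydrophobic", "other"),
    aromatic = AA_ALPHABET %in% c("Y", "F", "W")
  )
}

# Theoretical maximum SASA (A^2) per residue in a Gly-X-Gly tripeptide
# (Tien et al. 2013, theoretical values); used for relative SASA.
MAX_SASA_GXG <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

#' Default van der Waals radii for SASA calculations
#'
#' Element radii in angstrom with a `.default` fallback for elements not
#' listed. Pass a modified copy to [sasa()] to change the parameterisation.
#'
#' @format Named numeric vector (angstrom).
#' @export
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               H = 1.20, P = 1.80, .default = 1.80)
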
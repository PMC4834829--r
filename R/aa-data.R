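# Amino-acid lookup tables shared across modules.

# three-letter -> one-letter, 20 standard residues
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# common modified residues mapped to their standard parent; anything not
# listed here (and not standard) is skipped with a warning at parse time
MODIFIED_PARENT <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  CME = "CYS", CSX = "CYS", HYP = "PRO", MLY = "LYS", KCX = "LYS",
  PCA = "GLU", SEC = "CYS", PYL = "LYS", FME = "MET"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Eight physicochemical categories used by the sequence-component descriptor:
# A aliphatic, B aromatic, C hydroxyl, D acidic, E acid amide, F basic,
# G sulphur, H cyclic.
SC_CATEGORY <- c(
  G = "A", A = "A", V = "A", L = "A", I = "A",
  F = "B", Y = "B", W = "B",
  S = "C", T = "C",
  D = "D", E = "D",
  N = "E", Q = "E",
  R = "F", K = "F", H = "F",
  C = "G", M = "G",
  P = "H"
)

# backbone atom names excluded from the side-chain geometric center
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Physicochemical category of a residue
#'
#' Maps a one-letter amino-acid code to one of eight physicochemical
#' categories: A aliphatic (G, A, V, L, I), B aromatic (F, Y, W),
#' C hydroxyl (S, T), D acidic (D, E), E acid amide (N, Q),
#' F basic (R, K, H), G sulphur (C, M), H cyclic (P).
#'
#' @param aa1 character vector of one-letter amino-acid codes.
#' @return character vector of category letters ("A"-"H").
#' @examples
#' residue_category(c("G", "P", "R"))
#' @export
residue_category <- function(aa1) {
  bad <- setdiff(unique(aa1), names(SC_CATEGORY))
  if (length(bad) > 0) {
    stop("unknown one-letter residue code(s): ", paste(bad, collapse = ", "))
  }
  unname(SC_CATEGORY[aa1])
}
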
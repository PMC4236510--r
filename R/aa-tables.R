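# Amino-acid constant tables: one-letter alphabet, Kyte-Doolittle hydropathy,
# average residue masses, and side-chain/terminal pKa sets for pI computation.

#' The 20 standard amino acids (one-letter codes)
#' @keywords internal
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Allowed residue alphabet (standard 20 plus ambiguity code X)
#' @keywords internal
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices of Kyte & Doolittle; `X` is scored 0
#' (indifferent).
#' @keywords internal
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0
)

# Average (isotope-averaged) residue masses in Daltons; a free peptide adds
# one water mass.
AA_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MASS_WATER <- 18.01524

# pKa sets used by compute_pi(). "bjellqvist" is the default (the set behind
# the common ExPASy-style pI); "emboss" is the EMBOSS iep set.
PKA_SETS <- list(
  bjellqvist = list(
    nterm = 7.50, cterm = 3.55,
    acidic = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
    basic  = c(H = 5.98, K = 10.00, R = 12.00)
  ),
  emboss = list(
    nterm = 8.60, cterm = 3.60,
    acidic = c(D = 3.90, E = 4.10, C = 8.50, Y = 10.10),
    basic  = c(H = 6.50, K = 10.80, R = 12.50)
  )
)

# residue groups used throughout
AA_CHARGED <- c("D", "E", "K", "R")     # H excluded: ambiguous protonation
AA_ACIDIC <- c("D", "E")
AA_BASIC <- c("K", "R")
AA_SMALL_POLAR <- c("G", "A", "S", "T", "C")  # helix-interface group set
AA_TM_BACKGROUND <- c("I", "L", "V")          # strongly hydrophobic TM core

# split a residue string into a character vector
split_residues <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
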
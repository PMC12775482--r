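# Field-standard constant tables. All scales are documented package constants
# so that results are reproducible bit-for-bit.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in alphabetical one-letter order. This ordering
#' fixes the token indices used throughout the package: PAD is index 0 and the
#' residues occupy indices 1 to 20 in this order.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Average amino-acid frequencies in nature
#'
#' Swiss-Prot average composition, normalised to sum to one. Used as the
#' default reference for IceLogo fold-change normalisation in "natural" mode.
#'
#' @format A named numeric vector over [AA_ALPHABET].
#' @export
NATURAL_AA_FREQS <- local({
  f <- c(A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  f / sum(f)
})

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

# Per-residue solubility (protein-interaction) values used for the Boman
# index: water-to-cyclohexane transfer free energies with inverted sign, in
# kcal/mol; proline has no measured value in the underlying scale and is
# assigned zero.
BOMAN_SCALE <- c(L = -4.92, I = -4.92, V = -4.04, F = -2.98, M = -2.35,
                 W = -2.33, A = -1.81, C = -1.28, G = -0.94, Y = 0.14,
                 P = 0.00, T = 2.57, S = 3.40, H = 4.66, Q = 5.54,
                 K = 5.55, N = 6.64, E = 6.81, D = 8.72, R = 14.92)

# EMBOSS-style pKa values for net-charge and isoelectric-point calculation
PKA_SET <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# IceLogo residue colour classes (hydrophobic aromatic, other hydrophobic,
# hydrophilic, acidic, basic)
AA_COLOR_CLASS <- c(
  F = "hydrophobic_aromatic", W = "hydrophobic_aromatic", Y = "hydrophobic_aromatic",
  A = "hydrophobic", I = "hydrophobic", L = "hydrophobic", M = "hydrophobic",
  P = "hydrophobic", V = "hydrophobic", G = "hydrophobic",
  C = "hydrophilic", N = "hydrophilic", Q = "hydrophilic", S = "hydrophilic",
  T = "hydrophilic",
  D = "acidic", E = "acidic", H = "acidic",
  K = "basic", R = "basic"
)
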
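# Physicochemical constant tables. All values are published reference data;
# sources are cited per table. Row/column order is the fixed alphabet below.

# The 20 standard amino acids, one-letter code, alphabetical.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte & Doolittle (1982) J Mol Biol 157:105 hydropathy scale.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Monoisotopic residue masses (Da), IUPAC standard values; water is added once
# per chain for the free termini.
MONO_MASS <- c(
  A =  71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G =  57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P =  97.05276, Q = 128.05858, R = 156.10111,
  S =  87.03203, T = 101.04768, V =  99.06841, W = 186.07931, Y = 163.06333
)
MASS_WATER <- 18.01056

# Built-in modification monoisotopic masses (Da). iTRAQ8 is the 8-plex
# isobaric tag added to free amines (protein/peptide N-terminus and lysine).
MOD_MASS <- c(iTRAQ8 = 304.2054, Oxidation = 15.9949, Acetyl = 42.0106)

# N-end-rule half-lives by N-terminal residue (ProtParam's lookup).
# Entries published as bounds (">20 h", ">10 h") are stored as the bound with
# `HALF_LIFE_IS_BOUND` flagging them.
HALF_LIFE_H <- list(
  mammalian = c(A = 4.4, C = 1.2, D = 1.1, E = 1.0, F = 1.1, G = 30, H = 3.5,
                I = 20, K = 1.3, L = 5.5, M = 30, N = 1.4, P = 20, Q = 0.8,
                R = 1.0, S = 1.9, T = 7.2, V = 100, W = 2.8, Y = 2.8),
  yeast     = c(A = 20, C = 20, D = 3 / 60, E = 30 / 60, F = 3 / 60, G = 20,
                H = 10 / 60, I = 30 / 60, K = 3 / 60, L = 3 / 60, M = 20,
                N = 3 / 60, P = 20, Q = 10 / 60, R = 2 / 60, S = 20, T = 20,
                V = 20, W = 3 / 60, Y = 10 / 60),
  ecoli     = c(A = 10, C = 10, D = 10, E = 10, F = 2 / 60, G = 10, H = 10,
                I = 10, K = 2 / 60, L = 2 / 60, M = 10, N = 10, P = 10,
                Q = 10, R = 2 / 60, S = 10, T = 10, V = 10, W = 2 / 60,
                Y = 2 / 60)
)
HALF_LIFE_IS_BOUND <- list(
  mammalian = c(P = TRUE),
  yeast     = c(A = TRUE, C = TRUE, G = TRUE, M = TRUE, P = TRUE, S = TRUE,
                T = TRUE, V = TRUE),
  ecoli     = c(A = TRUE, C = TRUE, D = TRUE, E = TRUE, G = TRUE, H = TRUE,
                I = TRUE, M = TRUE, N = TRUE, P = TRUE, Q = TRUE, S = TRUE,
                T = TRUE, V = TRUE)
)

# Bjellqvist pKa set as used by ProtParam: side chains, C-terminus, and the
# residue-dependent alpha-amino pKa (generic 7.5 unless overridden).
PKA_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_CTERM <- 3.55
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM_BY_RES <- c(A = 7.59, E = 7.70, G = 7.50, M = 7.00, P = 8.36,
                      S = 6.93, T = 6.82, V = 7.44)

# Residue polarity classes used for helical-wheel summaries. Aromatics
# (F, W, Y) are classed nonpolar.
RESIDUE_CLASS <- c(
  K = "polar-basic", R = "polar-basic", H = "polar-basic",
  D = "polar-acidic", E = "polar-acidic",
  S = "polar-uncharged", T = "polar-uncharged", N = "polar-uncharged",
  Q = "polar-uncharged", C = "polar-uncharged",
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", M = "nonpolar", F = "nonpolar",
  W = "nonpolar", Y = "nonpolar"
)
RESIDUE_CLASS_LEVELS <- c("nonpolar", "polar-uncharged", "polar-basic",
                          "polar-acidic")

# Guruprasad, Reddy & Pandit (1990) Protein Eng 4:155 dipeptide instability
# weight values (DIWV); rows = first residue, columns = second residue.
DIWV <- matrix(c(
  1,44.94,-7.49,1,1,1,-7.49,1,1,1,1,1,20.26,1,1,1,1,1,1,1,
  1,1,20.26,1,1,1,33.6,1,1,20.26,33.6,1,20.26,-6.54,1,1,33.6,-6.54,24.68,1,
  1,1,1,1,-6.54,1,1,1,-7.49,1,1,1,1,1,-6.54,20.26,-14.03,1,1,1,
  1,44.94,20.26,33.6,1,1,-6.54,20.26,1,1,1,1,20.26,20.26,1,20.26,1,1,-14.03,1,
  1,1,13.34,1,1,1,1,1,-14.03,1,1,1,20.26,1,1,1,1,1,1,33.601,
  -7.49,1,1,-6.54,1,13.34,1,-7.49,-7.49,1,1,-7.49,1,1,1,1,-7.49,1,13.34,-7.49,
  1,1,1,1,-9.37,-9.37,1,44.94,24.68,1,1,24.68,-1.88,1,1,1,-6.54,1,-1.88,44.94,
  1,1,1,44.94,1,1,13.34,1,-7.49,20.26,1,1,-1.88,1,1,1,1,-7.49,1,1,
  1,1,1,1,1,-7.49,1,-7.49,1,-7.49,33.6,1,-6.54,24.64,33.6,1,1,-7.49,1,1,
  1,1,1,1,1,1,1,1,-7.49,1,1,1,20.26,33.6,20.26,1,1,1,24.68,1,
  13.34,1,1,1,1,1,58.28,1,1,1,-1.88,1,44.94,-6.54,-6.54,44.94,-1.88,1,1,24.68,
  1,-1.88,1,1,-14.03,-14.03,1,44.94,24.68,1,1,1,-1.88,-6.54,1,1,-7.49,1,-9.37,1,
  20.26,-6.54,-6.54,18.38,20.26,1,1,1,1,1,-6.54,1,20.26,20.26,-6.54,20.26,1,20.26,-1.88,1,
  1,-6.54,20.26,20.26,-6.54,1,1,1,1,1,1,1,20.26,20.26,1,44.94,1,-6.54,1,-6.54,
  1,1,1,1,1,-7.49,20.26,1,1,1,1,13.34,20.26,20.26,58.28,44.94,1,1,58.28,-6.54,
  1,33.6,1,20.26,1,1,1,1,1,1,1,1,44.94,20.26,20.26,20.26,1,1,1,1,
  1,1,1,20.26,13.34,-7.49,1,1,1,1,1,-14.03,1,-6.54,1,1,1,1,-14.03,1,
  1,1,-14.03,1,1,-7.49,1,1,-1.88,1,1,1,20.26,1,1,1,-7.49,1,1,-6.54,
  -14.03,1,1,1,1,-9.37,24.68,1,1,13.34,24.68,13.34,1,1,1,1,-14.03,-7.49,1,1,
  24.68,1,24.68,-6.54,1,-7.49,13.34,1,1,1,44.94,1,13.34,1,-15.91,1,-7.49,1,-9.37,13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Uniform background residue composition for the simulator; a vertebrate
# average (Swiss-Prot frequencies, rounded) is offered as an option.
AA_FREQ_UNIFORM <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
AA_FREQ_VERTEBRATE <- c(
  A = 0.0826, C = 0.0139, D = 0.0546, E = 0.0672, F = 0.0387,
  G = 0.0708, H = 0.0228, I = 0.0593, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0664, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)

#' Validate a vector of peptide/protein sequences
#'
#' Checks that every sequence is a non-empty string over the 20 standard
#' one-letter amino-acid codes. Ambiguity and non-standard codes
#' (B, J, O, U, X, Z) are rejected.
#'
#' @param sequences Character vector of sequences.
#' @param what Label used in error messages.
#' @return The sequences, invisibly, uppercased.
#' @keywords internal
validate_sequences <- function(sequences, what = "sequence") {
  if (!is.character(sequences)) {
    stop(what, " must be a character vector", call. = FALSE)
  }
  sequences <- toupper(sequences)
  bad_empty <- which(is.na(sequences) | nchar(sequences) == 0L)
  if (length(bad_empty)) {
    stop(what, " at position ", bad_empty[1], " is empty or NA", call. = FALSE)
  }
  bad <- which(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                     sequences))
  if (length(bad)) {
    i <- bad[1]
    chars <- setdiff(strsplit(sequences[i], "")[[1]], AA_ALPHABET)
    stop(what, " at position ", i, " ('", sequences[i],
         "') contains invalid residue letter(s): ",
         paste(chars, collapse = ", "), call. = FALSE)
  }
  invisible(sequences)
}
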
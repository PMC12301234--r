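# Shared sequence constants: alphabets, codon usage, residue scales.

#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# CDR randomization alphabet. N, D and C are excluded so that randomly drawn
# CDRs are free of deamidation/isomerization/glycosylation/unpaired-cysteine
# motifs by construction (the library-design screen is then exact on planted
# liabilities); W is reserved for the planted binder motif so that binder
# labels are separable in descriptor space.
#' @keywords internal
AA_CDR_SAFE <- c("A", "E", "F", "G", "H", "I", "K", "L",
                 "M", "P", "Q", "R", "S", "T", "V", "Y")

# Kyte-Doolittle hydropathy index.
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Side-chain charge at pH 7 used by the net-charge descriptor.
#' @keywords internal
AA_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0.1)

# One representative + alternates per amino acid (E. coli-biased), used for
# back-translation of designed protein sequences.
#' @keywords internal
CODON_CHOICES <- list(
  A = c("GCT", "GCA", "GCC"),
  C = c("TGC", "TGT"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTC", "TTT"),
  G = c("GGT", "GGC"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC"),
  K = c("AAA", "AAG"),
  L = c("CTG", "CTC"),
  M = "ATG",
  N = c("AAT", "AAC"),
  P = c("CCG", "CCA"),
  Q = c("CAG", "CAA"),
  R = c("CGT", "CGC"),
  S = c("TCT", "AGC"),
  T = c("ACC", "ACA"),
  V = c("GTT", "GTG"),
  W = "TGG",
  Y = c("TAT", "TAC")
)

# Amplicon anchor immediately upstream of FR1 in the display construct.
#' @keywords internal
PHIS4_ANCHOR <- "GCGGATAACAATTTGAATTCAAGGAGACAG"

#' Default amplicon anchor sequence
#'
#' Nucleotide anchor located immediately upstream of the VHH coding region in
#' the phagemid amplicon; reads are oriented and trimmed relative to its first
#' occurrence (forward strand searched first, then the reverse complement).
#'
#' @return A single nucleotide string.
#' @export
#' @examples
#' default_anchor()
default_anchor <- function() PHIS4_ANCHOR

# Region order used throughout.
#' @keywords internal
REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
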
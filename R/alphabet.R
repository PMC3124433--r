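#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, in the conventional alphabetical
#' order of the codes themselves.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Ambiguity and non-standard residue letters
#'
#' Letters that may occur in protein databases but do not denote one of the 20
#' standard residues (B, Z, J ambiguity codes; U selenocysteine, O
#' pyrrolysine, X unknown). These letters break homopolymer runs, count
#' towards protein length, and contribute to no standard-residue frequency.
#'
#' @format Character vector of length 6.
#' @export
AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' Typical proteome-wide amino-acid frequencies
#'
#' Average residue frequencies of well-curated protein databases, used as the
#' default base composition of the synthetic proteome generator. Leucine is
#' the most frequent residue, tryptophan the rarest.
#'
#' @format Named numeric vector over [AA_STANDARD], summing to 1.
#' @export
AA_BASE_FREQ <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292
)
AA_BASE_FREQ <- AA_BASE_FREQ / sum(AA_BASE_FREQ)

check_residue <- function(residue) {
  if (!(is.character(residue) && length(residue) == 1L &&
        nchar(residue) == 1L && residue %in% AA_STANDARD)) {
    stop("'residue' must be a single standard amino-acid letter, got: ",
         deparse(residue), call. = FALSE)
  }
  invisible(residue)
}
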
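## 20 canonical amino acids; gap "-"; "X" allowed in decoys only.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes used throughout the
#' package. The gap character is `"-"`; `"X"` denotes an unknown residue
#' and is permitted only in decoy sequences.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcidAlphabet()
aminoAcidAlphabet <- function() AA20
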
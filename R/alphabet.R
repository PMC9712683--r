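#' Amino-acid alphabets and residue groupings
#'
#' Fixed orderings used throughout the package: the 20 standard residues in
#' alphabetical order (feature naming for composition encoders), the
#' PSI-BLAST profile column order, and the five physicochemical residue
#' groups behind the grouped amino-acid composition encoder.
#'
#' @format `aa_alphabet` and `pssm_column_order` are length-20 character
#'   vectors; `gaac_groups` is a named list of five character vectors that
#'   partition the alphabet.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabets
#' @export
pssm_column_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname alphabets
#' @export
gaac_groups <- list(
  G1 = c("A", "G", "L", "I", "M", "V"),  # aliphatic
  G2 = c("D", "E"),                      # negatively charged
  G3 = c("F", "W", "Y"),                 # aromatic
  G4 = c("H", "R", "K"),                 # positively charged
  G5 = c("C", "N", "P", "Q", "S", "T")   # uncharged
)

# Ambiguity / non-standard one-letter codes removed (or rejected) during
# sequence validation.
nonstandard_letters <- c("B", "J", "O", "U", "X", "Z")
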
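#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order
#' (`A, C, D, ..., Y`).  This fixed order defines the row index `k = 1..20`
#' used everywhere in the package: the one-hot spin encoding of a residue,
#' the rows of 20 x Gamma bias/weight/probability tables, and the
#' observation order of the weight PCA.
#'
#' @format A character vector of length 20.
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Map residues to alphabet indices
#'
#' @param residues Character vector of one-letter codes (single characters).
#' @returns Integer vector of indices into [aa_alphabet]; an error names the
#'   first non-canonical symbol.
#' @keywords internal
aa_index <- function(residues) {
  idx <- match(residues, aa_alphabet)
  if (anyNA(idx)) {
    bad <- unique(residues[is.na(idx)])
    stop("non-canonical residue symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

# Visible-unit index of residue k in block gamma (1-based): i = 20*(gamma-1) + k.
visible_index <- function(gamma, k) 20L * (gamma - 1L) + k

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
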
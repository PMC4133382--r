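#' The 21-symbol residue alphabet
#'
#' The 20 standard amino acids in alphabetical order of their one-letter
#' codes, followed by the dummy residue `X` used to pad windows that run past
#' a protein terminus. Residues are coded numerically by their position in
#' this vector (`A` = 1, ..., `Y` = 20, `X` = 21); all dipeptide indexing is
#' derived from these codes.
#'
#' @format A character vector of length 21.
#' @export
#' @examples
#' nitro_alphabet()
nitro_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

#' Numeric code of a residue symbol
#'
#' @param x Character vector of single-letter residue symbols.
#' @return Integer vector of codes in `1..21`.
#' @export
#' @examples
#' residue_code(c("A", "Y", "X"))
residue_code <- function(x) {
  code <- match(x, nitro_alphabet())
  if (anyNA(code)) {
    bad <- unique(x[is.na(code)])
    stop_data("unknown residue symbol(s): %s", paste(bad, collapse = ", "))
  }
  code
}

# n x (2l+1) integer code matrix from equal-length peptide strings
peptide_codes <- function(peptides, half_width) {
  len <- 2L * half_width + 1L
  if (any(nchar(peptides) != len)) {
    stop_contract("all peptides must have length %d (2*half_width + 1)", len)
  }
  chars <- strsplit(peptides, "", fixed = TRUE)
  m <- matrix(residue_code(unlist(chars)), nrow = length(peptides), byrow = TRUE)
  if (any(m[, half_width + 1L] != 20L)) {
    stop_contract("every peptide must have Y at its center")
  }
  m
}

# Infer and validate the half-width l of a set of window peptides
infer_half_width <- function(peptides) {
  len <- unique(nchar(peptides))
  if (length(len) != 1L) stop_contract("peptides have inconsistent lengths")
  if (len %% 2L == 0L || len < 3L) {
    stop_contract("peptide length must be odd and >= 3, got %d", len)
  }
  as.integer((len - 1L) / 2L)
}
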
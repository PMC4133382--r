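#' Index of an ordered residue pair
#'
#' Maps an ordered pair of residue symbols to its row in a propensity matrix,
#' using the row-major convention over the numeric residue codes:
#' `(code(a) - 1) * 21 + code(b)`. This is a bijection between the 441
#' ordered pairs of the 21-symbol alphabet and `1..441`.
#'
#' @param a,b Character vectors of single-letter residue symbols (recycled).
#' @return Integer vector of dipeptide indices in `1..441`.
#' @export
#' @examples
#' dipeptide_index("A", "A") # 1
#' dipeptide_index("X", "X") # 441
dipeptide_index <- function(a, b) {
  (residue_code(a) - 1L) * 21L + residue_code(b)
}

#' Dipeptide indices at each subsite of a window
#'
#' A window of `2l + 1` residues has `2l` dipeptide subsites: the overlapping
#' adjacent residue pairs read left to right. Subsite `j` is the ordered pair
#' of window positions `j` and `j + 1` (1-based), so subsites `l` and `l + 1`
#' both contain the central tyrosine.
#'
#' @param peptides Character vector of equal-length window peptides with Y at
#'   the center.
#' @return An integer matrix with one row per peptide and `2l` columns of
#'   dipeptide indices.
#' @export
#' @examples
#' subsite_dipeptides("AYC") # 20 (A,Y) and 401 (Y,C)
subsite_dipeptides <- function(peptides) {
  hw <- infer_half_width(peptides)
  codes <- peptide_codes(peptides, hw)
  w <- 2L * hw
  (codes[, 1:w, drop = FALSE] - 1L) * 21L + codes[, 2:(w + 1L), drop = FALSE]
}

# Encode peptides for a given encoder: a list with the per-sample state-index
# matrix (n x 2l) and the number of states per subsite (441 or 21).
encode_windows <- function(peptides, half_width, encoder = c("dipeptide", "single")) {
  encoder <- match.arg(encoder)
  codes <- peptide_codes(peptides, half_width)
  w <- 2L * half_width
  if (encoder == "dipeptide") {
    idx <- (codes[, 1:w, drop = FALSE] - 1L) * 21L + codes[, 2:(w + 1L), drop = FALSE]
    list(idx = idx, n_states = 441L)
  } else {
    idx <- codes[, -(half_width + 1L), drop = FALSE]
    list(idx = idx, n_states = 21L)
  }
}

# n_states x 2l integer count matrix from an encoded index matrix
count_matrix <- function(idx, n_states) {
  vapply(seq_len(ncol(idx)), function(j) tabulate(idx[, j], n_states),
         integer(n_states))
}

# Sum over subsites of matrix entries looked up at each sample's indices.
# M is n_states x 2l; idx is n x 2l; returns a length-n numeric vector.
lookup_sum <- function(idx, M) {
  lin <- idx + matrix((seq_len(ncol(idx)) - 1L) * nrow(M),
                      nrow = nrow(idx), ncol = ncol(idx), byrow = TRUE)
  # index with a plain vector: an n x 2 index matrix would otherwise be
  # read as (row, col) coordinate pairs
  rowSums(matrix(M[as.vector(lin)], nrow = nrow(idx)))
}

new_propensity_matrix <- function(freq, counts, half_width, class_tag, encoder,
                                  sample_count) {
  structure(freq,
            counts = counts,
            half_width = half_width,
            class_tag = class_tag,
            encoder = encoder,
            sample_count = sample_count,
            class = c("propensity_matrix", class(freq)))
}

propensity_from_peptides <- function(peptides, half_width, class_tag, encoder,
                                     pseudocount = 0) {
  if (length(peptides) == 0L) stop_data("cannot estimate a propensity matrix from zero peptides")
  if (is.null(half_width)) half_width <- infer_half_width(peptides)
  if (any(nchar(peptides) != 2L * half_width + 1L)) {
    stop_contract("peptides do not match half_width %d", half_width)
  }
  enc <- encode_windows(peptides, half_width, encoder)
  counts <- count_matrix(enc$idx, enc$n_states)
  n <- length(peptides)
  freq <- (counts + pseudocount) / (n + pseudocount * enc$n_states)
  new_propensity_matrix(freq, counts, half_width, class_tag, encoder, n)
}

#' Position-specific dipeptide propensity (PSDP) matrix
#'
#' Estimates, for one class of training peptides, the occurrence frequency of
#' each of the 441 ordered residue pairs at each of the `2l` dipeptide
#' subsites. Every peptide contributes exactly one dipeptide per subsite, so
#' each of the `2l` columns sums to 1 (raw relative frequencies; no smoothing
#' unless `pseudocount > 0`).
#'
#' @param peptides Character vector of window peptides, or a benchmark tibble
#'   (in which case the `peptide` column is used).
#' @param class_tag `"positive"` or `"negative"`; recorded on the result.
#' @param half_width Window half-width; inferred from the peptides when `NULL`.
#' @param pseudocount Optional additive smoothing constant per cell
#'   (default 0, the definition used throughout; exposed for robustness
#'   experiments only).
#' @return A `propensity_matrix`: a 441 x `2l` numeric matrix with attributes
#'   `half_width`, `class_tag`, `encoder`, `sample_count` and the raw integer
#'   `counts`.
#' @export
#' @examples
#' z <- compute_psdp(c("AYC", "AYD"), class_tag = "positive")
#' z[dipeptide_index("A", "Y"), 1] # 1.0
#' z[dipeptide_index("Y", "C"), 2] # 0.5
compute_psdp <- function(peptides, class_tag = "positive", half_width = NULL,
                         pseudocount = 0) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  propensity_from_peptides(peptides, half_width, class_tag, "dipeptide", pseudocount)
}

#' Position-specific single-residue propensity matrix (baseline encoder)
#'
#' The single-amino-acid baseline: occurrence frequencies of the 21 residue
#' symbols at each of the `2l` non-central window positions. Used to
#' quantify how much the dipeptide (pairwise-coupling) encoder adds over
#' per-position residue composition alone.
#'
#' @inheritParams compute_psdp
#' @return A `propensity_matrix` of dimension 21 x `2l` with
#'   `encoder = "single"`.
#' @export
#' @examples
#' f <- compute_psap(c("AYC", "AYD"), class_tag = "positive")
#' f[residue_code("A"), 1] # 1.0
compute_psap <- function(peptides, class_tag = "positive", half_width = NULL,
                         pseudocount = 0) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  propensity_from_peptides(peptides, half_width, class_tag, "single", pseudocount)
}

#' Feature vector of a window under a propensity matrix
#'
#' Looks up, for each subsite, the propensity of the dipeptide (or residue,
#' for the single-residue encoder) observed there. Components lie in
#' `[0, 1]`; the hypothetical "ideal" peptide of a class has every component
#' at the upper limit 1.
#'
#' @param peptides Character vector of window peptides.
#' @param matrix A `propensity_matrix` with matching half-width.
#' @return A numeric matrix with one row per peptide and `2l` columns.
#' @export
#' @examples
#' z <- compute_psdp(c("AYC", "AYD"))
#' feature_vector("AYC", z) # 1.0 0.5
feature_vector <- function(peptides, matrix) {
  stopifnot(inherits(matrix, "propensity_matrix"))
  hw <- attr(matrix, "half_width")
  if (infer_half_width(peptides) != hw) {
    stop_contract("peptide half-width does not match the matrix (expected %d)", hw)
  }
  enc <- encode_windows(peptides, hw, attr(matrix, "encoder"))
  lin <- enc$idx + base::matrix((seq_len(ncol(enc$idx)) - 1L) * nrow(matrix),
                                nrow = nrow(enc$idx), ncol = ncol(enc$idx), byrow = TRUE)
  out <- base::matrix(unclass(matrix)[as.vector(lin)], nrow = nrow(enc$idx))
  dimnames(out) <- NULL
  out
}

#' @export
print.propensity_matrix <- function(x, ...) {
  cat(sprintf("<propensity_matrix> %s encoder, class %s: %d x %d (half_width %d, n = %d)\n",
              attr(x, "encoder"), attr(x, "class_tag"),
              nrow(x), ncol(x), attr(x, "half_width"), attr(x, "sample_count")))
  cat(sprintf("  nonzero cells: %d; every column sums to 1\n", sum(x > 0)))
  invisible(x)
}
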
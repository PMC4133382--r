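#' Specify planted position-specific dipeptide enrichments
#'
#' A motif is a set of "plants": at subsite `j` (one of the `2l` adjacent
#' residue-pair positions of the window), the ordered residue pair
#' `(first, second)` overwrites whatever the background drew, independently
#' per peptide with probability `prob`. Plants are applied left-to-right, so
#' a later plant may overwrite one residue of an earlier, overlapping one.
#' A plant touching the central position must keep tyrosine there: at
#' subsite `l` the second residue must be `Y`, at subsite `l + 1` the first
#' must be.
#'
#' @param subsite Integer vector of subsites in `1..2l`.
#' @param first,second Character vectors of residue symbols (the ordered
#'   pair planted at each subsite).
#' @param prob Numeric vector of per-peptide plant probabilities in `[0, 1]`.
#' @return A `motif_spec` tibble with columns `subsite`, `first`, `second`,
#'   `prob`.
#' @export
#' @examples
#' motif_spec(subsite = 1, first = "A", second = "A", prob = 1)
motif_spec <- function(subsite, first, second, prob) {
  out <- tibble(subsite = as.integer(subsite), first = first,
                second = second, prob = as.numeric(prob))
  if (any(out$prob < 0 | out$prob > 1)) stop_contract("plant probabilities must lie in [0, 1]")
  residue_code(out$first)
  residue_code(out$second)
  structure(out, class = c("motif_spec", class(out)))
}

#' Default planted nitration-like motif
#'
#' A fixed, moderate enrichment of charged/acidic residue pairs in the
#' positions flanking the central tyrosine -- the kind of near-site
#' compositional contrast seen between real nitrated and non-nitrated
#' peptides. Used as the default signal of [generate_benchmark()].
#'
#' @param half_width Window half-width (`l >= 2`).
#' @return A `motif_spec`.
#' @export
default_nitration_motif <- function(half_width) {
  if (half_width < 2) stop_contract("the default motif needs half_width >= 2")
  l <- as.integer(half_width)
  motif_spec(
    subsite = c(l - 1L, l, l + 1L, l + 2L),
    first   = c("D",    "E", "Y",    "D"),
    second  = c("E",    "Y", "D",    "K"),
    prob    = c(0.20,   0.30, 0.30,  0.20)
  )
}

check_motif <- function(motif, half_width) {
  if (is.null(motif)) return(invisible(NULL))
  stopifnot(is.data.frame(motif),
            all(c("subsite", "first", "second", "prob") %in% names(motif)))
  l <- half_width
  if (any(motif$subsite < 1L | motif$subsite > 2L * l)) {
    stop_contract("plant subsite out of range 1..%d", 2L * l)
  }
  center_second <- motif$subsite == l & motif$second != "Y"
  center_first <- motif$subsite == l + 1L & motif$first != "Y"
  if (any(center_second | center_first)) {
    stop_contract("a plant covering the central position must place Y there")
  }
  invisible(NULL)
}

#' Generate a synthetic labeled benchmark
#'
#' Draws tyrosine-centered window peptides with flanking residues sampled
#' from a background distribution over the 20 standard amino acids (the
#' dummy residue X never appears: padding is a windowing artifact, not a
#' residue). Negatives are pure background; positives additionally receive
#' the planted dipeptide enrichments of `motif`. The defaults mirror the
#' scale of a realistic nitration benchmark: 1,044 positive and 7,669
#' negative 19-mers.
#'
#' @param n_pos,n_neg Numbers of positive and negative peptides.
#' @param half_width Window half-width (default 9, i.e. 19-mers).
#' @param motif A `motif_spec` of planted enrichments applied to positives,
#'   or `NULL` for no signal. Default: [default_nitration_motif()].
#' @param background Optional length-20 probability vector over the standard
#'   amino acids (alphabetical order); default uniform.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   arguments and the seed.
#' @return A benchmark tibble (`protein_id`, `position`, `peptide`, `label`)
#'   with synthetic ids.
#' @export
#' @examples
#' bench <- generate_benchmark(n_pos = 5, n_neg = 5, half_width = 2,
#'                             motif = NULL, seed = 1)
#' bench
generate_benchmark <- function(n_pos = 1044, n_neg = 7669, half_width = 9,
                               motif = default_nitration_motif(half_width),
                               background = NULL, seed = 1) {
  half_width <- as.integer(half_width)
  if (n_pos < 1 || n_neg < 1) stop_contract("n_pos and n_neg must be >= 1")
  check_motif(motif, half_width)
  aa <- nitro_alphabet()[1:20]
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20 || any(background < 0) || abs(sum(background) - 1) > 1e-8) {
    stop_contract("background must be 20 non-negative probabilities summing to 1")
  }
  len <- 2L * half_width + 1L
  n <- n_pos + n_neg
  withr::with_seed(seed, {
    m <- base::matrix(sample(aa, n * len, replace = TRUE, prob = background),
                      nrow = n, ncol = len)
    m[, half_width + 1L] <- "Y"
    if (!is.null(motif) && n_pos > 0) {
      for (r in seq_len(nrow(motif))) {
        j <- motif$subsite[[r]]
        hit <- which(stats::runif(n_pos) < motif$prob[[r]])
        if (length(hit) > 0) {
          m[hit, j] <- motif$first[[r]]
          m[hit, j + 1L] <- motif$second[[r]]
        }
      }
      m[, half_width + 1L] <- "Y" # plants at the center subsites keep Y by contract
    }
  })
  peptides <- apply(m, 1L, paste, collapse = "")
  tibble(
    protein_id = sprintf("SYN%05d", seq_len(n)),
    position = rep(half_width + 1L, n),
    peptide = peptides,
    label = rep(c("positive", "negative"), c(n_pos, n_neg))
  )
}

#' Generate synthetic annotated proteins
#'
#' Produces full-length protein sequences with designated nitration sites,
#' for exercising the FASTA-to-benchmark path end-to-end (window extraction,
#' padding, labeling, window-size sweeps). Each protein gets `sites_per_protein`
#' designated tyrosines at spaced interior positions; the motif's plants are
#' applied around each designated site (in protein coordinates, using the
#' motif's own `half_width` frame). Background tyrosines occur naturally and
#' become negative windows.
#'
#' @param n_proteins Number of proteins.
#' @param protein_length Residues per protein.
#' @param sites_per_protein Designated (positive) sites per protein.
#' @param motif A `motif_spec` (coordinates in the frame of `half_width`),
#'   or `NULL`.
#' @param half_width The window frame in which `motif` subsites are
#'   interpreted.
#' @param seed Integer seed.
#' @return A list with `proteins` (tibble `id`, `sequence`) and `sites`
#'   (tibble `protein_id`, `position`).
#' @export
generate_annotated_proteins <- function(n_proteins = 50, protein_length = 80,
                                        sites_per_protein = 2,
                                        motif = default_nitration_motif(half_width),
                                        half_width = 9, seed = 1) {
  half_width <- as.integer(half_width)
  check_motif(motif, half_width)
  aa <- nitro_alphabet()[1:20]
  gap <- 2L * half_width + 3L
  lo <- half_width + 2L
  hi <- protein_length - half_width - 1L
  candidates <- seq(lo, hi, by = gap)
  if (length(candidates) < sites_per_protein) {
    stop_contract("protein_length %d too short for %d spaced sites at half_width %d",
                  protein_length, sites_per_protein, half_width)
  }
  withr::with_seed(seed, {
    proteins <- purrr::map_dfr(seq_len(n_proteins), function(i) {
      chars <- sample(aa, protein_length, replace = TRUE)
      sites <- sort(candidates[sample.int(length(candidates), sites_per_protein)])
      chars[sites] <- "Y"
      if (!is.null(motif)) {
        for (r in seq_len(nrow(motif))) {
          j <- motif$subsite[[r]]
          for (p in sites) {
            if (stats::runif(1) < motif$prob[[r]]) {
              a <- p - half_width + j - 1L # protein position of the pair's first residue
              chars[a] <- motif$first[[r]]
              chars[a + 1L] <- motif$second[[r]]
            }
          }
        }
        chars[sites] <- "Y"
      }
      tibble(id = sprintf("SYNPROT%04d", i),
             sequence = paste(chars, collapse = ""),
             sites = list(sites))
    })
  })
  sites <- tibble(
    protein_id = rep(proteins$id, lengths(proteins$sites)),
    position = as.integer(unlist(proteins$sites))
  )
  list(proteins = proteins[c("id", "sequence")], sites = sites)
}
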
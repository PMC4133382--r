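#' Read protein sequences from a FASTA file
#'
#' Parses FASTA text into a tibble of protein records. Sequences are
#' uppercased and whitespace-stripped; letters outside the 21-symbol alphabet
#' (ambiguity codes `B`, `J`, `Z`, the rare residues `O`, `U`, and the gap or
#' stop symbols `-`, `*`) are replaced by the dummy residue `X`, with a single
#' warning reporting how many substitutions were made.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 example", "MKY", ">p2", "YY"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    stop_data("cannot read file: %s", paste(path, collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop_format("empty FASTA input: %s", path)
  first <- nonblank[[1L]]
  if (!startsWith(trimws(lines[[first]]), ">")) {
    stop_format("line %d: sequence data before any FASTA header ('>')", first)
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  seqs <- gsub("[[:space:]]", "", seqs)
  clean <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", seqs)
  n_sub <- sum(nchar(seqs)) - sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, seqs, clean))
  if (n_sub > 0) {
    warn(sprintf("replaced %d non-standard residue(s) by the dummy residue X", n_sub))
  }
  if (any(!nzchar(clean))) stop_format("empty sequence for record '%s'", ids[!nzchar(clean)][1])
  tibble(id = ids, sequence = unname(clean))
}

#' Extract tyrosine-centered peptide windows from proteins
#'
#' Slides a window of `2 * half_width + 1` residues along each protein and
#' keeps exactly the positions where the central residue is tyrosine (Y).
#' Positions that fall outside the protein are padded with the dummy residue
#' `X`, so every tyrosine (including terminal ones) yields one window.
#'
#' @param proteins A data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param half_width Number of residues on each side of the central Y
#'   (an integer `>= 1`); the window length is `2 * half_width + 1`.
#' @return A tibble with one row per tyrosine: `protein_id`, `position`
#'   (1-based site of the central Y in the protein), and `peptide`.
#' @export
#' @examples
#' extract_windows(tibble::tibble(id = "p1", sequence = "MYAY"), half_width = 2)
extract_windows <- function(proteins, half_width) {
  half_width <- as.integer(half_width)
  if (is.na(half_width) || half_width < 1L) {
    stop_contract("half_width must be an integer >= 1")
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  purrr::pmap_dfr(proteins[c("id", "sequence")], function(id, sequence) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (!all(chars %in% nitro_alphabet())) {
      stop_data("protein '%s' contains residues outside the 21-symbol alphabet; read it with read_fasta()", id)
    }
    pos <- which(chars == "Y")
    if (length(pos) == 0L) {
      return(tibble(protein_id = character(), position = integer(), peptide = character()))
    }
    padded <- c(rep("X", half_width), chars, rep("X", half_width))
    pep <- vapply(pos, function(p) {
      paste(padded[p:(p + 2L * half_width)], collapse = "")
    }, character(1))
    tibble(protein_id = id, position = as.integer(pos), peptide = pep)
  })
}

#' Build a labeled benchmark from proteins and annotated nitration sites
#'
#' Extracts every tyrosine-centered window and labels it `"positive"` when
#' its central position is an experimentally annotated nitration site,
#' `"negative"` otherwise. Duplicate peptide strings are retained: propensity
#' estimation is occurrence-based.
#'
#' @inheritParams extract_windows
#' @param sites A data frame of annotated nitrotyrosine sites with columns
#'   `protein_id` and `position` (1-based, must point at a Y).
#' @return A benchmark tibble with columns `protein_id`, `position`,
#'   `peptide`, `label` (`"positive"` / `"negative"`).
#' @export
#' @examples
#' prot <- tibble::tibble(id = "p1", sequence = "MYAY")
#' sites <- tibble::tibble(protein_id = "p1", position = 2)
#' build_benchmark(prot, sites, half_width = 2)
build_benchmark <- function(proteins, sites, half_width) {
  stopifnot(all(c("protein_id", "position") %in% names(sites)))
  missing_ids <- setdiff(unique(sites$protein_id), proteins$id)
  if (length(missing_ids) > 0) {
    stop_data("annotated protein id(s) absent from the protein set: %s",
              paste(missing_ids, collapse = ", "))
  }
  seq_of <- stats::setNames(proteins$sequence, proteins$id)
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[[i]]
    p <- sites$position[[i]]
    s <- seq_of[[pid]]
    if (p < 1 || p > nchar(s) || substr(s, p, p) != "Y") {
      stop_data("annotated site %s:%d is not a tyrosine", pid, p)
    }
  }
  windows <- extract_windows(proteins, half_width)
  key <- paste(windows$protein_id, windows$position)
  site_key <- paste(sites$protein_id, sites$position)
  windows$label <- ifelse(key %in% site_key, "positive", "negative")
  windows
}

# Validate a benchmark-shaped tibble; returns its half-width invisibly
validate_benchmark <- function(benchmark) {
  stopifnot(all(c("peptide", "label") %in% names(benchmark)))
  if (!all(benchmark$label %in% c("positive", "negative"))) {
    stop_contract("benchmark labels must be 'positive' or 'negative'")
  }
  hw <- infer_half_width(benchmark$peptide)
  peptide_codes(benchmark$peptide, hw) # side effect: alphabet + center-Y checks
  invisible(hw)
}
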
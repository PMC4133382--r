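# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the code paths they check: counting is done with
# nested loops and table(), jackknife by explicit model refits, thresholds by
# exhaustive search.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

make_bench <- function(pos, neg) {
  tibble::tibble(
    protein_id = sprintf("T%03d", seq_len(length(pos) + length(neg))),
    position = rep(1L, length(pos) + length(neg)),
    peptide = c(pos, neg),
    label = rep(c("positive", "negative"), c(length(pos), length(neg)))
  )
}

# random Y-centered peptides over the 20 standard residues
random_peptides <- function(n, half_width, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      chars <- sample(AA20, 2 * half_width + 1, replace = TRUE)
      chars[half_width + 1] <- "Y"
      paste(chars, collapse = "")
    }, character(1))
  })
}

random_bench <- function(n_pos, n_neg, half_width, seed) {
  make_bench(random_peptides(n_pos, half_width, seed),
             random_peptides(n_neg, half_width, seed + 10000))
}

# Oracle: occurrence-frequency matrix by explicit per-peptide loops
oracle_psdp <- function(peptides) {
  hw <- (nchar(peptides[1]) - 1) / 2
  m <- matrix(0, 441, 2 * hw)
  for (p in peptides) {
    chars <- strsplit(p, "")[[1]]
    for (j in seq_len(2 * hw)) {
      i <- dipeptide_index(chars[j], chars[j + 1])
      m[i, j] <- m[i, j] + 1
    }
  }
  m / length(peptides)
}

# Oracle: jackknife by explicit refit on the n-1 remaining samples
oracle_jackknife_calls <- function(bench, encoder = "dipeptide", xi = 0) {
  n <- nrow(bench)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- nitro_train(bench[-i, , drop = FALSE], encoder = encoder, xi = xi)
    out[[i]] <- score_peptides(bench$peptide[i], m)
  }
  dplyr::bind_rows(out)
}

# Oracle: best achievable accuracy over all thresholds, by brute force
oracle_best_acc <- function(scores, labels) {
  cand <- c(min(scores) - 1, sort(unique(scores)), max(scores) + 1)
  best <- 0
  for (t in cand) {
    calls <- ifelse(scores >= t, "positive", "negative")
    best <- max(best, mean(calls == labels))
  }
  best
}

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
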
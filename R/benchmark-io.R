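#' Read a benchmark peptide table
#'
#' Reads the tab-separated benchmark dialect: four columns `protein_id`,
#' `position`, `peptide`, `label` (`1` = nitrotyrosine, `0` = non-site).
#' A header line is optional and lines starting with `#` are ignored. The
#' window half-width is inferred from the (common, odd) peptide length.
#'
#' @param path Path to a benchmark TSV file.
#' @return A benchmark tibble (`protein_id`, `position`, `peptide`, `label`).
#' @export
read_benchmark <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    stop_data("cannot read file: %s", paste(path, collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  rows <- which(keep) # original line numbers, for error messages
  if (length(lines) == 0L) stop_format("empty benchmark table: %s", path)
  has_header <- grepl("protein_id", lines[[1L]], fixed = TRUE)
  if (has_header) {
    lines <- lines[-1L]
    rows <- rows[-1L]
  }
  if (length(lines) == 0L) stop_format("benchmark table has a header but no rows: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop_format("line %d: expected 4 tab-separated columns, found %d",
                rows[which(nf != 4L)[1]], nf[nf != 4L][1])
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  out <- tibble(
    protein_id = m[, 1L],
    position = suppressWarnings(as.integer(m[, 2L])),
    peptide = toupper(m[, 3L]),
    label_tok = m[, 4L]
  )
  if (anyNA(out$position)) {
    stop_format("line %d: position is not an integer", rows[which(is.na(out$position))[1]])
  }
  if (!all(out$label_tok %in% c("0", "1"))) {
    stop_format("line %d: unknown label token '%s' (expected 0 or 1)",
                rows[which(!out$label_tok %in% c("0", "1"))[1]],
                out$label_tok[!out$label_tok %in% c("0", "1")][1])
  }
  len <- nchar(out$peptide)
  if (length(unique(len)) != 1L) {
    stop_format("line %d: inconsistent peptide length %d (first row has %d)",
                rows[which(len != len[1])[1]], len[len != len[1]][1], len[1])
  }
  if (len[1] %% 2L == 0L) {
    stop_format("peptide length %d is even; windows must have odd length", len[1])
  }
  hw <- as.integer((len[1] - 1L) / 2L)
  center <- substr(out$peptide, hw + 1L, hw + 1L)
  if (any(center != "Y")) {
    stop_format("line %d: center residue '%s' is not Y",
                rows[which(center != "Y")[1]], center[center != "Y"][1])
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", out$peptide)
  if (any(bad)) stop_format("line %d: peptide contains symbols outside the 21-letter alphabet", rows[which(bad)[1]])
  out$label <- ifelse(out$label_tok == "1", "positive", "negative")
  out$label_tok <- NULL
  out
}

#' Write a benchmark peptide table
#'
#' Writes the four-column tab-separated dialect read by [read_benchmark()],
#' with a header line.
#'
#' @param benchmark A benchmark tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_benchmark <- function(benchmark, path) {
  validate_benchmark(benchmark)
  out <- tibble(
    protein_id = benchmark$protein_id,
    position = benchmark$position,
    peptide = benchmark$peptide,
    label = ifelse(benchmark$label == "positive", 1L, 0L)
  )
  readr::write_tsv(out, path)
  invisible(benchmark)
}
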
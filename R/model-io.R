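#' Save a trained model to a text file
#'
#' Serializes a `nitro_model` as a self-describing plain-text document: a
#' key-value header (format version, half-width, encoder, xi, class sample
#' counts) followed by the two propensity matrices as sparse tab-separated
#' triplets (state index, subsite, frequency). Frequencies and xi are written
#' with 17 significant digits so that [read_model()] restores the model
#' bit-exactly.
#'
#' @param model A `nitro_model`.
#' @param path Output path.
#' @return The model, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "nitro_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# nitrotyr model",
    "version: 1",
    sprintf("half_width: %d", model$half_width),
    sprintf("encoder: %s", model$encoder),
    sprintf("xi: %.17g", model$xi),
    sprintf("xi_policy: %s", model$xi_policy),
    sprintf("n_pos: %d", attr(model$z_plus, "sample_count")),
    sprintf("n_neg: %d", attr(model$z_minus, "sample_count"))
  ), con)
  write_sparse <- function(tag, m) {
    writeLines(sprintf("[%s]", tag), con)
    nz <- which(unclass(m) > 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 2], nz[, 1]), , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%.17g", nz[, 1], nz[, 2], m[nz]), con)
  }
  write_sparse("z_plus", model$z_plus)
  write_sparse("z_minus", model$z_minus)
  invisible(model)
}

#' Load a model saved by [write_model()]
#'
#' @param path Path to a model file.
#' @return A `nitro_model` identical to the one saved.
#' @export
read_model <- function(path) {
  if (length(path) != 1L || !file.exists(path)) {
    stop_data("cannot read file: %s", paste(path, collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  header_end <- match("[z_plus]", lines)
  if (is.na(header_end)) stop_format("not a nitrotyr model file: %s", path)
  header <- lines[seq_len(header_end - 1L)]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop_format("model file is missing header field '%s'", k)
    vals[[i]]
  }
  if (get("version") != "1") stop_format("unsupported model file version: %s", get("version"))
  hw <- as.integer(get("half_width"))
  encoder <- get("encoder")
  if (!encoder %in% c("dipeptide", "single")) stop_format("unknown encoder '%s'", encoder)
  n_states <- if (encoder == "dipeptide") 441L else 21L
  minus_at <- match("[z_minus]", lines)
  if (is.na(minus_at)) stop_format("model file is missing the [z_minus] section")
  parse_sparse <- function(body, n, class_tag) {
    m <- base::matrix(0, n_states, 2L * hw)
    if (length(body) > 0) {
      f <- strsplit(body, "\t", fixed = TRUE)
      if (any(lengths(f) != 3L)) stop_format("malformed matrix triplet in model file")
      i <- as.integer(vapply(f, `[[`, "", 1L))
      j <- as.integer(vapply(f, `[[`, "", 2L))
      v <- as.numeric(vapply(f, `[[`, "", 3L))
      if (anyNA(i) || anyNA(j) || anyNA(v) ||
          any(i < 1 | i > n_states | j < 1 | j > 2L * hw)) {
        stop_format("matrix triplet out of range in model file")
      }
      m[cbind(i, j)] <- v
    }
    counts <- base::matrix(as.integer(round(m * n)), n_states, 2L * hw)
    new_propensity_matrix(m, counts, hw, class_tag, encoder, n)
  }
  z_plus <- parse_sparse(lines[(header_end + 1L):(minus_at - 1L)],
                         as.integer(get("n_pos")), "positive")
  z_minus <- parse_sparse(if (minus_at < length(lines)) lines[(minus_at + 1L):length(lines)] else character(),
                          as.integer(get("n_neg")), "negative")
  structure(
    list(z_plus = z_plus, z_minus = z_minus, half_width = hw, encoder = encoder,
         xi = as.numeric(get("xi")), xi_policy = get("xi_policy")),
    class = "nitro_model"
  )
}
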
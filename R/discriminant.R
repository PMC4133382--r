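# Misclassification counts over a vector of candidate thresholds.
# A sample is called positive iff its score >= threshold; thresholds equal to
# an observed score therefore call that sample positive.
threshold_counts <- function(scores, labels, thresholds) {
  d_pos <- sort(scores[labels == "positive"])
  d_neg <- sort(scores[labels == "negative"])
  # findInterval with left.open counts values strictly below each threshold
  n_pm <- findInterval(thresholds, d_pos, left.open = TRUE) # positives called negative
  neg_below <- findInterval(thresholds, d_neg, left.open = TRUE)
  n_mp <- length(d_neg) - neg_below                         # negatives called positive
  list(n_pos = length(d_pos), n_neg = length(d_neg), n_pm = n_pm, n_mp = n_mp)
}

# Vectorized Matthews correlation coefficient; 0 when the denominator is 0
mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  num <- tp * tn - fp * fn
  ifelse(denom > 0, num / denom, 0)
}

#' Tune the adjust parameter xi
#'
#' Given raw discriminant scores (computed with `xi = 0`) and their labels,
#' searches the candidate decision thresholds -- the midpoints between
#' consecutive distinct sorted scores, plus guard thresholds below the
#' minimum and above the maximum (which call everything positive or
#' everything negative) -- and returns `xi = -t*` for the threshold `t*`
#' that maximizes overall accuracy. Ties are broken by higher MCC, then by
#' smaller `|xi|`. This is how the class-imbalance offset of the
#' discriminant is chosen on imbalanced benchmarks.
#'
#' @param scores Numeric vector of raw (`xi = 0`) discriminant scores.
#' @param labels Character vector, `"positive"` / `"negative"`.
#' @return The tuned `xi` (a single number).
#' @export
#' @examples
#' tune_xi(c(2, 3), c("negative", "positive")) # -2.5
tune_xi <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_contract("scores and labels differ in length")
  if (length(unique(labels[labels %in% c("positive", "negative")])) < 2L ||
      !all(labels %in% c("positive", "negative"))) {
    stop_data("xi tuning needs at least one score in each class")
  }
  d <- sort(unique(scores))
  cand <- c(d[1] - 1, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2, d[length(d)] + 1)
  cc <- threshold_counts(scores, labels, cand)
  tp <- cc$n_pos - cc$n_pm
  tn <- cc$n_neg - cc$n_mp
  acc <- (tp + tn) / (cc$n_pos + cc$n_neg)
  mcc <- mcc_from_counts(tp, cc$n_mp, tn, cc$n_pm)
  xi <- -cand
  ord <- order(-acc, -mcc, abs(xi))
  xi[ord[1]]
}

#' Train a nitrotyrosine discriminant model
#'
#' Estimates the positive and negative propensity matrices from a labeled
#' benchmark and fixes the adjust parameter `xi`. A window is later scored by
#' the similarity of its two feature vectors to the ideal (all-ones) profile
#' of each class -- i.e. by the component sums `phi+` and `phi-` -- and the
#' discriminant `delta = phi+ - phi- + xi`.
#'
#' @param benchmark A benchmark tibble with `peptide` and `label` columns;
#'   both classes must be non-empty.
#' @param encoder `"dipeptide"` for the position-specific dipeptide
#'   propensity encoder (the default), or `"single"` for the single-residue
#'   baseline.
#' @param xi Either a fixed numeric value, or `"tuned"` (default) to maximize
#'   training accuracy via [tune_xi()] on the training scores.
#' @param pseudocount Optional additive smoothing for the matrices (default 0).
#' @return A `nitro_model` object.
#' @export
#' @examples
#' bench <- tibble::tibble(
#'   peptide = c("AYC", "AYD", "GYG", "GYG"),
#'   label = c("positive", "positive", "negative", "negative")
#' )
#' m <- nitro_train(bench, xi = 0)
#' score_peptides("AYC", m)
nitro_train <- function(benchmark, encoder = c("dipeptide", "single"),
                        xi = "tuned", pseudocount = 0) {
  encoder <- match.arg(encoder)
  hw <- validate_benchmark(benchmark)
  pos <- benchmark$peptide[benchmark$label == "positive"]
  neg <- benchmark$peptide[benchmark$label == "negative"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_data("training needs non-empty positive and negative subsets (got %d / %d)",
              length(pos), length(neg))
  }
  fit <- if (encoder == "dipeptide") compute_psdp else compute_psap
  z_plus <- fit(pos, class_tag = "positive", half_width = hw, pseudocount = pseudocount)
  z_minus <- fit(neg, class_tag = "negative", half_width = hw, pseudocount = pseudocount)
  model <- structure(
    list(z_plus = z_plus, z_minus = z_minus, half_width = hw,
         encoder = encoder, xi = 0, xi_policy = "fixed"),
    class = "nitro_model"
  )
  if (identical(xi, "tuned")) {
    raw <- score_peptides(benchmark$peptide, model)$delta
    model$xi <- tune_xi(raw, benchmark$label)
    model$xi_policy <- "tuned"
  } else if (is.numeric(xi) && length(xi) == 1L && is.finite(xi)) {
    model$xi <- as.numeric(xi)
  } else {
    stop_contract("xi must be a finite number or \"tuned\"")
  }
  model
}

#' Score tyrosine-centered peptides with a trained model
#'
#' Computes, for each window, the similarity scores toward the positive and
#' negative ideal profiles (`phi_pos`, `phi_neg`: sums of the `2l` feature
#' components, each in `[0, 2l]`), the discriminant
#' `delta = phi_pos - phi_neg + xi`, and the call. The decision boundary is
#' inclusive: `delta >= 0` is called `"positive"`.
#'
#' @param peptides Character vector of window peptides (length `2l + 1`,
#'   center Y), or a tibble with a `peptide` column.
#' @param model A `nitro_model`.
#' @return A tibble with columns `peptide`, `phi_pos`, `phi_neg`, `delta`,
#'   `call`.
#' @export
score_peptides <- function(peptides, model) {
  stopifnot(inherits(model, "nitro_model"))
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  if (infer_half_width(peptides) != model$half_width) {
    stop_contract("peptide length does not match the model window (half_width %d)",
                  model$half_width)
  }
  phi_pos <- rowSums(feature_vector(peptides, model$z_plus))
  phi_neg <- rowSums(feature_vector(peptides, model$z_minus))
  delta <- phi_pos - phi_neg + model$xi
  tibble(
    peptide = peptides,
    phi_pos = phi_pos,
    phi_neg = phi_neg,
    delta = delta,
    call = ifelse(delta >= 0, "positive", "negative")
  )
}

#' Predict nitration sites in proteins
#'
#' Extracts every tyrosine-centered window at the model's half-width and
#' scores it, producing one row per Y residue of each input protein, sorted
#' by protein and position.
#'
#' @param proteins A tibble with `id` and `sequence` columns (see
#'   [read_fasta()]).
#' @param model A `nitro_model`.
#' @return A tibble `protein_id`, `position`, `peptide`, `phi_pos`,
#'   `phi_neg`, `delta`, `call`.
#' @export
predict_sites <- function(proteins, model) {
  windows <- extract_windows(proteins, model$half_width)
  if (nrow(windows) == 0L) {
    return(tibble(protein_id = character(), position = integer(),
                  peptide = character(), phi_pos = numeric(),
                  phi_neg = numeric(), delta = numeric(), call = character()))
  }
  scored <- score_peptides(windows$peptide, model)
  dplyr::bind_cols(windows[c("protein_id", "position")], scored) %>%
    dplyr::arrange(.data$protein_id, .data$position)
}

#' @export
#' @rdname predict_sites
#' @param object,newdata,... `predict()` method arguments: a `nitro_model`
#'   and a protein tibble.
predict.nitro_model <- function(object, newdata, ...) {
  predict_sites(newdata, object)
}

#' @export
print.nitro_model <- function(x, ...) {
  cat("<nitro_model> tyrosine nitration site predictor\n")
  cat(sprintf("  encoder:    %s\n", x$encoder))
  cat(sprintf("  half_width: %d (window length %d)\n", x$half_width, 2 * x$half_width + 1))
  cat(sprintf("  xi:         %.6f (%s)\n", x$xi, x$xi_policy))
  cat(sprintf("  training:   %d positive / %d negative peptides\n",
              attr(x$z_plus, "sample_count"), attr(x$z_minus, "sample_count")))
  invisible(x)
}
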
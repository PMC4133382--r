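#' Prediction-quality metrics from confusion counts
#'
#' Computes sensitivity, specificity, overall accuracy and the Matthews
#' correlation coefficient in both standard formulations and cross-checks
#' them: the TP/TN/FP/FN form, and the intuitive form written in terms of
#' the class sizes and the two misclassification counts
#' (`Sn = 1 - N+-/N+`, `Sp = 1 - N-+/N-`,
#' `Acc = 1 - (N+- + N-+)/(N+ + N-)`, and the corresponding MCC). The two
#' formulations are algebraically identical; both are returned so tests can
#' verify the agreement numerically.
#'
#' @param n_pos Number of positive samples (`N+`).
#' @param n_neg Number of negative samples (`N-`).
#' @param n_pos_to_neg Positives called negative (`N+-`, i.e. FN).
#' @param n_neg_to_pos Negatives called positive (`N-+`, i.e. FP).
#' @return A one-row tibble with the counts (`n_pos`, `n_neg`,
#'   `n_pos_to_neg`, `n_neg_to_pos`, `tp`, `fp`, `tn`, `fn`), the metrics
#'   `sn`, `sp`, `acc`, `mcc`, the intuitive-form duplicates (`sn_intuitive`,
#'   `sp_intuitive`, `acc_intuitive`, `mcc_intuitive`), and `mcc_defined`
#'   (FALSE when the MCC denominator is zero, in which case `mcc` is
#'   reported as 0).
#' @export
#' @examples
#' confusion_metrics(10, 90, 2, 9)
confusion_metrics <- function(n_pos, n_neg, n_pos_to_neg, n_neg_to_pos) {
  if (any(c(n_pos, n_neg, n_pos_to_neg, n_neg_to_pos) < 0) ||
      n_pos_to_neg > n_pos || n_neg_to_pos > n_neg) {
    stop_contract("invalid confusion counts: need 0 <= N+- <= N+ and 0 <= N-+ <= N-")
  }
  if (n_pos == 0 || n_neg == 0) {
    stop_contract("sensitivity/specificity need N+ > 0 and N- > 0")
  }
  # double arithmetic: the MCC denominator overflows 32-bit integers at
  # realistic benchmark sizes
  n_pos <- as.numeric(n_pos)
  n_neg <- as.numeric(n_neg)
  n_pos_to_neg <- as.numeric(n_pos_to_neg)
  n_neg_to_pos <- as.numeric(n_neg_to_pos)
  tp <- n_pos - n_pos_to_neg
  fn <- n_pos_to_neg
  tn <- n_neg - n_neg_to_pos
  fp <- n_neg_to_pos
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc_defined <- denom > 0
  mcc <- if (mcc_defined) (tp * tn - fp * fn) / denom else 0
  # intuitive form: class sizes and the two misclassification counts only
  sn_intuitive <- 1 - n_pos_to_neg / n_pos
  sp_intuitive <- 1 - n_neg_to_pos / n_neg
  acc_intuitive <- 1 - (n_pos_to_neg + n_neg_to_pos) / (n_pos + n_neg)
  intuitive_denom <- (1 + (n_neg_to_pos - n_pos_to_neg) / n_pos) *
    (1 + (n_pos_to_neg - n_neg_to_pos) / n_neg)
  mcc_intuitive <- if (mcc_defined) {
    (1 - (n_pos_to_neg / n_pos + n_neg_to_pos / n_neg)) / sqrt(intuitive_denom)
  } else 0
  tibble(
    n_pos = n_pos, n_neg = n_neg,
    n_pos_to_neg = n_pos_to_neg, n_neg_to_pos = n_neg_to_pos,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sn = sn, sp = sp, acc = acc, mcc = mcc,
    sn_intuitive = sn_intuitive, sp_intuitive = sp_intuitive,
    acc_intuitive = acc_intuitive, mcc_intuitive = mcc_intuitive,
    mcc_defined = mcc_defined
  )
}

metrics_from_calls <- function(labels, calls) {
  confusion_metrics(
    n_pos = sum(labels == "positive"),
    n_neg = sum(labels == "negative"),
    n_pos_to_neg = sum(labels == "positive" & calls == "negative"),
    n_neg_to_pos = sum(labels == "negative" & calls == "positive")
  )
}

new_nitro_eval <- function(metrics, scores, roc, settings) {
  structure(list(metrics = metrics, scores = scores, roc = roc$points,
                 auc = roc$auc, settings = settings),
            class = "nitro_eval")
}

#' Leave-one-out jackknife evaluation
#'
#' Scores every benchmark peptide with the model trained on the remaining
#' samples. The held-out sample's own class matrix is obtained by
#' decrementing its dipeptide (or residue) counts and renormalizing by
#' `n - 1`; the other class matrix is unchanged. Because each sample
#' contributes exactly one count per subsite, the decremental update is
#' exact and the whole jackknife runs in one vectorized pass. The result is
#' deterministic: the jackknife yields a unique outcome for a given
#' benchmark.
#'
#' @param benchmark A benchmark tibble; each class needs at least 2 samples.
#' @param encoder `"dipeptide"` (default) or `"single"`.
#' @param xi `"shared"` (default): the adjust parameter is tuned once on the
#'   full dataset's resubstitution scores and shared across all leave-one-out
#'   folds; `"nested"`: re-tuned inside every fold on the remaining samples
#'   only (leakage-free but quadratic in `n`); or a fixed numeric value.
#' @param pseudocount Optional additive smoothing (default 0).
#' @return A `nitro_eval` object: `$metrics` (one-row tibble from
#'   [confusion_metrics()]), `$scores` (per-sample raw scores, `delta`, and
#'   calls), `$roc` and `$auc` computed from the raw leave-one-out scores,
#'   and `$settings`.
#' @export
jackknife_eval <- function(benchmark, encoder = c("dipeptide", "single"),
                           xi = "shared", pseudocount = 0) {
  encoder <- match.arg(encoder)
  hw <- validate_benchmark(benchmark)
  labels <- benchmark$label
  is_pos <- labels == "positive"
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos < 2L || n_neg < 2L) {
    stop_data("jackknife needs at least 2 samples per class (got %d / %d)", n_pos, n_neg)
  }
  enc <- encode_windows(benchmark$peptide, hw, encoder)
  w <- ncol(enc$idx)
  if (pseudocount != 0) {
    # smoothing breaks the simple decremental identity; fall back to explicit
    # per-sample retraining (still exact, just slower)
    return(jackknife_eval_explicit(benchmark, encoder, xi, pseudocount, hw))
  }
  c_pos <- count_matrix(enc$idx[is_pos, , drop = FALSE], enc$n_states)
  c_neg <- count_matrix(enc$idx[!is_pos, , drop = FALSE], enc$n_states)
  s_pos <- lookup_sum(enc$idx, c_pos)
  s_neg <- lookup_sum(enc$idx, c_neg)
  # held-out sample: subtract its own w counts from its class, renormalize
  phi_pos <- ifelse(is_pos, (s_pos - w) / (n_pos - 1L), s_pos / n_pos)
  phi_neg <- ifelse(is_pos, s_neg / n_neg, (s_neg - w) / (n_neg - 1L))
  delta_raw <- phi_pos - phi_neg
  if (identical(xi, "shared")) {
    resub <- s_pos / n_pos - s_neg / n_neg
    xi_val <- tune_xi(resub, labels)
    xi_vec <- rep(xi_val, length(delta_raw))
    xi_policy <- "shared"
  } else if (identical(xi, "nested")) {
    xi_vec <- nested_xi_jackknife(enc, is_pos, c_pos, c_neg, n_pos, n_neg, labels)
    xi_val <- NA_real_
    xi_policy <- "nested"
  } else if (is.numeric(xi) && length(xi) == 1L && is.finite(xi)) {
    xi_val <- as.numeric(xi)
    xi_vec <- rep(xi_val, length(delta_raw))
    xi_policy <- "fixed"
  } else {
    stop_contract("xi must be \"shared\", \"nested\" or a finite number")
  }
  calls <- ifelse(delta_raw + xi_vec >= 0, "positive", "negative")
  scores <- dplyr::bind_cols(
    benchmark[intersect(c("protein_id", "position", "peptide", "label"), names(benchmark))],
    tibble(phi_pos = phi_pos, phi_neg = phi_neg, delta_raw = delta_raw,
           xi = xi_vec, delta = delta_raw + xi_vec, call = calls)
  )
  roc <- roc_curve(delta_raw, labels)
  new_nitro_eval(metrics_from_calls(labels, calls), scores, roc,
                 list(method = "jackknife", encoder = encoder,
                      xi = xi_val, xi_policy = xi_policy, pseudocount = pseudocount))
}

# Per-sample nested xi: for each held-out sample, tune on the resubstitution
# scores of the n-1 remaining samples under the decremented matrices.
nested_xi_jackknife <- function(enc, is_pos, c_pos, c_neg, n_pos, n_neg, labels) {
  n <- nrow(enc$idx)
  vapply(seq_len(n), function(i) {
    cp <- c_pos
    cn <- c_neg
    np <- n_pos
    nn <- n_neg
    cells <- cbind(enc$idx[i, ], seq_len(ncol(enc$idx)))
    if (is_pos[i]) {
      cp[cells] <- cp[cells] - 1L
      np <- np - 1L
    } else {
      cn[cells] <- cn[cells] - 1L
      nn <- nn - 1L
    }
    rest <- setdiff(seq_len(n), i)
    idx_rest <- enc$idx[rest, , drop = FALSE]
    resub <- lookup_sum(idx_rest, cp) / np - lookup_sum(idx_rest, cn) / nn
    tune_xi(resub, labels[rest])
  }, numeric(1))
}

# Reference-style jackknife by explicit retraining (used when smoothing is on)
jackknife_eval_explicit <- function(benchmark, encoder, xi, pseudocount, hw) {
  labels <- benchmark$label
  n <- nrow(benchmark)
  xi_fixed <- if (is.numeric(xi)) as.numeric(xi) else NULL
  if (identical(xi, "shared")) {
    full <- nitro_train(benchmark, encoder = encoder, xi = 0, pseudocount = pseudocount)
    xi_fixed <- tune_xi(score_peptides(benchmark$peptide, full)$delta, labels)
  }
  res <- purrr::map_dfr(seq_len(n), function(i) {
    train <- benchmark[-i, , drop = FALSE]
    xi_i <- xi_fixed
    if (identical(xi, "nested")) {
      m0 <- nitro_train(train, encoder = encoder, xi = 0, pseudocount = pseudocount)
      xi_i <- tune_xi(score_peptides(train$peptide, m0)$delta, train$label)
    }
    m <- nitro_train(train, encoder = encoder, xi = xi_i, pseudocount = pseudocount)
    score_peptides(benchmark$peptide[i], m)
  })
  delta_raw <- res$phi_pos - res$phi_neg
  roc <- roc_curve(delta_raw, labels)
  scores <- dplyr::bind_cols(
    benchmark[intersect(c("protein_id", "position", "peptide", "label"), names(benchmark))],
    tibble(phi_pos = res$phi_pos, phi_neg = res$phi_neg, delta_raw = delta_raw,
           xi = res$delta - delta_raw, delta = res$delta, call = res$call)
  )
  new_nitro_eval(metrics_from_calls(labels, res$call), scores, roc,
                 list(method = "jackknife", encoder = encoder,
                      xi = xi_fixed %||% NA_real_,
                      xi_policy = if (is.numeric(xi)) "fixed" else xi,
                      pseudocount = pseudocount))
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into `k` folds by a seeded shuffle, trains on the
#' complement of each fold and scores its members, then pools the counts of
#' all folds into a single confusion table (micro-averaging). With
#' `k` equal to the total number of samples the folds are singletons and the
#' procedure is exactly the leave-one-out jackknife.
#'
#' @inheritParams jackknife_eval
#' @param k Number of folds (`>= 2`); unless `k` equals the dataset size,
#'   each class must have at least `k` samples.
#' @param seed Integer seed for the fold-assignment shuffle (recorded in the
#'   result; same seed, same folds).
#' @param xi `"shared"`, `"nested"` (re-tuned per fold on the training
#'   split), or a fixed numeric value.
#' @return A `nitro_eval`; `$scores` includes each sample's fold.
#' @export
kfold_eval <- function(benchmark, k = 10, seed = 1,
                       encoder = c("dipeptide", "single"), xi = "shared",
                       pseudocount = 0) {
  encoder <- match.arg(encoder)
  hw <- validate_benchmark(benchmark)
  k <- as.integer(k)
  labels <- benchmark$label
  n <- nrow(benchmark)
  is_pos <- labels == "positive"
  n_pos <- sum(is_pos)
  n_neg <- n - n_pos
  if (is.na(k) || k < 2L) stop_data("k must be an integer >= 2")
  if (k != n && (n_pos < k || n_neg < k)) {
    stop_data("each class needs at least k = %d samples (got %d / %d)", k, n_pos, n_neg)
  }
  fold <- integer(n)
  if (k == n) {
    fold <- seq_len(n) # singleton folds: exact leave-one-out
  } else {
    withr::with_seed(seed, {
      fold[is_pos] <- sample(rep_len(seq_len(k), n_pos))
      fold[!is_pos] <- sample(rep_len(seq_len(k), n_neg))
    })
  }
  enc <- encode_windows(benchmark$peptide, hw, encoder)
  c_pos <- count_matrix(enc$idx[is_pos, , drop = FALSE], enc$n_states)
  c_neg <- count_matrix(enc$idx[!is_pos, , drop = FALSE], enc$n_states)
  if (pseudocount != 0) stop_contract("kfold_eval does not support pseudocount smoothing")
  xi_shared <- NULL
  if (identical(xi, "shared")) {
    resub <- lookup_sum(enc$idx, c_pos) / n_pos - lookup_sum(enc$idx, c_neg) / n_neg
    xi_shared <- tune_xi(resub, labels)
  } else if (is.numeric(xi) && length(xi) == 1L && is.finite(xi)) {
    xi_shared <- as.numeric(xi)
  } else if (!identical(xi, "nested")) {
    stop_contract("xi must be \"shared\", \"nested\" or a finite number")
  }
  phi_pos <- numeric(n)
  phi_neg <- numeric(n)
  xi_vec <- numeric(n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    cp <- c_pos - count_matrix(enc$idx[test & is_pos, , drop = FALSE], enc$n_states)
    cn <- c_neg - count_matrix(enc$idx[test & !is_pos, , drop = FALSE], enc$n_states)
    np <- n_pos - sum(test & is_pos)
    nn <- n_neg - sum(test & !is_pos)
    if (np < 1L || nn < 1L) stop_data("fold %d leaves an empty training class", f)
    idx_test <- enc$idx[test, , drop = FALSE]
    phi_pos[test] <- lookup_sum(idx_test, cp) / np
    phi_neg[test] <- lookup_sum(idx_test, cn) / nn
    if (identical(xi, "nested")) {
      idx_train <- enc$idx[!test, , drop = FALSE]
      resub <- lookup_sum(idx_train, cp) / np - lookup_sum(idx_train, cn) / nn
      xi_vec[test] <- tune_xi(resub, labels[!test])
    } else {
      xi_vec[test] <- xi_shared
    }
  }
  delta_raw <- phi_pos - phi_neg
  calls <- ifelse(delta_raw + xi_vec >= 0, "positive", "negative")
  scores <- dplyr::bind_cols(
    benchmark[intersect(c("protein_id", "position", "peptide", "label"), names(benchmark))],
    tibble(fold = fold, phi_pos = phi_pos, phi_neg = phi_neg,
           delta_raw = delta_raw, xi = xi_vec, delta = delta_raw + xi_vec,
           call = calls)
  )
  roc <- roc_curve(delta_raw, labels)
  new_nitro_eval(metrics_from_calls(labels, calls), scores, roc,
                 list(method = "kfold", k = k, seed = seed, encoder = encoder,
                      xi = xi_shared %||% NA_real_,
                      xi_policy = if (is.numeric(xi)) "fixed" else xi,
                      pseudocount = pseudocount))
}

#' ROC curve and AUC from raw discriminant scores
#'
#' Sweeps the decision threshold over every distinct observed score (plus a
#' guard above the maximum), which is equivalent to sweeping the adjust
#' parameter xi. At threshold `t` a sample is called positive when its score
#' is `>= t`. Points run from (0, 0) to (1, 1) in (1 - Sp, Sn) coordinates
#' and the AUC is the trapezoidal area under them.
#'
#' @param scores Numeric raw scores (higher = more positive-like).
#' @param labels `"positive"` / `"negative"` per score.
#' @return A list with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (!all(labels %in% c("positive", "negative")) ||
      length(unique(labels)) < 2L) {
    stop_data("ROC needs scores from both classes")
  }
  if (length(scores) != length(labels)) stop_contract("scores and labels differ in length")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  cc <- threshold_counts(scores, labels, thr)
  tpr <- (cc$n_pos - cc$n_pm) / cc$n_pos
  fpr <- cc$n_mp / cc$n_neg
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(points = tibble(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' AUC across window half-widths
#'
#' Builds a benchmark for each requested half-width from the same proteins
#' and annotated sites, runs stratified k-fold cross-validation, and reports
#' the ROC AUC per half-width. Used to choose the window size: enlarging the
#' window helps only while the flanking positions still carry nitration
#' signal.
#'
#' @inheritParams build_benchmark
#' @param half_widths Integer vector of half-widths to evaluate.
#' @param k,seed,encoder,xi Passed to [kfold_eval()].
#' @return A tibble with one row per half-width: `half_width`, `auc`.
#' @export
window_size_sweep <- function(proteins, sites, half_widths, k = 10, seed = 1,
                              encoder = "dipeptide", xi = "shared") {
  if (length(half_widths) == 0L) stop_contract("half_widths must be non-empty")
  purrr::map_dfr(half_widths, function(hw) {
    bench <- build_benchmark(proteins, sites, half_width = hw)
    ev <- kfold_eval(bench, k = k, seed = seed, encoder = encoder, xi = xi)
    tibble(half_width = as.integer(hw), auc = ev$auc)
  })
}

#' @export
print.nitro_eval <- function(x, ...) {
  s <- x$settings
  m <- x$metrics
  cat(sprintf("<nitro_eval> %s cross-validation (%s encoder, xi policy: %s)\n",
              s$method, s$encoder, s$xi_policy))
  if (!is.null(s$k)) cat(sprintf("  k = %d, seed = %d\n", s$k, s$seed))
  if (!is.na(s$xi %||% NA_real_)) cat(sprintf("  xi = %.6f\n", s$xi))
  cat(sprintf("  N+ = %d, N- = %d, N+- = %d, N-+ = %d\n",
              m$n_pos, m$n_neg, m$n_pos_to_neg, m$n_neg_to_pos))
  cat(sprintf("  Sn = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.4f  AUC = %.4f\n",
              100 * m$sn, 100 * m$sp, 100 * m$acc, m$mcc, x$auc))
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits the evaluation both as a flat key-value text block and as a
#' one-row machine-readable TSV.
#'
#' @param eval_result A `nitro_eval`.
#' @param path Path for the TSV table; the key-value block goes to
#'   `paste0(path, ".txt")` when `text_path` is not given.
#' @param text_path Optional explicit path for the key-value block.
#' @return `eval_result`, invisibly.
#' @export
write_eval_report <- function(eval_result, path, text_path = NULL) {
  stopifnot(inherits(eval_result, "nitro_eval"))
  m <- eval_result$metrics
  s <- eval_result$settings
  row <- dplyr::bind_cols(
    tibble(method = s$method, encoder = s$encoder, xi_policy = s$xi_policy,
           xi = s$xi %||% NA_real_, k = s$k %||% NA_integer_,
           seed = s$seed %||% NA_integer_, auc = eval_result$auc),
    m
  )
  readr::write_tsv(row, path)
  kv <- sprintf("%s: %s", names(row), vapply(row, function(v) format(v[[1]], digits = 10), ""))
  writeLines(kv, text_path %||% paste0(path, ".txt"))
  invisible(eval_result)
}
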
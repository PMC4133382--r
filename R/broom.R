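#' Tidy a trained model into sparse propensity triplets
#'
#' @param x A `nitro_model`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero matrix cell: `class`
#'   (`"positive"` / `"negative"`), `subsite`, `state` (dipeptide index, or
#'   residue code for the single-residue encoder), `residues` (the decoded
#'   pair or residue), `frequency`.
#' @export
tidy.nitro_model <- function(x, ...) {
  decode <- function(state) {
    if (x$encoder == "single") return(nitro_alphabet()[state])
    a <- (state - 1L) %/% 21L + 1L
    b <- (state - 1L) %% 21L + 1L
    paste0(nitro_alphabet()[a], nitro_alphabet()[b])
  }
  one <- function(m, tag) {
    nz <- which(unclass(m) > 0, arr.ind = TRUE)
    tibble(class = tag, subsite = as.integer(nz[, 2]),
           state = as.integer(nz[, 1]),
           residues = decode(as.integer(nz[, 1])),
           frequency = m[nz])
  }
  dplyr::arrange(
    dplyr::bind_rows(one(x$z_plus, "positive"), one(x$z_minus, "negative")),
    .data$class, .data$subsite, .data$state
  )
}

#' One-row summary of a trained model
#'
#' @inheritParams tidy.nitro_model
#' @return A one-row tibble: `encoder`, `half_width`, `window_length`,
#'   `xi`, `xi_policy`, `n_pos`, `n_neg`.
#' @export
glance.nitro_model <- function(x, ...) {
  tibble(
    encoder = x$encoder,
    half_width = x$half_width,
    window_length = 2L * x$half_width + 1L,
    xi = x$xi,
    xi_policy = x$xi_policy,
    n_pos = attr(x$z_plus, "sample_count"),
    n_neg = attr(x$z_minus, "sample_count")
  )
}

#' Per-sample scores of an evaluation
#'
#' @param x A `nitro_eval`.
#' @param ... Unused.
#' @return The per-sample score tibble (`label`, `phi_pos`, `phi_neg`,
#'   `delta_raw`, `delta`, `call`, plus provenance columns when present).
#' @export
tidy.nitro_eval <- function(x, ...) {
  as_tibble(x$scores)
}

#' One-row summary of an evaluation
#'
#' @inheritParams tidy.nitro_eval
#' @return A one-row tibble with the confusion counts, Sn/Sp/Acc/MCC, AUC
#'   and the evaluation settings.
#' @export
glance.nitro_eval <- function(x, ...) {
  s <- x$settings
  dplyr::bind_cols(
    x$metrics[c("n_pos", "n_neg", "n_pos_to_neg", "n_neg_to_pos",
                "sn", "sp", "acc", "mcc")],
    tibble(auc = x$auc, method = s$method, encoder = s$encoder,
           xi = s$xi %||% NA_real_, xi_policy = s$xi_policy)
  )
}

#' ROC curve plot for an evaluation
#'
#' @param object A `nitro_eval`.
#' @param ... Unused.
#' @return A ggplot: the ROC curve in (1 - Sp, Sn) coordinates with the
#'   chance diagonal, annotated with the AUC.
#' @export
autoplot.nitro_eval <- function(object, ...) {
  pts <- object$roc
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - Specificity", y = "Sensitivity",
      title = sprintf("%s cross-validation ROC", object$settings$method),
      subtitle = sprintf("AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Propensity-contrast plot for a trained model
#'
#' Shows, per subsite, the states (dipeptides or residues) with the largest
#' positive-minus-negative propensity differences -- the model's view of
#' which pairings around the central tyrosine discriminate nitrated from
#' non-nitrated sites.
#'
#' @param object A `nitro_model`.
#' @param top_n Number of states (ranked by total absolute contrast across
#'   subsites) to display.
#' @param ... Unused.
#' @return A ggplot tile plot of the propensity difference.
#' @export
autoplot.nitro_model <- function(object, top_n = 20, ...) {
  diff <- unclass(object$z_plus) - unclass(object$z_minus)
  score <- rowSums(abs(diff))
  keep <- utils::head(order(score, decreasing = TRUE), top_n)
  decode <- if (object$encoder == "single") {
    function(s) nitro_alphabet()[s]
  } else {
    function(s) paste0(nitro_alphabet()[(s - 1L) %/% 21L + 1L],
                       nitro_alphabet()[(s - 1L) %% 21L + 1L])
  }
  df <- purrr::map_dfr(keep, function(s) {
    tibble(residues = decode(s), subsite = seq_len(ncol(diff)),
           contrast = diff[s, ])
  })
  df$residues <- factor(df$residues, levels = rev(decode(keep)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subsite, y = .data$residues,
                                   fill = .data$contrast)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "dipeptide subsite", y = NULL,
                  fill = "z+ - z-",
                  title = "Position-specific propensity contrast") +
    ggplot2::theme_minimal()
}
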
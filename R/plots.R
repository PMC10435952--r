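#' Long-format pair-status table
#'
#' Classifies every unordered pair of samples as `correct`, `incorrect`
#' (from the verdicts; ties count as incorrect), or `unrankable`, for a
#' performance-landscape heatmap across all sample pairs.
#'
#' @param data Sample table (`sample_id`, `label`, ...).
#' @param verdicts Verdict tibble over the rankable pairs.
#' @return A tibble `hi`, `lo`, `status`.
#' @export
pair_status <- function(data, verdicts) {
  ids <- sort(as.character(data$sample_id))
  if (length(ids) < 2L) abort("need at least 2 samples.")
  idx <- utils::combn(length(ids), 2L)
  all_pairs <- tibble::tibble(a = ids[idx[1L, ]], b = ids[idx[2L, ]])
  vkey <- c(paste(verdicts$hi, verdicts$lo, sep = "\r"),
            paste(verdicts$lo, verdicts$hi, sep = "\r"))
  vstat <- rep(ifelse(verdicts$credit == 1, "correct", "incorrect"), 2L)
  m <- match(paste(all_pairs$a, all_pairs$b, sep = "\r"), vkey)
  tibble::tibble(
    hi = all_pairs$a, lo = all_pairs$b,
    status = factor(ifelse(is.na(m), "unrankable", vstat[m]),
                    levels = c("correct", "incorrect", "unrankable")))
}

#' Plot the pair-status landscape
#'
#' @param data,verdicts As in [pair_status()].
#' @return A ggplot tile map over sample pairs.
#' @export
plot_pair_status <- function(data, verdicts) {
  ps <- pair_status(data, verdicts)
  ggplot2::ggplot(ps, ggplot2::aes(x = .data$hi, y = .data$lo,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(correct = "#2166ac",
                                          incorrect = "#ef8a62",
                                          unrankable = "grey85")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "pair") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @method autoplot paireval_outliers
#' @export
autoplot.paireval_outliers <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      sample_id = stats::reorder(.data$sample_id, .data$auc_k),
                      flagged = .data$p_adjusted < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$auc_k,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60"),
                               name = "adj. p < 0.05") +
    ggplot2::labs(x = NULL, y = "sample-specific AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @method autoplot paireval_confounder
#' @export
autoplot.paireval_confounder <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_set, y = .data$auc)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "pair set", y = "AUC") +
    ggplot2::theme_minimal()
}
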
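#' Sample-specific AUC
#'
#' Restricts the paired-evaluation AUC to the subset of rankable pairs that
#' contain one focal sample. A sample whose pairs are disproportionately
#' misranked — a sample-specific AUC well below the overall AUC — is an
#' outlier candidate: its label disagrees with what its features imply.
#'
#' @param verdicts Verdict tibble (`hi`, `lo`, `credit`).
#' @param sample_id The focal sample.
#' @return A `paireval_auc` over the pairs containing `sample_id`.
#' @export
sample_auc <- function(verdicts, sample_id) {
  in_k <- verdicts$hi == sample_id | verdicts$lo == sample_id
  if (!any(in_k)) {
    abort(sprintf("sample '%s' appears in no rankable pair; its AUC is undefined.",
                  sample_id))
  }
  auc_estimate(verdicts[in_k, , drop = FALSE])
}

#' Scan all samples for outliers
#'
#' For each sample k, tallies a 2x2 table of (pair contains k / does not) by
#' (ranked correctly / not) and applies a one-sided Fisher test with the
#' alternative that pairs containing k are more likely misranked. Tied-score
#' pairs count as incorrect in the table (exact tests need integers), but the
#' reported `auc_k` keeps half credits. P-values are Benjamini-Hochberg
#' adjusted across samples; raw p-values are kept alongside.
#'
#' @param verdicts Verdict tibble (`hi`, `lo`, `credit`).
#' @param sample_ids Samples to scan; defaults to every sample appearing in
#'   the verdicts.
#' @return A tibble of class `paireval_outliers`, one row per sample, sorted
#'   by ascending p: `sample_id`, `n_pairs_k`, `credit_k`, `auc_k`,
#'   `p_value`, `p_adjusted`.
#' @export
outlier_scan <- function(verdicts, sample_ids = NULL) {
  if (!is.data.frame(verdicts) || nrow(verdicts) == 0L) {
    abort("verdicts must be a non-empty data frame.")
  }
  if (is.null(sample_ids)) sample_ids <- sort(unique(c(verdicts$hi, verdicts$lo)))
  if (length(sample_ids) < 2L) abort("need at least 2 samples to scan.")
  correct <- verdicts$credit == 1
  n_correct <- sum(correct)
  n_total <- nrow(verdicts)
  rows <- purrr::map(sample_ids, function(k) {
    in_k <- verdicts$hi == k | verdicts$lo == k
    nk <- sum(in_k)
    if (nk == 0L) return(NULL)
    in_cor <- sum(correct & in_k)
    tab <- matrix(c(in_cor, nk - in_cor,
                    n_correct - in_cor, (n_total - nk) - (n_correct - in_cor)),
                  nrow = 2L, byrow = TRUE)
    tibble::tibble(
      sample_id = k, n_pairs_k = nk,
      credit_k = sum(verdicts$credit[in_k]),
      auc_k = sum(verdicts$credit[in_k]) / nk,
      # alternative: pairs containing k are misranked MORE often, i.e. the
      # correct-given-in-k odds are lower than outside
      p_value = fisher_exact(tab, alternative = "less")$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out <- dplyr::arrange(out, .data$p_value, .data$sample_id)
  tibble::new_tibble(out, nrow = nrow(out), class = "paireval_outliers")
}

#' Remove a sample and re-evaluate
#'
#' Drops one sample, rebuilds the rankable pairs without it (the pair count
#' shrinks by exactly the sample's |R_k|), and either retrains the LPOCV
#' models on the reduced dataset (default) or simply re-tallies the existing
#' verdicts with the sample's pairs removed (`retrain = FALSE`). When the
#' adapter exposes importances, full-data fits before and after are returned
#' so the effect of the removal on model interpretation can be inspected.
#'
#' @param data Sample table (see [run_lpocv()]).
#' @param exclude The sample_id to remove.
#' @param spec A [delta_spec()] used to rebuild pairs.
#' @param adapter A [model_adapter()].
#' @param seed Integer seed for the LPOCV runs.
#' @param retrain If `FALSE`, reuse `verdicts` and drop the excluded sample's
#'   pairs instead of retraining.
#' @param verdicts Existing verdicts (required when `retrain = FALSE`; when
#'   retraining they are used for the "before" estimate if supplied,
#'   otherwise the before-LPOCV is run too).
#' @param features,label Passed through to [run_lpocv()].
#' @return A list: `before`/`after` ([auc_estimate()]s), `n_pairs_removed`
#'   (|R_k|), and `importances_before`/`importances_after` when available.
#' @export
remove_and_reevaluate <- function(data, exclude, spec = NULL, adapter = NULL,
                                  seed = 1L, retrain = TRUE, verdicts = NULL,
                                  features = NULL, label = "label") {
  if (!exclude %in% data$sample_id) {
    abort(sprintf("sample '%s' is not in the dataset.", exclude))
  }
  if (nrow(data) - 1L < 3L) abort("removal would leave fewer than 3 samples.")
  pairs_before <- rankable_pairs(data, spec, label = label)
  data_after <- data[data$sample_id != exclude, , drop = FALSE]
  attr(data_after, "features") <- attr(data, "features")
  pairs_after <- rankable_pairs(data_after, spec, label = label)
  if (nrow(pairs_after) < 1L) abort("removal leaves no rankable pairs.")
  n_removed <- nrow(pairs_before) - nrow(pairs_after)

  if (!retrain) {
    if (is.null(verdicts)) abort("retrain = FALSE needs the existing verdicts.")
    before <- auc_estimate(verdicts)
    keep <- verdicts$hi != exclude & verdicts$lo != exclude
    after <- auc_estimate(verdicts[keep, , drop = FALSE])
    imp_before <- imp_after <- NULL
  } else {
    if (is.null(adapter)) abort("retrain = TRUE needs an adapter.")
    before <- if (!is.null(verdicts)) auc_estimate(verdicts) else
      run_lpocv(data, pairs_before, adapter, seed = seed,
                features = features, label = label)$auc
    after <- run_lpocv(data_after, pairs_after, adapter, seed = seed,
                       features = features, label = label)$auc
    has_imp <- !is.null(adapter$importances)
    imp_before <- if (has_imp)
      fit_full_and_importances(data, adapter, seed, features, label) else NULL
    imp_after <- if (has_imp)
      fit_full_and_importances(data_after, adapter, seed, features, label) else NULL
  }
  list(before = before, after = after, n_pairs_removed = n_removed,
       importances_before = imp_before, importances_after = imp_after)
}
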
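#' Score rankable pairs under a model's predictions
#'
#' Each oriented pair `(hi, lo)` earns credit 1 when the model scores `hi`
#' strictly above `lo`, 0.5 when the scores tie (the Mann-Whitney convention,
#' so a constant predictor lands at AUC 0.5), and 0 otherwise.
#'
#' @param pairs A pair tibble from [rankable_pairs()] (columns `hi`, `lo`).
#' @param scores A data frame with columns `sample_id`, `score`, or a named
#'   numeric vector of scores.
#' @return A tibble of verdicts: `hi`, `lo`, `credit`.
#' @examples
#' labs <- tibble::tibble(sample_id = c("a", "b", "c"), label = c(0, 0, 1))
#' prs <- rankable_pairs(labs, delta_spec("indicator"))
#' score_pairs(prs, c(a = 0.1, b = 0.4, c = 0.9))
#' @export
score_pairs <- function(pairs, scores) {
  s <- as_score_lookup(scores)
  missing <- setdiff(unique(c(pairs$hi, pairs$lo)), names(s))
  if (length(missing) > 0L) {
    abort(sprintf("no score for sample(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(s))) {
    abort(sprintf("non-finite score for sample(s): %s",
                  paste(names(s)[!is.finite(s)], collapse = ", ")))
  }
  s_hi <- unname(s[pairs$hi])
  s_lo <- unname(s[pairs$lo])
  tibble::tibble(
    hi = pairs$hi, lo = pairs$lo,
    credit = dplyr::case_when(s_hi > s_lo ~ 1, s_hi == s_lo ~ 0.5, TRUE ~ 0)
  )
}

as_score_lookup <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("sample_id", "score") %in% names(scores))) {
      abort("scores data frame needs columns sample_id and score.")
    }
    if (anyDuplicated(scores$sample_id)) abort("duplicate sample_id in scores.")
    return(setNames(scores$score, as.character(scores$sample_id)))
  }
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  abort("scores must be a data frame (sample_id, score) or a named numeric vector.")
}

new_auc_estimate <- function(credit_sum, n_pairs) {
  structure(
    list(credit_sum = credit_sum, n_pairs = n_pairs, auc = credit_sum / n_pairs),
    class = "paireval_auc"
  )
}

#' @export
print.paireval_auc <- function(x, ...) {
  cat(sprintf("<paired-evaluation AUC> %.4f (%g of %d rankable pairs correct)\n",
              x$auc, x$credit_sum, x$n_pairs))
  invisible(x)
}

#' @method tidy paireval_auc
#' @export
tidy.paireval_auc <- function(x, ...) {
  tibble::tibble(credit_sum = x$credit_sum, n_pairs = x$n_pairs, auc = x$auc)
}

#' @method glance paireval_auc
#' @export
glance.paireval_auc <- function(x, ...) tidy(x)

#' AUC from scored verdicts
#'
#' The paired-evaluation AUC is the fraction of rankable pairs ranked
#' correctly: the sum of pair credits divided by the number of rankable pairs.
#' This exhaustive form is the authoritative definition; [auc_fast()] must
#' agree with it wherever its preconditions hold.
#'
#' @param verdicts A verdict tibble from [score_pairs()] (or any data frame
#'   with a `credit` column).
#' @return A `paireval_auc` object: `credit_sum`, `n_pairs`, `auc`.
#' @examples
#' auc_estimate(tibble::tibble(hi = "b", lo = "a", credit = 1))
#' @export
auc_estimate <- function(verdicts) {
  if (!is.data.frame(verdicts) || !"credit" %in% names(verdicts)) {
    abort("verdicts must be a data frame with a credit column.")
  }
  if (nrow(verdicts) == 0L) abort("AUC is undefined on an empty pair set.")
  new_auc_estimate(sum(verdicts$credit), nrow(verdicts))
}

#' @rdname auc_estimate
#' @inheritParams score_pairs
#' @export
auc_bruteforce <- function(pairs, scores) auc_estimate(score_pairs(pairs, scores))

#' AUC from correct / incorrect pair tallies
#'
#' @param n_correct,n_incorrect Non-negative pair counts.
#' @return A `paireval_auc` with `auc = n_correct / (n_correct + n_incorrect)`.
#' @examples
#' auc_from_counts(524, 128)
#' @export
auc_from_counts <- function(n_correct, n_incorrect) {
  if (n_correct < 0 || n_incorrect < 0) abort("counts must be non-negative.")
  if (n_correct + n_incorrect < 1) abort("AUC undefined: no pairs tallied.")
  new_auc_estimate(n_correct, n_correct + n_incorrect)
}

#' Count inversions in a sequence
#'
#' An inversion is a pair of positions `i < j` with `x[i] > x[j]`; equal values
#' never count. Computed by a bottom-up merge sort in O(n log n), so sequences
#' of millions of values are handled in seconds.
#'
#' @param x Numeric (or integer-coded ordinal) vector.
#' @param detail If `TRUE`, also return the number of merge comparisons
#'   performed (useful for verifying the n log n growth).
#' @return The inversion count (a double: counts can exceed 2^31), or a list
#'   `(inversions, comparisons)` when `detail = TRUE`.
#' @examples
#' count_inversions(c(2, 1))      # 1
#' count_inversions(1:4)          # 0
#' @export
count_inversions <- function(x, detail = FALSE) {
  if (length(x) == 0L) {
    return(if (detail) list(inversions = 0, comparisons = 0) else 0)
  }
  if (!is.numeric(x)) abort("x must be numeric.")
  if (anyNA(x)) abort("x must not contain NA.")
  res <- count_inversions_cpp(as.numeric(x))
  if (detail) list(inversions = res[["inversions"]], comparisons = res[["comparisons"]])
  else res[["inversions"]]
}

#' Fast AUC via inversion counting
#'
#' Sorts samples by model score and counts label inversions: every misranked
#' rankable pair is an inversion, so `AUC = (|R| - inversions - 0.5 * t) / |R|`
#' where `t` is the number of rankable pairs with tied scores. This equivalence
#' requires that rankability depend only on label inequality (indicator mode /
#' discrete ordinal labels); with per-pair deltas use [auc_bruteforce()].
#'
#' Score ties are broken by ascending label before counting, so tied-score
#' pairs contribute no inversions and are credited 0.5 afterwards — the result
#' equals the brute-force AUC exactly.
#'
#' @param data A data frame with columns `sample_id` and `label` (numeric,
#'   factor, or character; treated as ordinal classes).
#' @param scores Scores as in [score_pairs()].
#' @param label Name of the label column.
#' @return A `paireval_auc`.
#' @examples
#' labs <- tibble::tibble(sample_id = letters[1:4], label = c(0, 0, 1, 1))
#' auc_fast(labs, c(a = .1, b = .2, c = .7, d = .9))
#' @export
auc_fast <- function(data, scores, label = "label") {
  if (!all(c("sample_id", label) %in% names(data))) {
    abort(sprintf("data needs columns sample_id and %s.", label))
  }
  y <- data[[label]]
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) y <- as.integer(y)
  if (!is.numeric(y)) abort("labels must be numeric, factor, or character.")
  s <- as_score_lookup(scores)
  ids <- as.character(data$sample_id)
  missing <- setdiff(ids, names(s))
  if (length(missing) > 0L) {
    abort(sprintf("no score for sample(s): %s", paste(missing, collapse = ", ")))
  }
  sc <- unname(s[ids])
  n <- length(y)
  if (n < 2L) abort("need at least 2 samples.")

  pair_count <- function(m) m * (m - 1) / 2
  # |R|: all pairs minus same-label pairs
  n_all <- pair_count(n)
  label_ties <- sum(pair_count(as.numeric(table(y))))
  n_rankable <- n_all - label_ties
  if (n_rankable == 0) abort("AUC undefined: no rankable pairs (all labels equal).")

  ord <- order(sc, y)
  z <- y[ord]
  inv <- count_inversions(z)

  # rankable pairs inside tied-score groups get half credit
  sc_sorted <- sc[ord]
  grp <- cumsum(c(TRUE, sc_sorted[-1] != sc_sorted[-n]))
  tied_rankable <- sum(purrr::map_dbl(split(z, grp), function(zz) {
    m <- length(zz)
    if (m < 2L) return(0)
    pair_count(m) - sum(pair_count(as.numeric(table(zz))))
  }))

  new_auc_estimate(n_rankable - inv - 0.5 * tied_rankable, n_rankable)
}
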
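#' Build comparison tables for two models' verdicts
#'
#' Aligns two verdict tables on their `(hi, lo)` pairs and tallies them two
#' ways: a marginal table (rows = model A / model B, columns = correct /
#' incorrect) for Fisher's exact test, and a paired table (both correct /
#' A only / B only / both incorrect) for McNemar's test. Exact tests need
#' integer counts, so a half-credit (tied-score) pair is counted as incorrect
#' for the model that tied — the conservative reading — unless
#' `ties = "exclude"` drops pairs tied under either model.
#'
#' @param verdicts_a,verdicts_b Verdict tibbles from [score_pairs()] /
#'   [run_lpocv()] covering the same pairs.
#' @param ties `"incorrect"` (default) or `"exclude"`.
#' @return A list with `marginal` and `paired` 2x2 integer matrices
#'   (dimnames label the rows/columns).
#' @export
build_comparison_tables <- function(verdicts_a, verdicts_b,
                                    ties = c("incorrect", "exclude")) {
  ties <- match.arg(ties)
  key_a <- paste(verdicts_a$hi, verdicts_a$lo, sep = "\r")
  key_b <- paste(verdicts_b$hi, verdicts_b$lo, sep = "\r")
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b) ||
      anyDuplicated(key_a) || anyDuplicated(key_b)) {
    diff <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    abort(sprintf("verdict pair sets differ (e.g. %s).",
                  paste(gsub("\r", "/", head(diff, 4L)), collapse = ", ")))
  }
  b_credit <- verdicts_b$credit[match(key_a, key_b)]
  a_credit <- verdicts_a$credit
  if (ties == "exclude") {
    keep <- a_credit != 0.5 & b_credit != 0.5
    a_credit <- a_credit[keep]; b_credit <- b_credit[keep]
  }
  a_ok <- a_credit == 1
  b_ok <- b_credit == 1
  marginal <- matrix(
    c(sum(a_ok), sum(!a_ok), sum(b_ok), sum(!b_ok)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(model = c("A", "B"), ranked = c("correct", "incorrect")))
  paired <- matrix(
    c(sum(a_ok & b_ok), sum(a_ok & !b_ok), sum(!a_ok & b_ok), sum(!a_ok & !b_ok)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(A = c("correct", "incorrect"), B = c("correct", "incorrect")))
  list(marginal = marginal, paired = paired)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the margins fixed. The two-sided p-value
#' sums the probabilities of all tables (with the same margins) no more
#' probable than the observed one. `alternative = "greater"` tests whether
#' the `[1,1]` cell is enriched (odds ratio > 1), `"less"` the reverse.
#'
#' @param table A 2x2 matrix of counts (or 4 counts in row-major order).
#' @param alternative `"two_sided"`, `"greater"`, or `"less"`.
#' @return A one-row tibble: `method`, `alternative`, `statistic` (the sample
#'   odds ratio), `p_value`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2), alternative = "greater")
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- as_2x2(table)
  ft <- fisher.test(m, alternative = sub("_", ".", alternative))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  tibble::tibble(method = "Fisher's exact test", alternative = alternative,
                 statistic = or, p_value = ft$p.value)
}

#' Exact McNemar test on paired verdicts
#'
#' An exact binomial test on the discordant pairs: under the null that both
#' models are equally likely to be the sole correct one, the count of
#' "A-only-correct" pairs among all discordant pairs is Binomial(b + c, 1/2).
#' Only the discordant cells matter; concordant counts do not move the
#' p-value. With no discordant pairs the p-value is 1.
#'
#' @param paired A 2x2 paired table from [build_comparison_tables()], or the
#'   two discordant counts `c(b, c)`.
#' @return A one-row tibble: `method`, `alternative`, `statistic`
#'   (`min(b, c)`), `p_value`.
#' @examples
#' mcnemar_exact(c(9, 1))
#' @export
mcnemar_exact <- function(paired) {
  if (length(paired) == 2L && is.numeric(paired)) {
    b <- paired[1]; c_ <- paired[2]
  } else {
    m <- as_2x2(paired)
    b <- m[1, 2]; c_ <- m[2, 1]
  }
  if (b < 0 || c_ < 0) abort("discordant counts must be non-negative.")
  n <- b + c_
  p <- if (n == 0) 1 else binom.test(min(b, c_), n, p = 0.5,
                                     alternative = "two.sided")$p.value
  tibble::tibble(method = "McNemar's exact test", alternative = "two_sided",
                 statistic = min(b, c_), p_value = min(p, 1))
}

as_2x2 <- function(table) {
  if (is.numeric(table) && length(table) == 4L && is.null(dim(table))) {
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  }
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) abort("expected a 2x2 table.")
  if (any(m < 0) || any(!is.finite(m))) abort("table counts must be non-negative and finite.")
  if (any(m != round(m))) abort("table counts must be integers.")
  m
}

#' Compare two models by paired evaluation
#'
#' The full head-to-head comparison: both tallies, a Fisher test on the
#' marginal table, an exact McNemar test on the paired table, and the AUC
#' difference. McNemar can flag models that differ pair by
#' pair even when their AUCs coincide — a hint the models are complementary.
#'
#' @inheritParams build_comparison_tables
#' @param alternative Alternative for the Fisher test on the marginal table.
#' @return A `paireval_comparison`: `tables` (marginal, paired), `tests`
#'   (tibble with both test rows), `auc_a`, `auc_b`, `delta_auc`.
#' @export
compare_models <- function(verdicts_a, verdicts_b,
                           ties = c("incorrect", "exclude"),
                           alternative = "two_sided") {
  tabs <- build_comparison_tables(verdicts_a, verdicts_b, ties = ties)
  auc_a <- auc_estimate(verdicts_a)
  auc_b <- auc_estimate(verdicts_b)
  tests <- dplyr::bind_rows(
    fisher_exact(tabs$marginal, alternative = alternative),
    mcnemar_exact(tabs$paired))
  structure(list(tables = tabs, tests = tests, auc_a = auc_a, auc_b = auc_b,
                 delta_auc = auc_a$auc - auc_b$auc),
            class = "paireval_comparison")
}

#' @export
print.paireval_comparison <- function(x, ...) {
  cat(sprintf("<model comparison> AUC A = %.4f, AUC B = %.4f (delta %.4f)\n",
              x$auc_a$auc, x$auc_b$auc, x$delta_auc))
  print(x$tables$paired)
  print(as.data.frame(x$tests))
  invisible(x)
}

#' @method tidy paireval_comparison
#' @export
tidy.paireval_comparison <- function(x, ...) x$tests

#' @method glance paireval_comparison
#' @export
glance.paireval_comparison <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a$auc, auc_b = x$auc_b$auc,
                 delta_auc = x$delta_auc,
                 p_fisher = x$tests$p_value[1], p_mcnemar = x$tests$p_value[2])
}
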
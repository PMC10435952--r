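#' Split rankable pairs by a discrete confounder
#'
#' Confounder-matched pairs share the confounder value exactly (e.g. two cell
#' lines of the same molecular subtype); a model cannot rank them correctly
#' just by recognising the confounder. The remaining pairs are
#' confounder-mismatched. The two sets partition the input.
#'
#' @param pairs Pair tibble from [rankable_pairs()].
#' @param data Sample table carrying the confounder column.
#' @param confounder Name of the confounder column.
#' @return A list with `matched` and `mismatched` pair tibbles.
#' @export
split_pairs_discrete <- function(pairs, data, confounder) {
  val <- confounder_lookup(data, confounder, unique(c(pairs$hi, pairs$lo)))
  same <- val[pairs$hi] == val[pairs$lo]
  list(matched = pairs[same, , drop = FALSE],
       mismatched = pairs[!same, , drop = FALSE])
}

confounder_lookup <- function(data, confounder, needed_ids) {
  if (!confounder %in% names(data)) {
    abort(sprintf("data has no confounder column '%s'.", confounder))
  }
  val <- setNames(data[[confounder]], as.character(data$sample_id))
  missing_ids <- setdiff(needed_ids, names(val))
  bad <- c(missing_ids, names(val)[is.na(val)])
  if (length(bad) > 0L) {
    abort(sprintf("missing confounder '%s' value for: %s", confounder,
                  paste(head(unique(bad), 5L), collapse = ", ")))
  }
  val
}

#' Select matched and mismatched pairs along a continuous confounder
#'
#' For each index sample, one confounder-matched rankable pair is selected —
#' the rankable partner minimising the absolute confounder difference — and
#' one mismatched pair per the chosen strategy, so each data point is
#' associated with the minimal and maximal separation along the confounder.
#' Values at or above `censor_at` form one censored category (e.g. age of
#' death recorded as 90+): two censored values have difference 0 and a
#' matched partner is drawn at random from the category. Ties are broken by
#' the smallest partner sample_id; duplicate pairs selected from different
#' index samples are kept once.
#'
#' @param pairs Pair tibble from [rankable_pairs()].
#' @param data Sample table carrying the numeric confounder column.
#' @param confounder Name of the confounder column.
#' @param censor_at Censoring bound, or `NULL` for none.
#' @param mismatched_strategy `"max_difference"` (partner maximising the
#'   confounder gap), `"random_from_censored"` (a random rankable partner
#'   from the censored category — the confounded contrast for an uncensored
#'   index sample), or `"all_remaining"` (every rankable pair not selected
#'   as matched).
#' @param seed Seed for the random draws among censored partners.
#' @return A list with `matched` and `mismatched` pair tibbles.
#' @export
select_pairs_continuous <- function(pairs, data, confounder, censor_at = NULL,
                                    mismatched_strategy = c("max_difference",
                                                            "random_from_censored",
                                                            "all_remaining"),
                                    seed = 1L) {
  mismatched_strategy <- match.arg(mismatched_strategy)
  ids <- unique(c(pairs$hi, pairs$lo))
  val <- confounder_lookup(data, confounder, ids)
  if (!is.numeric(val)) abort("continuous pair selection needs a numeric confounder.")
  censored <- if (is.null(censor_at)) rep(FALSE, length(val)) else val >= censor_at
  names(censored) <- names(val)
  gap <- function(a, b) {
    ifelse(censored[a] & censored[b], 0, abs(val[a] - val[b]))
  }
  pair_gap <- unname(gap(pairs$hi, pairs$lo))
  partner_of <- function(p, id) ifelse(p$hi == id, p$lo, p$hi)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  matched_idx <- integer(0)
  mismatched_idx <- integer(0)
  skipped <- character(0)
  for (id in sort(ids)) {
    cand <- which(pairs$hi == id | pairs$lo == id)
    if (length(cand) == 0L) { skipped <- c(skipped, id); next }
    partners <- partner_of(pairs[cand, ], id)
    g <- pair_gap[cand]
    best <- which(g == min(g))
    pick <- if (length(best) > 1L && !is.null(censor_at) &&
                censored[id] && all(censored[partners[best]])) {
      sample(best, 1L) # random draw within the censored category
    } else {
      best[order(partners[best])][1L]
    }
    matched_idx <- c(matched_idx, cand[pick])
    if (mismatched_strategy == "max_difference") {
      worst <- which(g == max(g))
      wpick <- worst[order(partners[worst])][1L]
      mismatched_idx <- c(mismatched_idx, cand[wpick])
    } else if (mismatched_strategy == "random_from_censored") {
      if (is.null(censor_at)) abort("random_from_censored needs censor_at.")
      cen <- which(censored[partners])
      if (length(cen) > 0L) {
        wpick <- if (length(cen) == 1L) cen else sample(cen, 1L)
        mismatched_idx <- c(mismatched_idx, cand[wpick])
      }
    }
  }
  if (length(skipped) > 0L) {
    warn(sprintf("no rankable partner for: %s", paste(skipped, collapse = ", ")))
  }
  matched <- dplyr::distinct(pairs[sort(unique(matched_idx)), , drop = FALSE])
  mismatched <- if (mismatched_strategy == "all_remaining") {
    pairs[-sort(unique(matched_idx)), , drop = FALSE]
  } else {
    dplyr::distinct(pairs[sort(unique(setdiff(mismatched_idx, matched_idx))), ,
                          drop = FALSE])
  }
  list(matched = matched, mismatched = mismatched)
}

#' Quantify the effect of a known confounder on model performance
#'
#' Contrasts the verdicts on confounder-matched pairs against the
#' confounder-mismatched ones. A significantly lower matched AUC indicates
#' the model has learned to recognise the confounder rather than the signal
#' of interest. The primary test is a one-sided Fisher test on the disjoint
#' matched / mismatched rows; a second, presentation-style test contrasts the
#' all-pairs and matched columns directly (the tabulation used when reporting
#' all-pairs vs matched AUC side by side), with the same one-sided
#' alternative that matched pairs are more likely misranked. Tied-score pairs
#' count as incorrect in both tables.
#'
#' @param verdicts Verdict tibble covering both pair sets.
#' @param matched,mismatched Pair tibbles from [split_pairs_discrete()] or
#'   [select_pairs_continuous()].
#' @return A `paireval_confounder`: AUC estimates over all / matched /
#'   mismatched pairs, `delta_auc = auc_all - auc_matched`, the disjoint 2x2
#'   `table`, `p_value` (disjoint rows), and `p_value_all_vs_matched`.
#' @export
confounder_effect <- function(verdicts, matched, mismatched) {
  if (nrow(matched) == 0L || nrow(mismatched) == 0L) {
    abort("confounder effect undefined: matched or mismatched pair set is empty.")
  }
  key <- function(p) paste(p$hi, p$lo, sep = "\r")
  vk <- key(verdicts)
  pick <- function(p) {
    idx <- match(key(p), vk)
    if (anyNA(idx)) abort("verdicts do not cover every matched/mismatched pair.")
    verdicts[idx, , drop = FALSE]
  }
  v_match <- pick(matched)
  v_mis <- pick(mismatched)
  v_all <- dplyr::bind_rows(v_match, v_mis)
  counts <- function(v) c(correct = sum(v$credit == 1), incorrect = sum(v$credit != 1))
  cm <- counts(v_match); cx <- counts(v_mis)
  tab <- matrix(c(cm, cx), nrow = 2L, byrow = TRUE,
                dimnames = list(pairs = c("matched", "mismatched"),
                                ranked = c("correct", "incorrect")))
  # matched pairs more likely misranked <=> matched correct-odds lower
  p_disjoint <- fisher_exact(tab, alternative = "less")$p_value
  ca <- cm + cx
  tab_presentation <- matrix(c(ca["correct"], cm["correct"],
                               ca["incorrect"], cm["incorrect"]),
                             nrow = 2L, byrow = TRUE,
                             dimnames = list(ranked = c("correct", "incorrect"),
                                             pairs = c("all", "matched")))
  p_all_vs_matched <- fisher_exact(tab_presentation, alternative = "greater")$p_value
  auc_all <- auc_estimate(v_all)
  auc_matched <- auc_estimate(v_match)
  structure(
    list(auc_all = auc_all, auc_matched = auc_matched,
         auc_mismatched = auc_estimate(v_mis),
         delta_auc = auc_all$auc - auc_matched$auc,
         table = tab, p_value = p_disjoint,
         p_value_all_vs_matched = unname(p_all_vs_matched)),
    class = "paireval_confounder")
}

#' @export
print.paireval_confounder <- function(x, ...) {
  cat(sprintf(paste0(
    "<confounder effect>\n",
    "  AUC all pairs:        %.4f (%d pairs)\n",
    "  AUC matched pairs:    %.4f (%d pairs)\n",
    "  AUC mismatched pairs: %.4f (%d pairs)\n",
    "  delta AUC (all - matched): %.4f\n",
    "  one-sided Fisher p (matched vs mismatched): %.3g\n"),
    x$auc_all$auc, x$auc_all$n_pairs,
    x$auc_matched$auc, x$auc_matched$n_pairs,
    x$auc_mismatched$auc, x$auc_mismatched$n_pairs,
    x$delta_auc, x$p_value))
  invisible(x)
}

#' @method tidy paireval_confounder
#' @export
tidy.paireval_confounder <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$auc_all), pair_set = "all"),
    dplyr::mutate(tidy(x$auc_matched), pair_set = "matched"),
    dplyr::mutate(tidy(x$auc_mismatched), pair_set = "mismatched")) |>
    dplyr::select("pair_set", dplyr::everything())
}

#' @method glance paireval_confounder
#' @export
glance.paireval_confounder <- function(x, ...) {
  tibble::tibble(auc_all = x$auc_all$auc, auc_matched = x$auc_matched$auc,
                 auc_mismatched = x$auc_mismatched$auc, delta_auc = x$delta_auc,
                 p_value = x$p_value,
                 p_value_all_vs_matched = x$p_value_all_vs_matched)
}

#' One-way ANOVA of labels across confounder groups
#'
#' Classical one-way ANOVA, `F = MS_between / MS_within` on `(g - 1, N - g)`
#' degrees of freedom — a quick check of how strongly a discrete confounder
#' is associated with the labels. A large F anticipates a large drop from
#' all-pairs to confounder-matched AUC.
#'
#' @param labels Numeric response vector.
#' @param groups Discrete group vector of the same length, at least 2 groups
#'   with at least 2 members each.
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' anova_f(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_f <- function(labels, groups) {
  if (length(labels) != length(groups)) abort("labels and groups differ in length.")
  g <- factor(groups)
  sizes <- table(g)
  if (length(sizes) < 2L) abort("need at least 2 groups.")
  if (any(sizes < 2L)) {
    abort(sprintf("every group needs >= 2 members (offending: %s).",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  a <- anova(lm(labels ~ g))
  tibble::tibble(statistic = a[["F value"]][1],
                 df_between = a[["Df"]][1], df_within = a[["Df"]][2],
                 p_value = a[["Pr(>F)"]][1])
}
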
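delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_table_auto <- function(path) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    progress = FALSE)
}

write_table_auto <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path))
  invisible(path)
}

#' Read a dataset from feature / label / confounder tables
#'
#' The feature table has one row per sample (`sample_id` column plus numeric
#' feature columns); the label table has `sample_id`, `label`, and optionally
#' `replicate_sd`; the optional confounder table has `sample_id` plus one
#' column per confounder. Tables are joined on `sample_id`; feature-table
#' samples without a label are dropped with a warning. Delimiters are taken
#' from the file extension (`.csv` comma, anything else tab).
#'
#' @param features_path,labels_path,confounders_path File paths
#'   (`confounders_path` may be `NULL`).
#' @return A sample tibble as produced by [simulate_dataset()] (feature
#'   column names in the `features` attribute).
#' @export
read_dataset <- function(features_path, labels_path, confounders_path = NULL) {
  feats <- read_table_auto(features_path)
  labs <- read_table_auto(labels_path)
  if (!"sample_id" %in% names(feats)) abort("feature table needs a sample_id column.")
  if (!all(c("sample_id", "label") %in% names(labs))) {
    abort("label table needs sample_id and label columns.")
  }
  for (tb in list(feats, labs)) {
    if (anyDuplicated(tb$sample_id)) {
      abort(sprintf("duplicate sample_id: %s",
                    paste(unique(tb$sample_id[duplicated(tb$sample_id)]),
                          collapse = ", ")))
    }
  }
  feat_cols <- setdiff(names(feats), "sample_id")
  bad <- feat_cols[!vapply(feats[feat_cols], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric feature column(s): %s", paste(bad, collapse = ", ")))
  }
  unlabeled <- setdiff(feats$sample_id, labs$sample_id)
  if (length(unlabeled) > 0L) {
    warn(sprintf("dropping %d sample(s) without a label: %s", length(unlabeled),
                 paste(head(unlabeled, 5L), collapse = ", ")))
  }
  out <- dplyr::inner_join(labs, feats, by = "sample_id")
  if (!is.null(confounders_path)) {
    conf <- read_table_auto(confounders_path)
    if (!"sample_id" %in% names(conf)) abort("confounder table needs a sample_id column.")
    out <- dplyr::left_join(out, conf, by = "sample_id")
  }
  out <- tibble::as_tibble(out)
  attr(out, "features") <- feat_cols
  out
}

#' Read / write pair, score, and verdict tables
#'
#' Plain delimited tables: pairs as `hi`, `lo`, `delta_used`; scores as
#' `sample_id`, `score` (plus `n_pooled` when pooled); verdicts as `hi`,
#' `lo`, `credit`.
#'
#' @param x The tibble to write.
#' @param path File path (`.csv` comma-separated, otherwise tab).
#' @name pair_io
#' @return Readers return the tibble; writers return `path` invisibly.
#' @export
write_pairs <- function(x, path) write_table_auto(x[c("hi", "lo", "delta_used")], path)

#' @rdname pair_io
#' @export
read_pairs <- function(path) {
  x <- read_table_auto(path)
  if (!all(c("hi", "lo") %in% names(x))) abort("pair table needs hi and lo columns.")
  if (!"delta_used" %in% names(x)) x$delta_used <- NA_real_
  new_paireval_pairs(x[c("hi", "lo", "delta_used")],
                     n_samples = length(unique(c(x$hi, x$lo))))
}

#' @rdname pair_io
#' @export
write_scores <- function(x, path) write_table_auto(x, path)

#' @rdname pair_io
#' @export
read_scores <- function(path) {
  x <- read_table_auto(path)
  if (!all(c("sample_id", "score") %in% names(x))) {
    abort("score table needs sample_id and score columns.")
  }
  x
}

#' @rdname pair_io
#' @export
write_verdicts <- function(x, path) write_table_auto(x[c("hi", "lo", "credit")], path)

#' @rdname pair_io
#' @export
read_verdicts <- function(path) {
  x <- read_table_auto(path)
  if (!all(c("hi", "lo", "credit") %in% names(x))) {
    abort("verdict table needs hi, lo, and credit columns.")
  }
  x
}

#' Write a machine-readable JSON report
#'
#' Serialises any list of results (tibbles become arrays of records) with the
#' seed and package version echoed, using stable key order so repeated runs
#' diff cleanly.
#'
#' @param results Named list of results.
#' @param path Output JSON path.
#' @param seed Seed to echo into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL) {
  payload <- c(
    list(package = "paireval",
         version = as.character(utils::packageVersion("paireval")),
         seed = seed),
    results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
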
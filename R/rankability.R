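#' Specify how label separation is judged
#'
#' A delta specification decides when two samples' labels are far enough apart
#' that a model can meaningfully be asked to order them. In classification the
#' distance function is an indicator on label identity with a threshold of 0.5,
#' so any two distinct labels form a rankable pair. In regression the distance
#' is `|y_i - y_j|` and the threshold delta is either a constant or, when
#' technical replicates are available, the larger of the two samples' replicate
#' standard deviations — the expected measurement error for that pair.
#'
#' @param mode `"indicator"` (distinct labels are rankable; delta is fixed at
#'   0.5) or `"absolute_difference"` (labels must differ by at least delta).
#' @param constant_delta Non-negative constant threshold. Only meaningful in
#'   `"absolute_difference"` mode; exactly one of `constant_delta` /
#'   `use_replicate_sd` must be given there.
#' @param use_replicate_sd If `TRUE`, delta for a pair is
#'   `max(replicate_sd_i, replicate_sd_j)`; every sample must then carry a
#'   `replicate_sd`.
#' @return An object of class `paireval_delta_spec`.
#' @examples
#' delta_spec("indicator")
#' delta_spec("absolute_difference", constant_delta = 0.3)
#' delta_spec("absolute_difference", use_replicate_sd = TRUE)
#' @export
delta_spec <- function(mode = c("indicator", "absolute_difference"),
                       constant_delta = NULL,
                       use_replicate_sd = FALSE) {
  mode <- match.arg(mode)
  if (mode == "indicator") {
    if (!is.null(constant_delta) || isTRUE(use_replicate_sd)) {
      abort("indicator mode fixes delta at 0.5; do not supply constant_delta or use_replicate_sd.")
    }
  } else {
    has_const <- !is.null(constant_delta)
    if (has_const == isTRUE(use_replicate_sd)) {
      abort("absolute_difference mode requires exactly one of constant_delta / use_replicate_sd.")
    }
    if (has_const) {
      if (!is.numeric(constant_delta) || length(constant_delta) != 1L ||
          is.na(constant_delta) || constant_delta < 0) {
        abort("constant_delta must be a single non-negative number.")
      }
    }
  }
  structure(
    list(mode = mode, constant_delta = constant_delta,
         use_replicate_sd = isTRUE(use_replicate_sd)),
    class = "paireval_delta_spec"
  )
}

#' @export
print.paireval_delta_spec <- function(x, ...) {
  if (x$mode == "indicator") {
    cat("<delta_spec> indicator (distinct labels rankable, delta = 0.5)\n")
  } else if (x$use_replicate_sd) {
    cat("<delta_spec> absolute difference, delta = max of the pair's replicate SDs\n")
  } else {
    cat(sprintf("<delta_spec> absolute difference, constant delta = %g\n", x$constant_delta))
  }
  invisible(x)
}

# Fallback used when the caller supplies no spec: indicator for few distinct
# label values (ordinal/classification data), otherwise strict inequality.
default_delta_spec <- function(labels) {
  n_distinct <- length(unique(labels[!is.na(labels)]))
  if (n_distinct <= 10L) {
    inform(sprintf(
      "No delta_spec given: %d distinct label values, using indicator rankability (distinct labels are rankable).",
      n_distinct))
    delta_spec("indicator")
  } else {
    inform("No delta_spec given: labels look continuous, using constant delta = 0 (any strict label difference is rankable).")
    delta_spec("absolute_difference", constant_delta = 0)
  }
}

assert_delta_inputs <- function(labels, replicate_sd, spec, ids = NULL) {
  if (!inherits(spec, "paireval_delta_spec")) {
    abort("spec must be created with delta_spec().")
  }
  if (spec$mode == "absolute_difference" && !is.numeric(labels)) {
    abort("absolute_difference rankability needs numeric labels.")
  }
  if (spec$mode == "absolute_difference" && spec$use_replicate_sd) {
    bad <- is.null(replicate_sd) | is.na(replicate_sd)
    if (any(bad)) {
      offenders <- if (is.null(ids)) "some samples" else
        paste(head(ids[bad], 5L), collapse = ", ")
      abort(sprintf(
        "use_replicate_sd = TRUE but replicate_sd is missing for: %s", offenders))
    }
    if (any(replicate_sd < 0)) abort("replicate_sd must be non-negative.")
  }
  invisible(TRUE)
}

#' Delta threshold for one pair of samples
#'
#' @param label_a,label_b Labels of the two samples (unused for the threshold
#'   itself but kept for interface symmetry with [is_rankable()]).
#' @param sd_a,sd_b Replicate standard deviations (needed when the spec uses
#'   them).
#' @param spec A [delta_spec()].
#' @return The non-negative delta used for this pair: 0.5 in indicator mode,
#'   the constant in constant mode, `max(sd_a, sd_b)` in replicate mode.
#' @examples
#' pair_delta(sd_a = 0.2, sd_b = 0.05,
#'            spec = delta_spec("absolute_difference", use_replicate_sd = TRUE))
#' @export
pair_delta <- function(label_a = NULL, label_b = NULL, sd_a = NULL, sd_b = NULL,
                       spec = delta_spec()) {
  if (!inherits(spec, "paireval_delta_spec")) abort("spec must be a delta_spec().")
  if (spec$mode == "indicator") return(0.5)
  if (!is.null(spec$constant_delta)) return(spec$constant_delta)
  if (is.null(sd_a) || is.null(sd_b) || is.na(sd_a) || is.na(sd_b)) {
    abort("replicate-SD delta requested but a replicate_sd is missing for this pair.")
  }
  max(sd_a, sd_b)
}

#' Is a pair of samples rankable?
#'
#' Two samples are rankable when their labels are separated by at least the
#' pair's delta threshold. Identical labels are never rankable (there is no
#' order to recover), in every mode.
#'
#' @inheritParams pair_delta
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_rankable(0, 1, spec = delta_spec("indicator"))
#' is_rankable(0.50, 0.60, sd_a = 0.2, sd_b = 0.05,
#'             spec = delta_spec("absolute_difference", use_replicate_sd = TRUE))
#' @export
is_rankable <- function(label_a, label_b, sd_a = NULL, sd_b = NULL,
                        spec = delta_spec()) {
  if (is.na(label_a) || is.na(label_b)) return(FALSE)
  if (spec$mode == "indicator") return(label_a != label_b)
  if (label_a == label_b) return(FALSE)
  abs(label_a - label_b) >= pair_delta(label_a, label_b, sd_a, sd_b, spec)
}

#' Build the set of rankable pairs
#'
#' Enumerates every unordered pair of samples, keeps those whose labels are
#' separated by at least the pair's delta, and orients each kept pair so that
#' `hi` is the sample with the larger label. A model ranks the pair correctly
#' when it scores `hi` above `lo`.
#'
#' @param data A data frame with columns `sample_id`, `label`, and (when the
#'   spec needs it) `replicate_sd`. Labels may be numeric, ordered factors, or
#'   character/factor categories (treated as unordered classes, valid for
#'   indicator mode only).
#' @param spec A [delta_spec()]; when `NULL` a default is chosen from the
#'   label structure and announced.
#' @param label Name of the label column.
#' @return A tibble of class `paireval_pairs` with columns `hi`, `lo`,
#'   `delta_used`, sorted by `(hi, lo)`; the number of samples considered is
#'   stored in the `n_samples` attribute.
#' @examples
#' labs <- tibble::tibble(sample_id = c("a", "b", "c"), label = c(0, 0, 1))
#' rankable_pairs(labs, delta_spec("indicator"))
#' @export
rankable_pairs <- function(data, spec = NULL, label = "label") {
  if (!is.data.frame(data)) abort("data must be a data frame.")
  if (!"sample_id" %in% names(data)) abort("data needs a sample_id column.")
  if (!label %in% names(data)) abort(sprintf("data has no column '%s'.", label))
  if (anyDuplicated(data$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  paste(unique(data$sample_id[duplicated(data$sample_id)]), collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 2L) abort("need at least 2 samples to form pairs.")

  y <- data[[label]]
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    if (is.null(spec)) spec <- delta_spec("indicator")
    if (spec$mode != "indicator") {
      abort("categorical labels support indicator rankability only.")
    }
    y <- as.integer(y) # any declared level order; indicator mode only needs identity
  }
  if (!is.numeric(y)) abort("labels must be numeric, factor, or character.")
  if (is.null(spec)) spec <- default_delta_spec(y)

  ids <- as.character(data$sample_id)
  sds <- if ("replicate_sd" %in% names(data)) data[["replicate_sd"]] else NULL
  assert_delta_inputs(y, sds, spec, ids)

  idx <- utils::combn(n, 2L)
  a <- idx[1L, ]; b <- idx[2L, ]
  dy <- y[a] - y[b]
  if (spec$mode == "indicator") {
    keep <- dy != 0
    delta <- rep(0.5, length(a))
  } else {
    delta <- if (!is.null(spec$constant_delta)) {
      rep(spec$constant_delta, length(a))
    } else {
      pmax(sds[a], sds[b])
    }
    keep <- dy != 0 & abs(dy) >= delta
  }
  keep[is.na(keep)] <- FALSE

  a <- a[keep]; b <- b[keep]; delta <- delta[keep]; dy <- dy[keep]
  hi <- ifelse(dy > 0, a, b)
  lo <- ifelse(dy > 0, b, a)
  out <- tibble::tibble(hi = ids[hi], lo = ids[lo], delta_used = delta)
  out <- dplyr::arrange(out, .data$hi, .data$lo)
  if (nrow(out) == 0L) {
    warn("no rankable pairs: downstream AUC is undefined for this dataset.")
  }
  new_paireval_pairs(out, n_samples = n)
}

new_paireval_pairs <- function(df, n_samples) {
  structure(
    tibble::new_tibble(df, nrow = nrow(df), class = "paireval_pairs"),
    n_samples = n_samples
  )
}

#' Number of samples a pair set was built from
#' @param pairs A `paireval_pairs` tibble.
#' @return Integer count.
#' @export
n_pair_samples <- function(pairs) {
  attr(pairs, "n_samples") %||% length(unique(c(pairs$hi, pairs$lo)))
}
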
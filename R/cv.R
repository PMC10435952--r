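#' Create a model adapter
#'
#' Paired evaluation is agnostic to the learning method: anything that can be
#' fitted on a training table and score held-out samples plugs in through this
#' adapter contract. Scores are always oriented "higher score = larger
#' predicted label" (probability of the positive class in classification).
#'
#' @param fit `function(x, y, seed)` returning an opaque fitted state; `x` is a
#'   numeric feature matrix (rows = samples), `y` the label vector. Same seed
#'   and data must give identical fits.
#' @param score `function(state, x)` returning one finite numeric score per row
#'   of `x`.
#' @param importances Optional `function(state)` returning a named numeric
#'   vector of feature importances.
#' @param name Human-readable adapter name.
#' @return A `paireval_adapter`.
#' @export
model_adapter <- function(fit, score, importances = NULL, name = "custom") {
  stopifnot(is.function(fit), is.function(score),
            is.null(importances) || is.function(importances))
  structure(list(fit = fit, score = score, importances = importances, name = name),
            class = "paireval_adapter")
}

#' @export
print.paireval_adapter <- function(x, ...) {
  cat(sprintf("<model adapter> %s%s\n", x$name,
              if (is.null(x$importances)) "" else " (reports feature importances)"))
  invisible(x)
}

#' Built-in model adapters
#'
#' `adapter_ridge()` fits penalised least squares in closed form (fast enough
#' for the thousands of fits a leave-pair-out run performs). Features and
#' labels are centred on the training set; the penalty is applied to the
#' slopes only. `adapter_logistic()` wraps [stats::glm()] with a binomial
#' link and scores by predicted class-1 probability. `adapter_random_forest()`
#' wraps `ranger` (regression forests; impurity importances).
#'
#' @param lambda Ridge penalty (in units of the feature variance scale).
#' @param num_trees Number of trees for the forest.
#' @name adapters
#' @return A `paireval_adapter`.
#' @export
adapter_ridge <- function(lambda = 1) {
  model_adapter(
    name = sprintf("ridge (lambda = %g)", lambda),
    fit = function(x, y, seed) {
      x <- as.matrix(x)
      xm <- colMeans(x); ym <- mean(y)
      xc <- sweep(x, 2L, xm)
      p <- ncol(xc)
      beta <- solve(crossprod(xc) + diag(lambda, p), crossprod(xc, y - ym))
      list(beta = beta, xm = xm, ym = ym)
    },
    score = function(state, x) {
      x <- as.matrix(x)
      drop(sweep(x, 2L, state$xm) %*% state$beta) + state$ym
    },
    importances = function(state) {
      b <- abs(drop(state$beta))
      names(b) <- rownames(state$beta)
      b
    }
  )
}

#' @rdname adapters
#' @export
adapter_logistic <- function() {
  model_adapter(
    name = "logistic regression",
    fit = function(x, y, seed) {
      df <- as.data.frame(as.matrix(x))
      df$.y <- as.numeric(y > min(y)) # positive class = above the smallest label
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    score = function(state, x) {
      unname(predict(state, newdata = as.data.frame(as.matrix(x)), type = "response"))
    }
  )
}

#' @rdname adapters
#' @export
adapter_random_forest <- function(num_trees = 500) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    abort("adapter_random_forest() needs the ranger package.")
  }
  model_adapter(
    name = sprintf("random forest (%d trees)", num_trees),
    fit = function(x, y, seed) {
      df <- as.data.frame(as.matrix(x))
      df$.y <- y
      ranger::ranger(.y ~ ., data = df, num.trees = num_trees, seed = seed,
                     importance = "impurity", num.threads = 1L)
    },
    score = function(state, x) {
      predict(state, data = as.data.frame(as.matrix(x)),
              num.threads = 1L)$predictions
    },
    importances = function(state) ranger::importance(state)
  )
}

# Feature matrix extraction: honour an explicit selection, then the
# "features" attribute set by simulate_dataset()/read_dataset(), then all
# numeric columns that are not bookkeeping.
feature_matrix <- function(data, features = NULL, label = "label") {
  if (is.null(features)) features <- attr(data, "features")
  if (is.null(features)) {
    reserved <- c("sample_id", label, "replicate_sd", "is_outlier")
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(numeric_cols, reserved)
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("feature column(s) not in data: %s", paste(missing, collapse = ", ")))
  }
  if (length(features) == 0L) abort("no feature columns identified.")
  x <- as.matrix(data[features])
  if (!is.numeric(x)) abort("feature columns must be numeric.")
  rownames(x) <- as.character(data$sample_id)
  x
}

fold_seed <- function(seed, fold) (seed * 1009L + fold) %% .Machine$integer.max

check_scores_finite <- function(s, where) {
  if (any(!is.finite(s))) abort(sprintf("adapter returned non-finite score in %s.", where))
  s
}

#' Leave-pair-out cross-validation
#'
#' For every rankable pair, a model is trained on all samples except the
#' pair's two members, both held-out samples are scored, and the pair's
#' verdict recorded. Per-sample scores are additionally pooled (averaged over
#' all pairs containing the sample) for downstream use.
#'
#' @param data Sample table: `sample_id`, the label column, feature columns.
#' @param pairs Rankable pairs from [rankable_pairs()].
#' @param adapter A [model_adapter()].
#' @param seed Integer seed; each fold's model gets a seed derived from
#'   `(seed, fold index)`.
#' @param features Optional character vector naming the feature columns.
#' @param label Name of the label column.
#' @return A list of class `paireval_lpocv`: `verdicts` (pair credits),
#'   `scores` (pooled per-sample score tibble with multiplicity `n_pooled`),
#'   and `auc` (the [auc_estimate()] over the verdicts).
#' @export
run_lpocv <- function(data, pairs, adapter, seed = 1L, features = NULL,
                      label = "label") {
  if (!inherits(adapter, "paireval_adapter")) abort("adapter must be a model_adapter().")
  if (nrow(data) < 3L) abort("LPOCV needs at least 3 samples.")
  if (nrow(pairs) < 1L) abort("no rankable pairs to evaluate.")
  x <- feature_matrix(data, features, label)
  y <- data[[label]]
  ids <- as.character(data$sample_id)
  absent <- setdiff(unique(c(pairs$hi, pairs$lo)), ids)
  if (length(absent) > 0L) {
    abort(sprintf("pair sample(s) missing from data: %s", paste(absent, collapse = ", ")))
  }
  row_of <- setNames(seq_along(ids), ids)

  n_pairs <- nrow(pairs)
  credit <- numeric(n_pairs)
  pred_id <- character(2L * n_pairs)
  pred_sc <- numeric(2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    hold <- c(row_of[[pairs$hi[i]]], row_of[[pairs$lo[i]]])
    state <- tryCatch(
      adapter$fit(x[-hold, , drop = FALSE], y[-hold], fold_seed(seed, i)),
      error = function(e) abort(sprintf(
        "adapter failed on LPOCV fold %d (pair %s / %s): %s",
        i, pairs$hi[i], pairs$lo[i], conditionMessage(e))))
    s <- check_scores_finite(
      adapter$score(state, x[hold, , drop = FALSE]),
      sprintf("LPOCV fold %d", i))
    credit[i] <- if (s[1] > s[2]) 1 else if (s[1] == s[2]) 0.5 else 0
    pred_id[c(2L * i - 1L, 2L * i)] <- c(pairs$hi[i], pairs$lo[i])
    pred_sc[c(2L * i - 1L, 2L * i)] <- s
  }
  verdicts <- tibble::tibble(hi = pairs$hi, lo = pairs$lo, credit = credit)
  scores <- pool_cv_scores(tibble::tibble(sample_id = pred_id, score = pred_sc))
  structure(list(verdicts = verdicts, scores = scores,
                 auc = auc_estimate(verdicts), adapter = adapter$name, seed = seed),
            class = "paireval_lpocv")
}

#' @export
print.paireval_lpocv <- function(x, ...) {
  cat(sprintf("<LPOCV run> %s, seed %d\n", x$adapter, x$seed))
  print(x$auc)
  invisible(x)
}

#' @method glance paireval_lpocv
#' @export
glance.paireval_lpocv <- function(x, ...) {
  dplyr::mutate(tidy(x$auc), adapter = x$adapter, seed = x$seed)
}

#' @method tidy paireval_lpocv
#' @export
tidy.paireval_lpocv <- function(x, ...) x$verdicts

#' Pool out-of-fold predictions into one score per sample
#'
#' When cross-validation produces several held-out scores for the same sample
#' (Monte Carlo repeats, LPOCV), the per-sample arithmetic mean is used for
#' paired evaluation.
#'
#' @param predictions Data frame with columns `sample_id`, `score` (one row
#'   per out-of-fold prediction).
#' @return A tibble `sample_id`, `score`, `n_pooled`.
#' @export
pool_cv_scores <- function(predictions) {
  if (!is.data.frame(predictions) ||
      !all(c("sample_id", "score") %in% names(predictions))) {
    abort("predictions must have columns sample_id and score.")
  }
  if (nrow(predictions) == 0L) abort("no predictions to pool.")
  predictions |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_pooled = dplyr::n(), score = mean(.data$score),
                     .groups = "drop") |>
    dplyr::select("sample_id", "score", "n_pooled")
}

#' Describe a cross-validation plan
#'
#' @param scheme `"kfold"`, `"loo"`, or `"monte_carlo"` (repeated random
#'   train/test splits). Leave-pair-out is run directly via [run_lpocv()].
#' @param k Number of folds (kfold).
#' @param n_repeats,test_fraction Monte Carlo parameters (e.g. 80%/20% splits
#'   with `test_fraction = 0.2`).
#' @param seed Integer seed driving fold assignment.
#' @return A `paireval_cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "loo", "monte_carlo"), k = 10L,
                    n_repeats = 20L, test_fraction = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold" && (!is.numeric(k) || k < 2)) abort("kfold needs k >= 2.")
  if (scheme == "monte_carlo") {
    if (n_repeats < 1) abort("monte_carlo needs n_repeats >= 1.")
    if (test_fraction <= 0 || test_fraction >= 1) abort("test_fraction must be in (0, 1).")
  }
  if (is.null(seed)) abort("a seed is mandatory for cross-validation plans.")
  structure(list(scheme = scheme, k = as.integer(k),
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "paireval_cv_plan")
}

#' Run cross-validation and pool out-of-fold scores
#'
#' Every sample is scored while held out at least once (exactly once for
#' k-fold and leave-one-out); Monte Carlo repeats are pooled by averaging.
#' Fold assignment is a seeded shuffle followed by a contiguous split, so fold
#' sizes differ by at most one.
#'
#' @inheritParams run_lpocv
#' @param plan A [cv_plan()].
#' @return A pooled score tibble (`sample_id`, `score`, `n_pooled`).
#' @export
run_cv <- function(data, plan, adapter, features = NULL, label = "label") {
  if (!inherits(plan, "paireval_cv_plan")) abort("plan must come from cv_plan().")
  if (!inherits(adapter, "paireval_adapter")) abort("adapter must be a model_adapter().")
  x <- feature_matrix(data, features, label)
  y <- data[[label]]
  ids <- as.character(data$sample_id)
  n <- length(ids)

  fold_sets <- switch(plan$scheme,
    loo = as.list(seq_len(n)),
    kfold = {
      if (plan$k > n) abort("k exceeds the number of samples.")
      perm <- sample_with_seed(n, plan$seed)
      unname(split(perm, cut(seq_len(n), plan$k, labels = FALSE)))
    },
    monte_carlo = {
      n_test <- max(1L, round(plan$test_fraction * n))
      if (n_test >= n) abort("test fraction leaves no training samples.")
      lapply(seq_len(plan$n_repeats), function(r) {
        sample_with_seed(n, fold_seed(plan$seed, r))[seq_len(n_test)]
      })
    })

  preds <- purrr::imap(fold_sets, function(test_rows, f) {
    if (length(test_rows) >= n) abort("fold leaves no training samples.")
    state <- tryCatch(
      adapter$fit(x[-test_rows, , drop = FALSE], y[-test_rows],
                  fold_seed(plan$seed, f)),
      error = function(e) abort(sprintf("adapter failed on fold %d: %s",
                                        f, conditionMessage(e))))
    s <- check_scores_finite(adapter$score(state, x[test_rows, , drop = FALSE]),
                             sprintf("fold %d", f))
    tibble::tibble(sample_id = ids[test_rows], score = s)
  })
  pooled <- pool_cv_scores(dplyr::bind_rows(preds))
  uncovered <- setdiff(ids, pooled$sample_id)
  if (length(uncovered) > 0L) {
    abort(sprintf("samples never held out under this plan: %s",
                  paste(uncovered, collapse = ", ")))
  }
  pooled
}

# seeded permutation that leaves the caller's RNG state untouched
sample_with_seed <- function(n, seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  sample.int(n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit on the full dataset and rank feature importances
#'
#' @inheritParams run_lpocv
#' @return A tibble `feature`, `importance`, sorted descending.
#' @export
fit_full_and_importances <- function(data, adapter, seed = 1L, features = NULL,
                                     label = "label") {
  if (!inherits(adapter, "paireval_adapter")) abort("adapter must be a model_adapter().")
  if (is.null(adapter$importances)) {
    abort(sprintf("adapter '%s' does not expose feature importances.", adapter$name))
  }
  x <- feature_matrix(data, features, label)
  state <- adapter$fit(x, data[[label]], seed)
  imp <- adapter$importances(state)
  if (is.null(names(imp)) || any(names(imp) == "")) names(imp) <- colnames(x)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
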
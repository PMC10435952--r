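#' Simulate an expression-like dataset with a confounder, replicates, and
#' outliers
#'
#' Generates the statistical structure paired evaluation is designed to probe:
#' standard-normal features, a block of signal features whose mean drives the
#' label, a confounder that shifts both a block of features and (optionally)
#' the label, technical-replicate noise from which per-sample label standard
#' deviations are estimated, and outlier samples whose label is replaced by a
#' draw from the opposite tail of the label distribution (their features stay
#' untouched, mimicking a sample whose molecular profile clusters with one
#' group while its response resembles the other).
#'
#' Defaults emulate a small-sample drug-response study: 60 samples, 100
#' features of which 10 carry signal, a binary confounder (two molecular
#' subtypes) shifting its own block of 10 features by one standard deviation,
#' label noise 0.3, and triplicate technical replicates with SD 0.2. The
#' continuous confounder mode draws ages uniformly on [65, 95], to be censored
#' at 90 downstream.
#'
#' @param n_samples,n_features,n_signal_features Dataset dimensions; the
#'   signal block defaults to `min(10, n_features)` features.
#' @param beta_signal Effect of the signal-feature mean on the label.
#' @param beta_confounder Effect of the (standardised) confounder on the label.
#' @param confounder_kind `"binary"` or `"continuous_censored"`.
#' @param n_confounder_features Size of the feature block shifted by the
#'   confounder; defaults to `min(10, n_features - n_signal_features)` and is
#'   always disjoint from the signal block.
#' @param confounder_feature_shift Mean shift applied to that block per unit
#'   of standardised confounder.
#' @param noise_sd Label noise SD.
#' @param n_replicates,replicate_sd Technical replicates per sample and their
#'   noise SD; the per-sample `replicate_sd` column is the empirical SD across
#'   the replicate draws.
#' @param n_outliers Number of samples whose label is replaced by an
#'   opposite-tail draw.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A tibble with columns `sample_id`, `label`, `replicate_sd`,
#'   `confounder`, `is_outlier`, and feature columns `feat_001`, ...; the
#'   feature column names are recorded in the `features` attribute and the
#'   call parameters in the `params` attribute.
#' @export
simulate_dataset <- function(n_samples = 60L, n_features = 100L,
                             n_signal_features = NULL, beta_signal = 1,
                             beta_confounder = 0,
                             confounder_kind = c("binary", "continuous_censored"),
                             n_confounder_features = NULL,
                             confounder_feature_shift = 1,
                             noise_sd = 0.3, n_replicates = 3L,
                             replicate_sd = 0.2, n_outliers = 0L, seed = 1L) {
  confounder_kind <- match.arg(confounder_kind)
  # default block sizes: 10 of each where the matrix allows, and the
  # confounder block never overlaps the signal block
  if (is.null(n_signal_features)) n_signal_features <- min(10L, n_features)
  if (is.null(n_confounder_features)) {
    n_confounder_features <- min(10L, n_features - n_signal_features)
  }
  stopifnot(n_samples >= 2, n_features >= 1,
            n_signal_features >= 0, n_signal_features <= n_features,
            n_confounder_features >= 0,
            n_signal_features + n_confounder_features <= n_features,
            noise_sd >= 0, replicate_sd >= 0,
            n_replicates >= 2, n_outliers >= 0, n_outliers <= n_samples)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  n <- as.integer(n_samples); p <- as.integer(n_features)
  x <- matrix(rnorm(n * p), nrow = n)
  colnames(x) <- sprintf("feat_%03d", seq_len(p))

  if (confounder_kind == "binary") {
    conf <- rbinom(n, 1L, 0.5)
    conf_std <- conf - mean(c(0, 1))
  } else {
    conf <- runif(n, 65, 95)
    conf_std <- (conf - 80) / 10
  }
  # the confounder leaves a molecular footprint: shift a feature block
  # disjoint from the signal block
  if (n_confounder_features > 0) {
    cf <- n_signal_features + seq_len(n_confounder_features)
    x[, cf] <- x[, cf] + confounder_feature_shift * conf_std
  }

  signal <- if (n_signal_features > 0) {
    rowMeans(x[, seq_len(n_signal_features), drop = FALSE])
  } else rep(0, n)
  label <- beta_signal * signal + beta_confounder * conf_std + rnorm(n, 0, noise_sd)

  reps <- matrix(label, n, n_replicates) +
    matrix(rnorm(n * n_replicates, 0, replicate_sd), n)
  rep_sd <- apply(reps, 1L, sd)

  is_outlier <- rep(FALSE, n)
  if (n_outliers > 0) {
    # flip samples away from the label median: an "opposite tail" only exists
    # for samples that sit in a tail themselves (the real-data archetype is a
    # sample whose profile clearly belongs to one group while its response
    # matches the other)
    dist_med <- abs(label - median(label))
    outer <- which(dist_med >= quantile(dist_med, 0.5))
    if (length(outer) < n_outliers) outer <- order(dist_med, decreasing = TRUE)
    flip <- outer[sample.int(length(outer), n_outliers)]
    is_outlier[flip] <- TRUE
    for (k in flip) {
      # draw from the opposite tail: lower quartile if the sample sits above
      # the median, upper quartile otherwise
      opp <- if (label[k] > median(label)) {
        label[!is_outlier & label <= quantile(label, 0.25)]
      } else {
        label[!is_outlier & label >= quantile(label, 0.75)]
      }
      label[k] <- opp[sample.int(length(opp), 1L)] + rnorm(1L, 0, noise_sd)
    }
  }

  out <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    label = label, replicate_sd = rep_sd,
    confounder = conf, is_outlier = is_outlier) |>
    dplyr::bind_cols(tibble::as_tibble(x))
  attr(out, "features") <- colnames(x)
  attr(out, "params") <- list(
    n_samples = n, n_features = p, n_signal_features = n_signal_features,
    beta_signal = beta_signal, beta_confounder = beta_confounder,
    confounder_kind = confounder_kind,
    n_confounder_features = n_confounder_features,
    confounder_feature_shift = confounder_feature_shift, noise_sd = noise_sd,
    n_replicates = n_replicates, replicate_sd = replicate_sd,
    n_outliers = n_outliers, seed = seed)
  out
}

#' A fixed hand-enumerable toy dataset
#'
#' Eight samples with binary labels, two features, and a frozen score table.
#' All 16 cross-class pairs are rankable under indicator rankability; one
#' score tie and one inversion are built in, so the exhaustive AUC is
#' 13.5 / 16 = 0.84375 (enumerated by hand once and frozen).
#'
#' @return A list: `samples` (tibble), `scores` (named vector),
#'   `expected_auc`, `expected_n_pairs`.
#' @export
make_toy_fixture <- function() {
  samples <- tibble::tibble(
    sample_id = paste0("t", 1:8),
    label = c(0, 0, 0, 0, 1, 1, 1, 1),
    feat_001 = c(-1.2, -0.8, -0.1, 0.6, 0.9, 0.4, -0.2, 0.7),
    feat_002 = c(0.3, -0.5, 0.1, -0.9, 1.1, 0.2, 0.8, -0.4))
  attr(samples, "features") <- c("feat_001", "feat_002")
  scores <- c(t1 = 0.1, t2 = 0.2, t3 = 0.4, t4 = 0.7,
              t5 = 0.9, t6 = 0.8, t7 = 0.4, t8 = 0.6)
  list(samples = samples, scores = scores,
       expected_auc = 13.5 / 16, expected_n_pairs = 16L)
}
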
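# Independent oracles used across the suite. These never call the code paths
# they check.

# O(n^2) inversion count by double loop
brute_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    total <- total + sum(x[i] > x[(i + 1L):n])
  }
  total
}

# Wilcoxon-Mann-Whitney AUC from ranks (average ranks give ties half credit)
wmw_auc <- function(labels, scores) {
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Fisher p by full enumeration of all 2x2 tables with the observed margins
enum_fisher <- function(tab, alternative) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(c1, x) * choose(r1 + r2 - c1, r1 - x) / choose(r1 + r2, r1)
  }, numeric(1))
  p_obs <- probs[support == a]
  switch(alternative,
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]),
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exhaustive paired-evaluation AUC for indicator rankability, by pair listing
enum_indicator_auc <- function(labels, scores) {
  n <- length(labels)
  credit <- 0; n_pairs <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (labels[i] == labels[j]) next
    n_pairs <- n_pairs + 1L
    hi <- if (labels[i] > labels[j]) i else j
    lo <- if (labels[i] > labels[j]) j else i
    credit <- credit + if (scores[hi] > scores[lo]) 1 else
      if (scores[hi] == scores[lo]) 0.5 else 0
  }
  list(auc = credit / n_pairs, n_pairs = n_pairs, credit = credit)
}

# Adapters for harness tests ------------------------------------------------

# scores the held-out samples by their first feature
adapter_first_feature <- function() {
  model_adapter(function(x, y, seed) NULL,
                function(state, x) x[, 1], name = "first feature")
}

adapter_constant <- function(value = 0) {
  model_adapter(function(x, y, seed) value,
                function(state, x) rep(state, nrow(x)), name = "constant")
}

adapter_neg_first_feature <- function() {
  model_adapter(function(x, y, seed) NULL,
                function(state, x) -x[, 1], name = "negated first feature")
}

# records every training set and refuses to score a sample it has seen
adapter_leak_guard <- function(log_env) {
  model_adapter(
    fit = function(x, y, seed) rownames(x),
    score = function(state, x) {
      leaked <- intersect(rownames(x), state)
      if (length(leaked) > 0L) {
        stop("leak: scored sample(s) present in training set: ",
             paste(leaked, collapse = ", "))
      }
      log_env$n_folds <- (log_env$n_folds %||% 0L) + 1L
      x[, 1]
    },
    name = "leak guard")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data where the label IS the first feature, so adapter_first_feature is a
# perfect oracle predictor
make_identity_data <- function(n = 10, seed = 1) {
  set.seed(seed)
  lab <- sample(c(0, 1), n, replace = TRUE)
  while (length(unique(lab)) < 2) lab <- sample(c(0, 1), n, replace = TRUE)
  d <- tibble::tibble(sample_id = sprintf("x%02d", seq_len(n)),
                      label = lab,
                      feat_001 = lab,
                      feat_002 = rnorm(n))
  attr(d, "features") <- c("feat_001", "feat_002")
  d
}
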
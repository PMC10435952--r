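test_that("LPOCV with an oracle / constant / anti-oracle adapter", {
  d <- make_identity_data(n = 10, seed = 2)
  prs <- rankable_pairs(d, delta_spec("indicator"))
  oracle <- run_lpocv(d, prs, adapter_first_feature(), seed = 1)
  expect_true(all(oracle$verdicts$credit == 1))
  expect_equal(oracle$auc$auc, 1)
  constant <- run_lpocv(d, prs, adapter_constant(), seed = 1)
  expect_true(all(constant$verdicts$credit == 0.5))
  expect_equal(constant$auc$auc, 0.5)
  anti <- run_lpocv(d, prs, adapter_neg_first_feature(), seed = 1)
  expect_equal(anti$auc$auc, 0)
})

test_that("LPOCV never leaks the held-out pair into training", {
  d <- make_identity_data(n = 12, seed = 3)
  prs <- rankable_pairs(d, delta_spec("indicator"))
  log_env <- new.env()
  expect_no_error(run_lpocv(d, prs, adapter_leak_guard(log_env), seed = 1))
  expect_equal(log_env$n_folds, nrow(prs))
})

test_that("pooled LPOCV scores average over the pairs containing a sample", {
  d <- make_identity_data(n = 8, seed = 4)
  prs <- rankable_pairs(d, delta_spec("indicator"))
  r <- run_lpocv(d, prs, adapter_first_feature(), seed = 1)
  counts <- table(c(prs$hi, prs$lo))
  expect_equal(sort(r$scores$sample_id), sort(names(counts)))
  expect_equal(r$scores$n_pooled[match(names(counts), r$scores$sample_id)],
               as.integer(counts), ignore_attr = TRUE)
})

test_that("pool_cv_scores is the per-sample mean with multiplicity", {
  preds <- tibble::tibble(sample_id = c("a", "a", "b"),
                          score = c(0.2, 0.4, 0.7))
  pooled <- pool_cv_scores(preds)
  expect_equal(pooled$score[pooled$sample_id == "a"], 0.3)
  expect_equal(pooled$n_pooled[pooled$sample_id == "a"], 2L)
  expect_equal(pooled$score[pooled$sample_id == "b"], 0.7)
  expect_error(pool_cv_scores(preds[0, ]), "no predictions")
})

test_that("run_cv covers every sample and respects the scheme", {
  d <- make_identity_data(n = 11, seed = 5)
  loo <- run_cv(d, cv_plan("loo"), adapter_first_feature())
  expect_equal(nrow(loo), 11L)
  expect_true(all(loo$n_pooled == 1L))

  k5 <- run_cv(d, cv_plan("kfold", k = 5, seed = 2), adapter_first_feature())
  expect_equal(nrow(k5), 11L)
  expect_true(all(k5$n_pooled == 1L))

  mc <- run_cv(d, cv_plan("monte_carlo", n_repeats = 30, test_fraction = 0.2,
                          seed = 3), adapter_first_feature())
  mc2 <- run_cv(d, cv_plan("monte_carlo", n_repeats = 30, test_fraction = 0.2,
                           seed = 3), adapter_first_feature())
  expect_identical(mc, mc2) # same plan + seed => identical pooled scores
  expect_error(run_cv(d, cv_plan("kfold", k = 50, seed = 1),
                      adapter_first_feature()), "exceeds")
})

test_that("kfold fold sizes differ by at most one", {
  set.seed(6)
  d <- make_identity_data(n = 63, seed = 6)
  sizes <- integer(0)
  counting <- model_adapter(
    fit = function(x, y, seed) { sizes <<- c(sizes, 63L - nrow(x)); NULL },
    score = function(state, x) x[, 1], name = "size counter")
  run_cv(d, cv_plan("kfold", k = 5, seed = 9), counting)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), 63L)
})

test_that("strong-signal AUC agrees across LPOCV, LOO, and 10-fold", {
  d <- make_identity_data(n = 24, seed = 7)
  prs <- rankable_pairs(d, delta_spec("indicator"))
  a_lpocv <- run_lpocv(d, prs, adapter_first_feature(), seed = 1)$auc$auc
  a_loo <- auc_bruteforce(prs, run_cv(d, cv_plan("loo"), adapter_first_feature()))$auc
  a_k10 <- auc_bruteforce(
    prs, run_cv(d, cv_plan("kfold", k = 10, seed = 4), adapter_first_feature()))$auc
  expect_lt(max(c(a_lpocv, a_loo, a_k10)) - min(c(a_lpocv, a_loo, a_k10)), 0.05)
})

test_that("full-fit importances rank a fully determining feature first", {
  skip_if_not_installed("ranger")
  set.seed(8)
  d <- tibble::tibble(sample_id = sprintf("r%02d", 1:40),
                      label = rnorm(40))
  d$feat_001 <- d$label
  d$feat_002 <- rnorm(40)
  d$feat_003 <- rnorm(40)
  attr(d, "features") <- c("feat_001", "feat_002", "feat_003")
  imp <- fit_full_and_importances(d, adapter_random_forest(num_trees = 100),
                                  seed = 10)
  expect_equal(imp$feature[1], "feat_001")
  expect_true(all(diff(imp$importance) <= 0))
  imp2 <- fit_full_and_importances(d, adapter_random_forest(num_trees = 100),
                                   seed = 10)
  expect_identical(imp, imp2)
  expect_error(fit_full_and_importances(d, adapter_first_feature()),
               "importances")
})

test_that("ridge and logistic adapters learn an easy signal", {
  set.seed(9)
  n <- 30
  d <- tibble::tibble(sample_id = sprintf("g%02d", 1:n),
                      feat_001 = rnorm(n), feat_002 = rnorm(n))
  d$label <- as.numeric(d$feat_001 > 0)
  attr(d, "features") <- c("feat_001", "feat_002")
  prs <- rankable_pairs(d, delta_spec("indicator"))
  expect_gt(run_lpocv(d, prs, adapter_ridge(), seed = 1)$auc$auc, 0.85)
  expect_gt(run_lpocv(d, prs, adapter_logistic(), seed = 1)$auc$auc, 0.85)
})
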
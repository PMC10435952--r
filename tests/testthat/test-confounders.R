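test_that("discrete split partitions the pair set by shared confounder", {
  d <- tibble::tibble(sample_id = c("l1", "l2", "b1", "b2"),
                      label = c(0.1, 0.9, 0.4, 0.95),
                      subtype = c("luminal", "luminal", "basal", "basal"))
  prs <- rankable_pairs(d, delta_spec("absolute_difference",
                                      constant_delta = 0))
  expect_equal(nrow(prs), 6L)
  sp <- split_pairs_discrete(prs, d, "subtype")
  expect_equal(nrow(sp$matched), 2L)
  expect_equal(nrow(sp$mismatched), 4L)
  key <- function(p) paste(p$hi, p$lo)
  expect_setequal(c(key(sp$matched), key(sp$mismatched)), key(prs))
  expect_length(intersect(key(sp$matched), key(sp$mismatched)), 0L)

  d_same <- dplyr::mutate(d, subtype = "luminal")
  sp_same <- split_pairs_discrete(prs, d_same, "subtype")
  expect_equal(nrow(sp_same$matched), 6L)
  expect_equal(nrow(sp_same$mismatched), 0L)

  d_na <- d; d_na$subtype[2] <- NA
  expect_error(split_pairs_discrete(prs, d_na, "subtype"), "l2")
})

test_that("continuous selection pairs each sample with its nearest confounder partner", {
  d <- tibble::tibble(
    sample_id = c("idx", "near", "far", "far2"),
    label = c(0, 1, 1, 0),
    age = c(75, 74, 89, 88))
  prs <- rankable_pairs(d, delta_spec("indicator"))
  sel <- select_pairs_continuous(prs, d, "age", seed = 1)
  # the index sample's matched partner is the 74-year-old
  expect_true(any(sel$matched$hi == "near" | sel$matched$lo == "near"))
  got <- sel$matched[sel$matched$hi == "near" | sel$matched$lo == "near", ]
  expect_true("idx" %in% c(got$hi, got$lo))
  # its max-separation partner is the 89-year-old
  expect_true(any((sel$mismatched$hi == "far" & sel$mismatched$lo == "idx") |
                  (sel$mismatched$hi == "idx" & sel$mismatched$lo == "far")))
})

test_that("censored confounder values count as perfectly matched", {
  d <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    label = c(0, 1, 1),
    age = c(92, 94, 70)) # a and b both in the 90+ category
  prs <- rankable_pairs(d, delta_spec("indicator"))
  sel <- select_pairs_continuous(prs, d, "age", censor_at = 90, seed = 1)
  ab <- sel$matched[(sel$matched$hi == "b" & sel$matched$lo == "a"), ]
  expect_equal(nrow(ab), 1L) # zero censored-censored gap beats |92 - 70|
})

test_that("continuous selection is deterministic given the seed and bounds gaps", {
  set.seed(37)
  d <- tibble::tibble(sample_id = sprintf("p%02d", 1:20),
                      label = sample(c(0, 1), 20, replace = TRUE),
                      age = runif(20, 65, 95))
  prs <- suppressWarnings(rankable_pairs(d, delta_spec("indicator")))
  s1 <- select_pairs_continuous(prs, d, "age", censor_at = 90, seed = 5)
  s2 <- select_pairs_continuous(prs, d, "age", censor_at = 90, seed = 5)
  expect_identical(s1, s2)
  # with max_difference, each index sample's matched gap <= mismatched gap
  gap <- function(p) abs(d$age[match(p$hi, d$sample_id)] -
                         d$age[match(p$lo, d$sample_id)])
  for (id in d$sample_id) {
    m <- s1$matched[s1$matched$hi == id | s1$matched$lo == id, ]
    x <- s1$mismatched[s1$mismatched$hi == id | s1$mismatched$lo == id, ]
    if (nrow(m) > 0 && nrow(x) > 0) expect_lte(min(gap(m)), max(gap(x)))
  }
})

test_that("confounder_effect contrasts matched and mismatched verdicts", {
  matched <- tibble::tibble(hi = sprintf("m%02d", 1:20),
                            lo = sprintf("mm%02d", 1:20), delta_used = 0.5)
  mismatched <- tibble::tibble(hi = sprintf("x%02d", 1:20),
                               lo = sprintf("xx%02d", 1:20), delta_used = 0.5)
  v <- dplyr::bind_rows(
    tibble::tibble(hi = matched$hi, lo = matched$lo,
                   credit = rep(c(1, 0), each = 10)),
    tibble::tibble(hi = mismatched$hi, lo = mismatched$lo, credit = 1))
  eff <- confounder_effect(v, matched, mismatched)
  expect_equal(eff$auc_matched$auc, 0.5)
  expect_equal(eff$auc_mismatched$auc, 1)
  expect_equal(eff$auc_all$auc, 0.75)
  expect_equal(eff$delta_auc, 0.25)
  expect_lt(eff$p_value, 0.01)
  expect_equal(unname(eff$table["matched", ]), c(10, 10))
  expect_error(confounder_effect(v, matched[0, ], mismatched), "empty")
})

test_that("Fisher p is uniform when correctness is independent of matching", {
  set.seed(41)
  n <- 60
  pairs_all <- tibble::tibble(hi = sprintf("h%02d", 1:n),
                              lo = sprintf("l%02d", 1:n), delta_used = 0.5)
  credit <- rbinom(n, 1, 0.7)
  v <- tibble::tibble(hi = pairs_all$hi, lo = pairs_all$lo, credit = credit)
  ps <- replicate(400, {
    flag <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(flag) || !any(flag)) return(NA_real_)
    confounder_effect(v, pairs_all[flag, ], pairs_all[!flag, ])$p_value
  })
  ps <- ps[!is.na(ps)]
  # one-sided exact p under the null: stochastically >= uniform; KS distance
  # of the subuniform empirical CDF from uniform stays moderate
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("anova_f reproduces the classical F statistic", {
  res <- anova_f(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  same <- anova_f(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_error(anova_f(1:5, c("a", "a", "b", "b", "c")), "c")
  # permutation oracle: null data give an F well inside the permutation cloud
  set.seed(43)
  y <- rnorm(24); g <- rep(letters[1:3], each = 8)
  obs <- anova_f(y, g)$statistic
  perm <- replicate(200, anova_f(y, sample(g))$statistic)
  expect_gt(mean(perm >= obs), 0.05)
})
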
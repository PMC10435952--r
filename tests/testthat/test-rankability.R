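test_that("pair_delta follows the spec for each mode", {
  rep_spec <- delta_spec("absolute_difference", use_replicate_sd = TRUE)
  expect_equal(pair_delta(sd_a = 0.2, sd_b = 0.05, spec = rep_spec), 0.2)
  expect_equal(pair_delta(spec = delta_spec("indicator")), 0.5)
  expect_equal(
    pair_delta(spec = delta_spec("absolute_difference", constant_delta = 0.3)),
    0.3)
  expect_error(pair_delta(sd_a = 0.2, spec = rep_spec), "replicate_sd")
})

test_that("delta_spec validates its invariants", {
  expect_error(delta_spec("indicator", constant_delta = 1), "indicator")
  expect_error(delta_spec("absolute_difference"), "exactly one")
  expect_error(delta_spec("absolute_difference", constant_delta = 0.1,
                          use_replicate_sd = TRUE), "exactly one")
  expect_error(delta_spec("absolute_difference", constant_delta = -1),
               "non-negative")
})

test_that("is_rankable applies the label-separation rule and is symmetric", {
  ind <- delta_spec("indicator")
  rep_spec <- delta_spec("absolute_difference", use_replicate_sd = TRUE)
  expect_true(is_rankable(0, 1, spec = ind))
  expect_false(is_rankable(0.50, 0.60, sd_a = 0.2, sd_b = 0.05, spec = rep_spec))
  expect_true(is_rankable(0.50, 0.80, sd_a = 0.2, sd_b = 0.05, spec = rep_spec))
  # identical labels are never rankable, whatever the mode
  expect_false(is_rankable(0.4, 0.4, spec = ind))
  expect_false(is_rankable(0.4, 0.4, sd_a = 0, sd_b = 0, spec = rep_spec))
  expect_false(is_rankable(
    0.4, 0.4, spec = delta_spec("absolute_difference", constant_delta = 0)))
  # symmetry over random inputs
  set.seed(42)
  for (i in 1:50) {
    a <- round(runif(1), 2); b <- round(runif(1), 2)
    sa <- runif(1, 0, 0.3); sb <- runif(1, 0, 0.3)
    spec <- if (i %% 2) ind else rep_spec
    expect_identical(is_rankable(a, b, sa, sb, spec),
                     is_rankable(b, a, sb, sa, spec))
  }
})

test_that("rankable_pairs builds the oriented pair set", {
  labs <- tibble::tibble(sample_id = c("a", "b", "c"), label = c(0, 0, 1))
  p <- rankable_pairs(labs, delta_spec("indicator"))
  expect_equal(nrow(p), 2L)
  expect_true(all(p$hi == "c"))
  expect_setequal(p$lo, c("a", "b"))
  expect_equal(p$delta_used, c(0.5, 0.5))

  labs2 <- tibble::tibble(sample_id = c("a", "b", "c"),
                          label = c(0.1, 0.2, 0.9))
  p2 <- rankable_pairs(labs2, delta_spec("absolute_difference",
                                         constant_delta = 0.3))
  expect_equal(nrow(p2), 2L)
  expect_true(all(p2$hi == "c"))

  labs3 <- tibble::tibble(sample_id = letters[1:4], label = rep(1, 4))
  expect_warning(p3 <- rankable_pairs(labs3, delta_spec("indicator")),
                 "no rankable pairs")
  expect_equal(nrow(p3), 0L)

  expect_error(rankable_pairs(labs[1, ], delta_spec("indicator")),
               "at least 2")
  expect_error(
    rankable_pairs(tibble::tibble(sample_id = c("a", "a"), label = 0:1)),
    "duplicate")
})

test_that("binary indicator pair count is positives x negatives", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    labs <- tibble::tibble(sample_id = as.character(seq_len(n)), label = lab)
    p <- suppressWarnings(rankable_pairs(labs, delta_spec("indicator")))
    expect_equal(nrow(p), sum(lab == 1) * sum(lab == 0))
    expect_lte(nrow(p), n * (n - 1) / 2)
    expect_false(any(duplicated(paste(pmin(p$hi, p$lo), pmax(p$hi, p$lo)))))
  }
})

test_that("increasing constant delta never adds pairs", {
  set.seed(11)
  labs <- tibble::tibble(sample_id = sprintf("s%02d", 1:25),
                         label = round(rnorm(25), 2))
  sizes <- vapply(seq(0, 2, by = 0.1), function(d) {
    nrow(suppressWarnings(
      rankable_pairs(labs, delta_spec("absolute_difference",
                                      constant_delta = d))))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ordinal multi-class labels are rankable when categories differ", {
  severity <- tibble::tibble(
    sample_id = sprintf("b%d", 1:6),
    label = factor(c("mild", "mild", "moderate", "severe", "severe", "moderate"),
                   levels = c("mild", "moderate", "severe"), ordered = TRUE))
  p <- rankable_pairs(severity)
  # cross-category pairs only: 2*2 + 2*2 + 2*2
  expect_equal(nrow(p), 12L)
  hi_lab <- severity$label[match(p$hi, severity$sample_id)]
  lo_lab <- severity$label[match(p$lo, severity$sample_id)]
  expect_true(all(hi_lab > lo_lab))
})

test_that("the default spec is chosen from the label structure", {
  few <- tibble::tibble(sample_id = as.character(1:6), label = rep(0:1, 3))
  expect_message(rankable_pairs(few), "indicator")
  many <- tibble::tibble(sample_id = as.character(1:20),
                         label = seq(0, 1, length.out = 20))
  expect_message(rankable_pairs(many), "constant delta = 0")
})
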
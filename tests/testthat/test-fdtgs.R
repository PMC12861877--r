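test_that("partition_by_thresholds boundary semantics and exhaustiveness", {
  pair <- threshold_pair(0.4827, 0.9729) # the reference AVG pair
  p <- partition_by_thresholds(c(0.10, 0.50, 0.99), pair)
  expect_equal(p$NS, 1L)
  expect_equal(p$U, 2L)
  expect_equal(p$RP, 3L)

  # t_low = 0 admits only s = 0 into NS; interior scores all uncertain
  p0 <- partition_by_thresholds(c(0.2, 0.5, 0.8), threshold_pair(0, 1))
  expect_length(p0$NS, 0)
  expect_length(p0$RP, 0)
  expect_length(p0$U, 3)

  withr::with_seed(2, {
    s <- stats::runif(200)
    pr <- partition_by_thresholds(s, threshold_pair(0.3, 0.7))
    expect_equal(sort(c(pr$RP, pr$NS, pr$U)), seq_along(s))
    expect_length(intersect(pr$RP, pr$NS), 0)
  })
  expect_error(threshold_pair(0.8, 0.5), "t_low < t_high")
})

test_that("threshold monotonicity over random score sets", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      s <- stats::runif(100)
      lows <- sort(stats::runif(4, 0, 0.45))
      highs <- sort(stats::runif(4, 0.55, 1))
      n_rp <- vapply(highs, function(h)
        length(partition_by_thresholds(s, threshold_pair(0.1, h))$RP), 0L)
      expect_true(all(diff(n_rp) <= 0)) # raising t_high never grows RP
      n_ns <- vapply(lows, function(l)
        length(partition_by_thresholds(s, threshold_pair(l, 0.9))$NS), 0L)
      expect_true(all(diff(n_ns) >= 0)) # lowering t_low never grows NS
    }
  })
})

test_that("score_patches honors the scorer contract", {
  spec <- tiny_spec(n_benign = 30, n_malignant = 30)
  ds <- build_channel_dataset(spec, seed = 19)
  f <- patch_feature_matrix(ds$patches)
  tr <- ds$split == "train"
  scorer <- make_seed_scorer(f[tr, ], ds$labels[tr])
  s <- score_patches(scorer, f)
  expect_true(all(s >= 0 & s <= 1))
  # per-patch function: reordering input reorders output
  perm <- rev(seq_len(nrow(f)))
  expect_equal(score_patches(scorer, f[perm, ]), s[perm])
  # separable channel scores discriminate
  expect_gte(roc_auc(s, ds$labels)$auc, 0.9)
  expect_error(score_patches(structure(list(fitted = FALSE),
                                       class = "octx_scorer"), f),
               "not fitted")
})

test_that("evaluate_threshold_pair is deterministic and errors when degenerate", {
  bm <- beta_mixture_data(150, seed = 6)
  bb <- light_backbone()
  f1a <- evaluate_threshold_pair(threshold_pair(0.3, 0.7), bm$data, bb, 4)
  f1b <- evaluate_threshold_pair(threshold_pair(0.3, 0.7), bm$data, bb, 4)
  expect_identical(f1a, f1b)
  expect_gt(f1a, 0.8)
  expect_error(
    evaluate_threshold_pair(threshold_pair(0.1, 0.999999), bm$data, bb),
    "degenerate")
})

test_that("coarse stage equals exhaustive grid enumeration (oracle)", {
  bm <- beta_mixture_data(80, seed = 14) # 160 patches, within oracle scale
  bb <- light_backbone()
  # independent oracle: enumerate init + all feasible 0.1-grid pairs in
  # the same scan order with strict-improvement acceptance
  eval1 <- function(pair) {
    key <- paste(sum(bm$data$scores[bm$data$train_idx] <= pair$t_low),
                 sum(bm$data$scores[bm$data$train_idx] >= pair$t_high),
                 sep = "/")
    tryCatch(evaluate_threshold_pair(pair, bm$data, bb,
                                     seed = octx::sub_seed(21, paste0("eval/", key))),
             error = function(e) -Inf)
  }
  best <- threshold_pair(0.5, 0.8); best_f1 <- eval1(best)
  for (lo in seq(0, 0.5, 0.1)) for (hi in seq(0.5, 1, 0.1)) {
    if (lo >= hi) next
    cand <- threshold_pair(lo, hi)
    f1 <- eval1(cand)
    if (f1 > best_f1) { best <- cand; best_f1 <- f1 }
  }
  got <- fdtgs_search(bm$data, bb, rounds = 1, fine_window = 0,
                      resample_rounds = FALSE, seed = 21)
  expect_equal(got$trace$performance[1], best_f1)
  expect_equal(c(got$pair$t_low, got$pair$t_high),
               c(best$t_low, best$t_high))
})

test_that("search trace has one row per round with non-decreasing best", {
  bm <- beta_mixture_data(100, seed = 3)
  got <- fdtgs_search(bm$data, light_backbone(), rounds = 4,
                      fine_window = 0.01, seed = 8)
  expect_equal(nrow(got$trace), 4)
  expect_true(all(diff(got$trace$best_f1) >= 0))
  # log writer appends an AVG row over all rounds
  path <- withr::local_tempfile(fileext = ".csv")
  log <- write_search_log(got, path)
  expect_equal(nrow(log), 5)
  expect_equal(log$round[5], "AVG")
  expect_equal(log$low_threshold[5], mean(got$trace$t_low))
})

test_that("deterministic rounds: AVG thresholds reproduce the incumbent", {
  bm <- beta_mixture_data(100, seed = 44)
  got <- fdtgs_search(bm$data, light_backbone(), rounds = 3,
                      fine_window = 0.01,
                      resample_rounds = FALSE, seed = 12)
  expect_lte(abs(mean(got$trace$t_low) - got$pair$t_low), 0.001)
  expect_lte(abs(mean(got$trace$t_high) - got$pair$t_high), 0.001)
})

test_that("identical scores leave no feasible pair", {
  f <- matrix(rep(0.5, 60), ncol = 1)
  fd <- fdtgs_data(f, rep(0.5, 60), rep(0:1, 30), 1:40, 41:60)
  expect_error(fdtgs_search(fd, light_backbone(), rounds = 1, seed = 1),
               "no feasible")
})

test_that("RP purity beats unfiltered purity under 20% label noise", {
  # the double threshold's reason to exist: scores concentrate truth
  hits <- vapply(1:10, function(s) {
    withr::with_seed(500 + s, {
      n <- 300
      true <- rep(0:1, each = n / 2)
      noisy <- true
      flip <- sample(n, round(0.2 * n))
      noisy[flip] <- 1 - noisy[flip]
      scores <- stats::plogis(stats::qlogis(0.02 + 0.96 * true) +
                                stats::rnorm(n, 0, 1.5))
      part <- partition_by_thresholds(scores, threshold_pair(0.2, 0.8))
      rp_pure <- mean(true[part$RP] == 1)
      base_pure <- mean(true[noisy == 1] == 1)
      rp_pure > base_pure
    })
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
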
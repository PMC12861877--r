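test_that("decompose_into_patches tiles and drops borders as specified", {
  img <- matrix(seq_len(200 * 200) %% 256, 200, 200)
  g <- decompose_into_patches(img, 50)
  expect_equal(unname(g$grid_shape), c(4, 4))
  expect_length(g$patches, 16)
  expect_identical(reassemble_patches(g), img * 1)

  g2 <- decompose_into_patches(matrix(0, 120, 70), 50)
  expect_equal(unname(g2$grid_shape), c(2, 1))
  expect_length(g2$patches, 2)

  g3 <- decompose_into_patches(img[1:50, 1:50], 50)
  expect_length(g3$patches, 1)
  expect_identical(g3$patches[[1]], img[1:50, 1:50])

  expect_error(decompose_into_patches(matrix(0, 30, 60), 50), "smaller")
  expect_error(decompose_into_patches(img, 1), ">= 2")
})

test_that("compute_glcm matches the brute-force pair-count oracle", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      patch <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
      g <- compute_glcm(patch, distances = c(1, 2), levels = 8)
      offs <- list(d1_a0 = c(0, 1), d1_a45 = c(-1, 1), d1_a90 = c(-1, 0),
                   d1_a135 = c(-1, -1), d2_a0 = c(0, 2), d2_a45 = c(-2, 2),
                   d2_a90 = c(-2, 0), d2_a135 = c(-2, -2))
      for (nm in names(offs)) {
        expect_equal(g[[nm]], brute_glcm(patch, offs[[nm]][1],
                                         offs[[nm]][2], 8),
                     info = nm)
      }
    }
  })
})

test_that("GLCM matrices are symmetric, non-negative, and sum to 1", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      patch <- matrix(sample(0:255, 2500, replace = TRUE), 50, 50)
      for (m in compute_glcm(patch)) {
        expect_equal(sum(m), 1, tolerance = 1e-12)
        expect_true(all(m >= 0))
        expect_equal(m, t(m))
      }
    }
  })
})

test_that("feature vector: degenerate and checkerboard cases", {
  # constant patch: single diagonal GLCM entry
  const <- matrix(100, 50, 50)
  g <- compute_glcm(const)
  expect_equal(sum(g$d1_a0 != 0), 1)
  expect_equal(g$d1_a0[13, 13], 1) # level floor(100*32/256) = 12, 1-based 13
  v <- glcm_feature_vector(g)
  expect_length(v, 22)
  expect_equal(unname(v["energy_d1"]), 1)
  expect_equal(unname(v["entropy_d1"]), 0)
  expect_equal(unname(v["contrast_d1"]), 0)
  expect_equal(unname(v["correlation_d1"]), 0) # flagged convention
  expect_true(attr(v, "zero_variance"))

  # two-level checkerboard at distance 1, angle 0: all 12 horizontal pairs
  # differ by one level -> all mass off-diagonal, contrast 1
  cb <- checkerboard4()
  gcb <- compute_glcm(cb, levels = 2)
  expect_equal(sum(diag(gcb$d1_a0)), 0)
  L <- matrix(0:1, 2, 2); contrast <- sum(gcb$d1_a0 * (L - t(L))^2)
  expect_equal(contrast, 1)
  # oracle equality for the angle-averaged feature values
  vcb <- glcm_feature_vector(compute_glcm(cb, levels = 8))
  oracle <- sapply(list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                   function(o) brute_stats(brute_glcm(cb, o[1], o[2], 8)))
  expect_equal(unname(vcb[1:11]), unname(rowMeans(oracle)),
               tolerance = 1e-12)
})

test_that("angle-averaged features are invariant to 90-degree rotation", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      patch <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
      rot <- t(patch)[, nrow(patch):1] # 90-degree rotation
      v1 <- glcm_feature_vector(compute_glcm(patch))
      v2 <- glcm_feature_vector(compute_glcm(rot))
      expect_equal(unname(v1), unname(v2), tolerance = 1e-9)
    }
  })
})

test_that("bin-preserving intensity shifts leave the features unchanged", {
  withr::with_seed(9, {
    # intensities at bin centers; shifting by < bin width keeps bins
    patch <- matrix(sample(seq(4, 252, by = 8), 400, replace = TRUE),
                    20, 20)
    v1 <- glcm_feature_vector(compute_glcm(patch))
    v2 <- glcm_feature_vector(compute_glcm(patch + 3))
    expect_equal(unname(v1), unname(v2))
  })
})

test_that("label_patch_from_mask applies the inclusive coverage rule", {
  mask <- matrix(0L, 100, 100)
  mask[1:50, 1:50] <- 1L
  expect_equal(label_patch_from_mask(0, 0, 50, mask), 1L)
  expect_equal(label_patch_from_mask(1, 1, 50, mask), 0L)
  # exactly tau * P^2 lesion pixels -> malignant (inclusive)
  half <- matrix(0L, 50, 50); half[1:25, ] <- 1L
  expect_equal(label_patch_from_mask(0, 0, 50, half, tau = 0.5), 1L)
  half[1, 1] <- 0L
  expect_equal(label_patch_from_mask(0, 0, 50, half, tau = 0.5), 0L)
})

test_that("fuse_feature_map normalizes to [0,1] with the zero convention", {
  img <- matrix(sample(0:255, 200 * 200, replace = TRUE), 200, 200)
  g <- decompose_into_patches(img, 50)
  f <- patch_feature_matrix(g)
  m <- fuse_feature_map(g, f, "contrast_d1")
  expect_equal(dim(m), c(4, 4))
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
  fc <- f; fc[, "contrast_d1"] <- 5
  expect_true(all(fuse_feature_map(g, fc, "contrast_d1") == 0))
  expect_error(fuse_feature_map(g, f, "nope"), "unknown feature")
})

test_that("patch_association odds ratios, correction, and null behavior", {
  # a=9 b=1 c=1 d=9 -> OR 81: feature high for 9 of 10 positives
  v <- c(rep(1, 9), 0, 1, rep(0, 9))
  l <- c(rep(1, 10), rep(0, 10))
  a <- patch_association(v, l)
  expect_equal(a$odds_ratio, 81)
  expect_false(a$corrected)

  # perfect separation -> Haldane correction, OR 441
  v2 <- c(rep(1, 10), rep(0, 10))
  a2 <- patch_association(v2, l)
  expect_true(a2$corrected)
  expect_equal(a2$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_true(a2$significant)

  # label-independent feature: OR near 1 in expectation over permutations
  withr::with_seed(31, {
    ors <- vapply(1:150, function(i)
      patch_association(stats::runif(40),
                        sample(rep(0:1, each = 20)))$odds_ratio, 0)
    expect_lt(abs(mean(log(ors))), 0.35)
  })
  expect_error(patch_association(1:10, rep(1, 10)), "class")
})

test_that("screen_features flags lesion-leaning patches", {
  spec <- tiny_spec(n_benign = 40, n_malignant = 40)
  ds <- build_channel_dataset(spec, seed = 17)
  f <- patch_feature_matrix(ds$patches)
  sc <- screen_features(f, ds$labels)
  expect_equal(nrow(sc$associations), 22)
  expect_true(any(sc$associations$significant))
  # the marked set should enrich for true lesions
  expect_gt(mean(ds$labels[sc$significant_patches]),
            mean(ds$labels))
})
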
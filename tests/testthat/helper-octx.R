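# Shared fixtures and independent oracles. Everything is generated in
# code; no data files.

# A small high-contrast channel: quick to synthesize, cleanly separable.
tiny_spec <- function(n_benign = 60, n_malignant = 40, noise = 0,
                      lesion_amp = 70, image_size = 150L) {
  channel_spec("GU", n_benign = n_benign, n_malignant = n_malignant,
               image_size = image_size, patch_size = 50L,
               texture_params = list(lesion_amp = lesion_amp),
               label_noise_rate = noise)
}

# Brute-force GLCM oracle: enumerate every pixel pair at offset (dr, dc),
# count both directions, normalize. Independent of compute_glcm().
brute_glcm <- function(patch, dr, dc, levels) {
  q <- floor(patch * levels / 256)
  q[q > levels - 1] <- levels - 1
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        m[i, j] <- m[i, j] + 1
        m[j, i] <- m[j, i] + 1
      }
    }
  }
  m / sum(m)
}

# The 11 statistics from a normalized GLCM, written independently (sums
# over explicit loops).
brute_stats <- function(m) {
  L <- nrow(m)
  mu <- 0; for (i in 1:L) for (j in 1:L) mu <- mu + (i - 1) * m[i, j]
  v <- 0; for (i in 1:L) for (j in 1:L) v <- v + (i - 1 - mu)^2 * m[i, j]
  s <- c(contrast = 0, dissimilarity = 0, homogeneity = 0, energy = 0,
         asm = 0, correlation = 0, entropy = 0, glcm_mean = mu,
         glcm_variance = v, cluster_shade = 0, cluster_prominence = 0)
  for (i in 1:L) for (j in 1:L) {
    p <- m[i, j]; d <- (i - 1) - (j - 1)
    s["contrast"] <- s["contrast"] + p * d^2
    s["dissimilarity"] <- s["dissimilarity"] + p * abs(d)
    s["homogeneity"] <- s["homogeneity"] + p / (1 + d^2)
    s["asm"] <- s["asm"] + p^2
    if (p > 0) s["entropy"] <- s["entropy"] - p * log(p)
    if (v > 1e-12)
      s["correlation"] <- s["correlation"] +
        (i - 1 - mu) * (j - 1 - mu) * p / v
    s["cluster_shade"] <- s["cluster_shade"] + (i + j - 2 - 2 * mu)^3 * p
    s["cluster_prominence"] <- s["cluster_prominence"] +
      (i + j - 2 - 2 * mu)^4 * p
  }
  s["energy"] <- sqrt(s["asm"])
  s
}

# Brute-force AUC: average over all positive/negative pairs, ties 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# 4x4 two-level checkerboard (0 / 255).
checkerboard4 <- function() {
  matrix(255 * ((outer(1:4, 1:4, "+") %% 2)), 4, 4)
}

# Beta-mixture scored dataset for the threshold search.
beta_mixture_data <- function(n_per_class, seed,
                              n_train = NULL, n_val = NULL) {
  withr::with_seed(seed, {
    scores <- c(stats::rbeta(n_per_class, 2, 8),
                stats::rbeta(n_per_class, 8, 2))
    labels <- rep(0:1, each = n_per_class)
    idx <- sample(2 * n_per_class)
    if (is.null(n_train)) n_train <- floor(0.7 * 2 * n_per_class)
    if (is.null(n_val)) n_val <- floor(0.15 * 2 * n_per_class)
    tr <- idx[seq_len(n_train)]
    va <- idx[n_train + seq_len(n_val)]
    te <- idx[(n_train + n_val + 1):(2 * n_per_class)]
    list(data = fdtgs_data(matrix(scores, ncol = 1,
                                  dimnames = list(NULL, "s")),
                           scores, labels, tr, va),
         scores = scores, labels = labels, test_idx = te)
  })
}

# A light backbone configuration for search-heavy tests.
light_backbone <- function() mlp_backbone(hidden = c(8L, 4L), epochs = 25L,
                                          lr = 0.1)

# Random normalized posterior over the four classes.
rand_posterior <- function() {
  v <- stats::runif(4)
  v / sum(v)
}
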
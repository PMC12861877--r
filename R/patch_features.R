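#' Decompose an image into non-overlapping P x P patches
#'
#' The grid has `floor(H/P)` rows and `floor(W/P)` columns of patches;
#' partial border strips are dropped, never padded, so every patch carries
#' the same stationary texture statistics. Grid coordinates are 0-based
#' `(row, col)` with origin at the image's top-left.
#'
#' @param image numeric or integer matrix (one image, grayscale).
#' @param P patch side in pixels, `P >= 2`.
#' @return object of class `octx_patchgrid`: list with `patches` (row-major
#'   list of P x P matrices), `coords` (matrix of 0-based grid row/col),
#'   `grid_shape`, `patch_size`.
#' @export
decompose_into_patches <- function(image, P) {
  stopifnot(is.matrix(image))
  P <- as.integer(P)
  if (P < 2) stop("patch size must be >= 2")
  if (nrow(image) < P || ncol(image) < P)
    stop("image (", nrow(image), "x", ncol(image),
         ") is smaller than the patch size ", P)
  n_rows <- nrow(image) %/% P
  n_cols <- ncol(image) %/% P
  patches <- vector("list", n_rows * n_cols)
  coords <- matrix(0L, n_rows * n_cols, 2L,
                   dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      k <- k + 1L
      patches[[k]] <- image[r * P + seq_len(P), cc * P + seq_len(P),
                            drop = FALSE]
      coords[k, ] <- c(r, cc)
    }
  }
  structure(list(patches = patches, coords = coords,
                 grid_shape = c(n_rows = n_rows, n_cols = n_cols),
                 patch_size = P),
            class = "octx_patchgrid")
}

#' Reassemble a patch grid into an image
#'
#' Inverse of [decompose_into_patches()] for exactly tiled images.
#' @param grid an `octx_patchgrid`.
#' @return matrix of size `(n_rows * P) x (n_cols * P)`.
#' @export
reassemble_patches <- function(grid) {
  P <- grid$patch_size
  out <- matrix(0, grid$grid_shape[1] * P, grid$grid_shape[2] * P)
  for (k in seq_along(grid$patches)) {
    r <- grid$coords[k, 1]; cc <- grid$coords[k, 2]
    out[r * P + seq_len(P), cc * P + seq_len(P)] <- grid$patches[[k]]
  }
  out
}

# Quantize 8-bit intensities to `levels` uniform bins of [0, 255],
# returning 0-based bin indices.
quantize_gray <- function(patch, levels) {
  q <- floor(patch * levels / 256)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  q
}

#' Convert an RGB array to 8-bit luminance
#'
#' ITU-R BT.601 weights (0.299, 0.587, 0.114).
#' @param rgb numeric array `H x W x 3` with values in `[0, 255]`.
#' @return integer luminance matrix.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  y <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(pmin(pmax(round(y), 0), 255)), dim(rgb)[1], dim(rgb)[2])
}

# Offset (dr, dc) for a GLCM angle in degrees at distance d.
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle))
}

#' Normalized gray-level co-occurrence matrices of a patch
#'
#' For every (distance, angle) combination, counts co-occurring quantized
#' intensity pairs at that pixel offset, symmetrizes (each pair counted in
#' both directions) and normalizes to sum 1.
#'
#' @param patch intensity matrix with values in `[0, 255]`.
#' @param distances integer pixel offsets (default `c(1, 2)`).
#' @param angles directions in degrees, subset of `{0, 45, 90, 135}`.
#' @param levels number of gray levels after uniform quantization of
#'   `[0, 255]` (default 32; a 50 x 50 patch under-populates 256 levels).
#' @return named list of `levels x levels` matrices (`"d<d>_a<angle>"`),
#'   each symmetric with entries summing to 1; attribute `glcm_meta` holds
#'   `(levels, distances, angles)`.
#' @export
compute_glcm <- function(patch, distances = c(1L, 2L),
                         angles = c(0, 45, 90, 135), levels = 32L) {
  stopifnot(is.matrix(patch), length(distances) >= 1, length(angles) >= 1)
  q <- quantize_gray(patch, levels)
  h <- nrow(q); w <- ncol(q)
  out <- list()
  for (d in distances) {
    for (a in angles) {
      off <- glcm_offset(a, as.integer(d))
      dr <- off[1]; dc <- off[2]
      r1 <- seq_len(h); c1 <- seq_len(w)
      rows <- r1[r1 + dr >= 1 & r1 + dr <= h]
      cols <- c1[c1 + dc >= 1 & c1 + dc <= w]
      if (!length(rows) || !length(cols))
        stop("no valid pixel pairs for distance ", d, ", angle ", a)
      i <- q[rows, cols, drop = FALSE]
      j <- q[rows + dr, cols + dc, drop = FALSE]
      counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
      m <- matrix(counts, levels, levels, byrow = TRUE)
      m <- m + t(m)
      out[[sprintf("d%d_a%d", d, a)]] <- m / sum(m)
    }
  }
  attr(out, "glcm_meta") <- list(levels = levels, distances = distances,
                                 angles = angles)
  out
}

# The 11 co-occurrence statistics of one normalized symmetric GLCM.
glcm_stats <- function(m) {
  L <- nrow(m)
  I <- matrix(0:(L - 1), L, L)
  J <- t(I)
  D <- I - J
  mu <- sum(I * m)
  v <- sum((I - mu)^2 * m)
  pos <- m > 0
  c(contrast = sum(m * D^2),
    dissimilarity = sum(m * abs(D)),
    homogeneity = sum(m / (1 + D^2)),
    energy = sqrt(sum(m^2)),
    asm = sum(m^2),
    correlation = if (v < 1e-12) 0 else sum((I - mu) * (J - mu) * m) / v,
    entropy = -sum(m[pos] * log(m[pos])),
    glcm_mean = mu,
    glcm_variance = v,
    cluster_shade = sum((I + J - 2 * mu)^3 * m),
    cluster_prominence = sum((I + J - 2 * mu)^4 * m))
}

#' The 22-dimensional GLCM texture feature vector
#'
#' Eleven co-occurrence statistics (contrast, dissimilarity, homogeneity,
#' energy, angular second moment, correlation, entropy, GLCM mean, GLCM
#' variance, cluster shade, cluster prominence), each averaged over the
#' four angles, at two distances (1 px and 2 px) — 22 values. Names are
#' `<stat>_d<distance>` and the order is all 11 statistics at distance 1
#' followed by the same 11 at distance 2.
#'
#' A zero-variance (constant) patch has undefined correlation; it is set
#' to 0 by convention and the result carries `attr(, "zero_variance")`.
#'
#' @param glcms output of [compute_glcm()] (needs both distances and the
#'   full angle set of the default configuration).
#' @return named numeric vector of length
#'   `11 * length(distances)` (22 for the defaults).
#' @export
glcm_feature_vector <- function(glcms) {
  meta <- attr(glcms, "glcm_meta")
  if (is.null(meta)) stop("glcms must come from compute_glcm()")
  zero_var <- FALSE
  out <- numeric(0)
  for (d in meta$distances) {
    acc <- 0
    for (a in meta$angles) {
      m <- glcms[[sprintf("d%d_a%d", d, a)]]
      if (abs(sum(m) - 1) > 1e-12) stop("GLCM not normalized")
      st <- glcm_stats(m)
      if (st[["glcm_variance"]] < 1e-12) zero_var <- TRUE
      acc <- acc + st
    }
    acc <- acc / length(meta$angles)
    names(acc) <- paste0(names(acc), "_d", d)
    out <- c(out, acc)
  }
  attr(out, "zero_variance") <- zero_var
  out
}

#' Feature matrix for a list of patches
#'
#' @param patches list of intensity matrices (or an `octx_patchgrid` /
#'   `octx_dataset`).
#' @param ... passed to [compute_glcm()].
#' @return numeric matrix, one row per patch, 22 named columns.
#' @export
patch_feature_matrix <- function(patches, ...) {
  if (inherits(patches, "octx_patchgrid") || inherits(patches, "octx_dataset"))
    patches <- patches$patches
  rows <- lapply(patches, function(p) glcm_feature_vector(compute_glcm(p, ...)))
  do.call(rbind, rows)
}

#' Label a patch from a binary lesion mask
#'
#' @param row,col 0-based grid coordinates of the patch.
#' @param P patch side, pixels.
#' @param mask binary mask matrix aligned with the source image (values 0/1
#'   or 0/255).
#' @param tau coverage fraction in `(0, 1]`; the patch is malignant iff
#'   `lesion pixels / P^2 >= tau` (inclusive).
#' @return integer label, 1 = malignant, 0 = benign.
#' @export
label_patch_from_mask <- function(row, col, P, mask, tau = 0.5) {
  stopifnot(tau > 0, tau <= 1)
  sub <- mask[row * P + seq_len(P), col * P + seq_len(P), drop = FALSE]
  as.integer(mean(sub > 0) >= tau)
}

#' Per-image map of one feature, min-max normalized
#'
#' Arranges the named feature over the patch grid and rescales to `[0, 1]`;
#' a constant input maps to all zeros by convention.
#'
#' @param grid an `octx_patchgrid`.
#' @param features matrix from [patch_feature_matrix()] aligned with
#'   `grid$patches`.
#' @param name one of the feature column names.
#' @return `n_rows x n_cols` numeric matrix in `[0, 1]`.
#' @export
fuse_feature_map <- function(grid, features, name) {
  stopifnot(inherits(grid, "octx_patchgrid"))
  if (!name %in% colnames(features))
    stop("unknown feature name: ", name)
  v <- features[, name]
  if (length(v) != length(grid$patches))
    stop("one feature row per patch required")
  rng <- range(v)
  v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  out <- matrix(0, grid$grid_shape[1], grid$grid_shape[2])
  out[grid$coords + 1L] <- v
  out
}

#' Univariate odds-ratio screen for one feature
#'
#' Dichotomizes the feature at its median (high = strictly above), forms
#' the 2 x 2 table against the binary labels and reports the cross-product
#' odds ratio (with Haldane +0.5 correction applied to all cells when any
#' cell is zero), the two-sided Fisher exact p-value, and a significance
#' flag: `p < alpha` and the odds ratio outside `[1/(1 + margin),
#' 1 + margin]`.
#'
#' @param values numeric feature values.
#' @param labels binary labels (1 = malignant), at least 2 per class.
#' @param alpha screen level (default 0.05).
#' @param margin minimal odds-ratio effect margin (default 0.05).
#' @return object of class `octx_association`: list with `feature`,
#'   `table`, `odds_ratio`, `p_value`, `significant`, `corrected`.
#' @export
patch_association <- function(values, labels, alpha = 0.05, margin = 0.05,
                              feature = "feature") {
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 patches per class")
  med <- stats::median(values)
  high <- values > med
  a <- sum(high & labels == 1); b <- sum(high & labels == 0)
  cc <- sum(!high & labels == 1); d <- sum(!high & labels == 0)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("high", "low"),
                                c("malignant", "benign")))
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- stats::fisher.test(tab)$p.value
  structure(list(feature = feature, table = tab, odds_ratio = or,
                 p_value = p,
                 significant = p < alpha &&
                   (or > 1 + margin || or < 1 / (1 + margin)),
                 corrected = corrected),
            class = "octx_association")
}

#' @export
print.octx_association <- function(x, ...) {
  cat(sprintf("<octx_association> %s: OR = %.3f, p = %.3g%s%s\n",
              x$feature, x$odds_ratio, x$p_value,
              if (x$significant) " [significant]" else "",
              if (x$corrected) " (Haldane-corrected)" else ""))
  invisible(x)
}

#' Odds-ratio screen over all features; marks significant patches
#'
#' Runs [patch_association()] per feature column and flags each patch as
#' significant when it is on the lesion-leaning side of the median for at
#' least half of the significant features.
#'
#' @param features feature matrix (patches x features).
#' @param labels binary labels.
#' @param alpha,margin passed to [patch_association()].
#' @return list with `associations` (data.frame: feature, odds_ratio,
#'   p_value, significant) and `significant_patches` (logical per patch).
#' @export
screen_features <- function(features, labels, alpha = 0.05, margin = 0.05) {
  assoc <- lapply(colnames(features), function(nm)
    patch_association(features[, nm], labels, alpha, margin, feature = nm))
  df <- data.frame(
    feature = vapply(assoc, `[[`, "", "feature"),
    odds_ratio = vapply(assoc, `[[`, 0, "odds_ratio"),
    p_value = vapply(assoc, `[[`, 0, "p_value"),
    significant = vapply(assoc, `[[`, TRUE, "significant"),
    stringsAsFactors = FALSE)
  sig <- which(df$significant)
  votes <- matrix(0, nrow(features), length(sig))
  for (k in seq_along(sig)) {
    nm <- df$feature[sig[k]]
    med <- stats::median(features[, nm])
    lean_high <- df$odds_ratio[sig[k]] > 1
    votes[, k] <- if (lean_high) features[, nm] > med else features[, nm] <= med
  }
  sig_patch <- if (length(sig)) rowMeans(votes) >= 0.5 else
    rep(FALSE, nrow(features))
  list(associations = df, significant_patches = sig_patch)
}
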
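#' Specification of a synthetic lesion channel
#'
#' A channel describes one lesion type (gastric ulcer `GU`, red spots `GRS`,
#' polyps `GPs`, bleeding `GB`) as a generative recipe: how many benign and
#' malignant patches to emit, the image and patch geometry, the elliptical
#' lesion geometry, the texture controls and the label-noise rate. The
#' default class quotas reproduce the per-channel benign/malignant imbalance
#' of the reference dataset (GU 1857/1351, GRS 1012/4731, GPs 5406/4224,
#' GB 167/1182), scaled down by `scale` so tests and examples stay fast.
#'
#' Textures are smoothed Gaussian random fields (white noise convolved with
#' a Gaussian kernel of correlation length `corr_len`) plus a class-specific
#' sinusoidal contrast of amplitude `lesion_amp` inside lesions (`bg_amp`
#' outside). The sinusoid amplitude is the separability dial: at
#' `lesion_amp = 0` (and equal remaining parameters) the two classes are
#' statistically identical; at high amplitude their co-occurrence contrast
#' differs strongly.
#'
#' @param name channel name, one of `"GU"`, `"GRS"`, `"GPs"`, `"GB"`.
#' @param n_benign,n_malignant patch quotas; defaults follow the channel's
#'   reference imbalance scaled by `scale`.
#' @param scale down-scaling factor applied to the reference quotas when
#'   `n_benign`/`n_malignant` are not given.
#' @param image_size side of the square source images, pixels.
#' @param patch_size patch side `P`, pixels (default 50).
#' @param lesion_geometry list with `n_range` (min/max ellipse count per
#'   image), `ax_range` (semi-axis range, pixels; at most `2 * image_size`),
#'   `center_frac` (center position range as a fraction of the image side).
#' @param texture_params list with `base` (mean gray level), `noise_sd`
#'   (field standard deviation, gray levels), `corr_len` (Gaussian kernel
#'   sd, pixels), `wavelength` (sinusoid period, pixels), `bg_amp` and
#'   `lesion_amp` (sinusoid amplitudes, gray levels).
#' @param label_noise_rate fraction of labels to flip, in `[0, 0.5)`.
#' @return an object of class `octx_channel_spec`.
#' @export
channel_spec <- function(name = c("GU", "GRS", "GPs", "GB"),
                         n_benign = NULL, n_malignant = NULL,
                         scale = 1,
                         image_size = 250L, patch_size = 50L,
                         lesion_geometry = list(),
                         texture_params = list(),
                         label_noise_rate = 0) {
  name <- match.arg(name)
  ref <- list(GU = c(1857L, 1351L), GRS = c(1012L, 4731L),
              GPs = c(5406L, 4224L), GB = c(167L, 1182L))[[name]]
  if (is.null(n_benign)) n_benign <- max(1L, round(ref[1] * scale))
  if (is.null(n_malignant)) n_malignant <- max(1L, round(ref[2] * scale))
  # lesions span several patch widths (as 50 px patches tiling endoscopy
  # frames do) so coverage-ambiguous boundary patches stay rare; some
  # frames carry no lesion at all
  geom <- utils::modifyList(list(
    n_range = c(0L, 2L),
    ax_range = c(0.28, 0.55) * image_size,
    center_frac = c(0.25, 0.75)
  ), lesion_geometry)
  tex <- utils::modifyList(list(
    base = 120, noise_sd = 25, corr_len = 2.5,
    wavelength = 6, bg_amp = 0, lesion_amp = 70
  ), texture_params)

  if (n_benign < 0 || n_malignant < 0 || n_benign + n_malignant == 0)
    stop("need n_benign >= 0, n_malignant >= 0 and a positive total")
  if (patch_size < 2 || image_size < patch_size)
    stop("patch_size must be >= 2 and <= image_size")
  if (label_noise_rate < 0 || label_noise_rate >= 0.5)
    stop("label_noise_rate must be in [0, 0.5)")
  if (any(geom$ax_range <= 0) || max(geom$ax_range) > 2 * image_size)
    stop("ellipse semi-axis range cannot fit inside the image")
  if (geom$n_range[1] < 0 || geom$n_range[2] < geom$n_range[1])
    stop("invalid lesion count range")

  structure(list(name = name, n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 lesion_geometry = geom, texture_params = tex,
                 label_noise_rate = label_noise_rate),
            class = "octx_channel_spec")
}

#' @export
print.octx_channel_spec <- function(x, ...) {
  cat(sprintf(
    "<octx_channel_spec> %s: %d benign / %d malignant (%.1f%% benign), %dpx images, P=%d, noise=%.2f\n",
    x$name, x$n_benign, x$n_malignant,
    100 * x$n_benign / (x$n_benign + x$n_malignant),
    x$image_size, x$patch_size, x$label_noise_rate))
  invisible(x)
}

# Smooth a matrix with a separable Gaussian kernel (circular boundary, so
# the field stays stationary).
gauss_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  m <- apply(m, 2L, function(v) as.numeric(stats::filter(v, k, circular = TRUE)))
  t(apply(m, 1L, function(v) as.numeric(stats::filter(v, k, circular = TRUE))))
}

# One stationary texture layer: unit-variance smoothed field plus a
# sinusoidal contrast of the given amplitude with random phase/orientation.
texture_layer <- function(size, tex, amp) {
  field <- gauss_smooth(matrix(stats::rnorm(size * size), size, size),
                        tex$corr_len)
  s <- stats::sd(field)
  if (s > 0) field <- field / s
  omega <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  xy <- seq_len(size) - 0.5
  wave <- sin(outer(xy * sin(omega), xy * cos(omega), "+") *
                (2 * pi / tex$wavelength) + phase)
  tex$base + tex$noise_sd * field + amp * wave
}

#' Generate one synthetic endoscopy-style image with elliptical lesions
#'
#' Draws a background texture, samples 0 or more elliptical lesion regions
#' (count, semi-axes, center and rotation from `spec$lesion_geometry`) and
#' fills them with the lesion texture class. Ellipses are rasterized with
#' center-of-pixel inclusion testing. The output is an 8-bit image plus a
#' binary mask that is 1 exactly inside the union of the ellipses.
#'
#' @param spec an [channel_spec()] object.
#' @param seed integer seed; two calls with equal `(spec, seed)` are
#'   bit-identical.
#' @return list with `image` (integer matrix in `[0, 255]`) and `mask`
#'   (0/1 integer matrix of the same shape).
#' @export
generate_texture_image <- function(spec, seed) {
  stopifnot(inherits(spec, "octx_channel_spec"))
  size <- spec$image_size
  geom <- spec$lesion_geometry
  tex <- spec$texture_params
  with_seed(seed, {
    bg <- texture_layer(size, tex, tex$bg_amp)
    lesion <- texture_layer(size, tex, tex$lesion_amp)
    mask <- matrix(0L, size, size)
    n_lesions <- if (geom$n_range[1] == geom$n_range[2]) geom$n_range[1] else
      sample(seq(geom$n_range[1], geom$n_range[2]), 1L)
    if (n_lesions > 0) {
      # center-of-pixel coordinates: pixel (r, c) sits at (r - 0.5, c - 0.5)
      rc <- seq_len(size) - 0.5
      R <- matrix(rc, size, size)
      C <- matrix(rc, size, size, byrow = TRUE)
      for (i in seq_len(n_lesions)) {
        a <- stats::runif(1, geom$ax_range[1], geom$ax_range[2])
        b <- stats::runif(1, geom$ax_range[1], geom$ax_range[2])
        th <- stats::runif(1, 0, pi)
        cr <- stats::runif(1, geom$center_frac[1], geom$center_frac[2]) * size
        cc <- stats::runif(1, geom$center_frac[1], geom$center_frac[2]) * size
        dr <- R - cr; dc <- C - cc
        u <- (dc * cos(th) + dr * sin(th)) / a
        v <- (-dc * sin(th) + dr * cos(th)) / b
        mask[u * u + v * v <= 1] <- 1L
      }
    }
    img <- bg
    img[mask == 1L] <- lesion[mask == 1L]
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), size, size)
    list(image = img, mask = mask)
  })
}

#' Deterministic 7:2:1-style split counts
#'
#' Splits `n` items into train/test/val counts using the fixed rule
#' `n_test = floor(r_test * n)`, `n_val = floor(r_val * n)`,
#' `n_train = n - n_test - n_val`. With the default 7:2:1 ratios this
#' reproduces the reference per-class split rows (e.g. 1857 benign
#' patches -> 1301/371/185).
#'
#' @param n number of items, `n >= 1`.
#' @param ratios numeric length-3 `(train, test, val)`, summing to 1.
#' @return named integer vector `c(train, test, val)` summing to `n`.
#' @export
#' @examples
#' split_dataset(1857) # 1301 371 185
split_dataset <- function(n, ratios = c(0.7, 0.2, 0.1)) {
  stopifnot(n >= 1, length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9,
            all(ratios >= 0))
  n <- as.integer(n)
  n_test <- as.integer(floor(ratios[2] * n))
  n_val <- as.integer(floor(ratios[3] * n))
  c(train = n - n_test - n_val, test = n_test, val = n_val)
}

#' Build a labeled, imbalanced patch dataset for one channel
#'
#' Generates images with [generate_texture_image()] until the benign and
#' malignant patch quotas of `spec` are both met, labels each patch from
#' the lesion mask (malignant iff lesion coverage >= `tau`), assigns
#' train/test/val tags per class with [split_dataset()], and injects label
#' noise at `spec$label_noise_rate` via [inject_label_noise()].
#'
#' @param spec an [channel_spec()] object.
#' @param seed integer seed for the whole construction.
#' @param tau lesion-coverage fraction at which a patch is malignant.
#' @param ratios split ratios passed to [split_dataset()].
#' @param max_images iteration cap on generated images; exceeding it raises
#'   an error naming the class whose quota could not be met.
#' @param keep_images retain the source images and masks on the object.
#' @return an object of class `octx_dataset` with fields `patches` (list of
#'   P x P integer matrices), `labels` (true 0 = benign / 1 = malignant),
#'   `noisy_labels`, `split`, `row`, `col`, `source_image`, `noise_index`,
#'   `channel`, `seed`.
#' @export
build_channel_dataset <- function(spec, seed, tau = 0.5,
                                  ratios = c(0.7, 0.2, 0.1),
                                  max_images = NULL, keep_images = FALSE) {
  stopifnot(inherits(spec, "octx_channel_spec"))
  P <- spec$patch_size
  per_image <- floor(spec$image_size / P)^2
  if (is.null(max_images)) {
    max_images <- 50L + ceiling(10 * (spec$n_benign + spec$n_malignant) /
                                  per_image)
  }
  patches <- list(); labels <- integer(0)
  rows <- integer(0); cols <- integer(0); srcs <- integer(0)
  images <- list(); masks <- list()
  k <- 0L
  while ((sum(labels == 0L) < spec$n_benign ||
          sum(labels == 1L) < spec$n_malignant) && k < max_images) {
    k <- k + 1L
    gi <- generate_texture_image(spec, sub_seed(seed, paste0("img/", k)))
    if (keep_images) { images[[k]] <- gi$image; masks[[k]] <- gi$mask }
    grid <- decompose_into_patches(gi$image, P)
    for (p in seq_along(grid$patches)) {
      pr <- grid$coords[p, 1]; pc <- grid$coords[p, 2]
      lab <- label_patch_from_mask(pr, pc, P, gi$mask, tau)
      patches[[length(patches) + 1L]] <- grid$patches[[p]]
      labels <- c(labels, lab); rows <- c(rows, pr); cols <- c(cols, pc)
      srcs <- c(srcs, k)
    }
  }
  if (sum(labels == 0L) < spec$n_benign)
    stop("benign patch quota unreachable within ", max_images, " images")
  if (sum(labels == 1L) < spec$n_malignant)
    stop("malignant patch quota unreachable within ", max_images, " images")

  keep <- c(which(labels == 0L)[seq_len(spec$n_benign)],
            which(labels == 1L)[seq_len(spec$n_malignant)])
  keep <- sort(keep)
  patches <- patches[keep]; labels <- labels[keep]
  rows <- rows[keep]; cols <- cols[keep]; srcs <- srcs[keep]
  n <- length(labels)

  split <- character(n)
  for (cls in c(0L, 1L)) {
    ids <- which(labels == cls)
    cnt <- split_dataset(length(ids), ratios)
    ids <- with_seed(sub_seed(seed, paste0("split/", cls)), sample(ids))
    split[ids] <- rep(c("train", "test", "val"), times = cnt)
  }

  ds <- structure(list(
    patches = patches, labels = labels, noisy_labels = labels,
    split = factor(split, levels = c("train", "test", "val")),
    row = rows, col = cols, source_image = srcs,
    noise_index = integer(0), channel = spec$name, seed = seed,
    patch_size = P,
    images = if (keep_images) images else NULL,
    masks = if (keep_images) masks else NULL
  ), class = "octx_dataset")
  if (spec$label_noise_rate > 0) {
    ds <- inject_label_noise(ds, spec$label_noise_rate,
                             sub_seed(seed, "noise"))
  }
  ds
}

#' @export
print.octx_dataset <- function(x, ...) {
  cat(sprintf(
    "<octx_dataset> %s: %d patches (%d benign / %d malignant), %d noisy labels\n",
    x$channel, length(x$labels), sum(x$labels == 0L), sum(x$labels == 1L),
    length(x$noise_index)))
  print(table(x$split))
  invisible(x)
}

#' Flip a fixed fraction of labels to emulate annotation noise
#'
#' Flips exactly `round(rate * n)` labels chosen uniformly at random and
#' records their ids in `noise_index`. The input dataset is not modified;
#' true labels remain in `labels`, corrupted ones in `noisy_labels`.
#'
#' @param dataset an `octx_dataset`.
#' @param rate fraction in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a new `octx_dataset` with `noisy_labels` and `noise_index` set.
#' @export
inject_label_noise <- function(dataset, rate, seed) {
  stopifnot(inherits(dataset, "octx_dataset"))
  if (rate < 0 || rate >= 0.5)
    stop("noise rate must be in [0, 0.5): noise would dominate signal")
  n <- length(dataset$labels)
  k <- round(rate * n)
  out <- dataset
  out$noisy_labels <- dataset$labels
  out$noise_index <- integer(0)
  if (k > 0) {
    idx <- with_seed(seed, sort(sample.int(n, k)))
    out$noisy_labels[idx] <- 1L - out$noisy_labels[idx]
    out$noise_index <- idx
  }
  out
}

#' Dataset manifest as a data frame
#'
#' @param dataset an `octx_dataset`.
#' @return data.frame with one row per patch: `patch_id`, `channel`,
#'   `split`, `label`, `noisy_label`, `source_image`, `row`, `col`.
#' @export
dataset_manifest <- function(dataset) {
  stopifnot(inherits(dataset, "octx_dataset"))
  data.frame(patch_id = seq_along(dataset$labels),
             channel = dataset$channel,
             split = as.character(dataset$split),
             label = dataset$labels,
             noisy_label = dataset$noisy_labels,
             source_image = dataset$source_image,
             row = dataset$row, col = dataset$col,
             stringsAsFactors = FALSE)
}

#' Write a channel dataset to disk
#'
#' Writes the manifest as CSV and, when the dataset kept its source images,
#' each image and 0/255 mask as PGM under `dir`.
#'
#' @param dataset an `octx_dataset` (ideally built with
#'   `keep_images = TRUE`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_channel_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset_manifest(dataset),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(dataset$images)) {
    for (k in seq_along(dataset$images)) {
      write_pgm(dataset$images[[k]],
                file.path(dir, sprintf("%s_img%03d.pgm", dataset$channel, k)))
      write_pgm(dataset$masks[[k]] * 255L,
                file.path(dir, sprintf("%s_msk%03d.pgm", dataset$channel, k)))
    }
  }
  invisible(dir)
}
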
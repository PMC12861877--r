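#' A small multilayer-perceptron backbone with a four-way softmax head
#'
#' Desk-scale stand-in for a deep segmentation backbone, exposed behind the
#' classifier contract used by the threshold search and the cross-learning
#' loop: `fit_backbone()` and `predict_posteriors()`. The input is a patch
#' feature vector plus a branch indicator (+1 plus branch, -1 minus
#' branch); the output is a posterior over `{P+, P-, N+, N-}`. Training is
#' full-batch Adam on the softmax cross-entropy; everything is
#' deterministic given the seed, and refitting warm-starts from the current
#' weights when the input dimension is unchanged.
#'
#' @param hidden integer sizes of the two hidden layers.
#' @param epochs gradient steps per `fit_backbone()` call.
#' @param lr Adam learning rate.
#' @param seed integer seed for weight initialization.
#' @return an object of class `octx_mlp` (unfitted).
#' @export
mlp_backbone <- function(hidden = c(16L, 8L), epochs = 80L, lr = 0.05,
                         seed = 1L) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), epochs >= 1, lr > 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), fitted = FALSE,
                 weights = NULL, adam = NULL, center = NULL, scale = NULL),
            class = "octx_mlp")
}

mlp_init_weights <- function(d_in, hidden, seed) {
  with_seed(seed, {
    sizes <- c(d_in, hidden, 4L)
    w <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[l]
      w[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * sizes[l + 1],
                                                 sd = sqrt(1 / fan_in)),
                                    fan_in, sizes[l + 1])
      w[[paste0("b", l)]] <- rep(0, sizes[l + 1])
    }
    w
  })
}

mlp_forward <- function(w, X) {
  A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- tanh(sweep(A1 %*% w$W2, 2, w$b2, "+"))
  Z <- sweep(A2 %*% w$W3, 2, w$b3, "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(A1 = A1, A2 = A2, P = P)
}

#' Fit the MLP backbone on four-class twin examples
#'
#' @param backbone an `octx_mlp`.
#' @param X numeric matrix, rows = examples (feature vector with branch
#'   indicator appended; see [twin_design()]).
#' @param y four-class labels (`"P+"`, `"P-"`, `"N+"`, `"N-"`).
#' @param warm_start continue from the current weights when already fitted
#'   with the same input dimension (default `FALSE`: re-initialize).
#' @return the fitted backbone.
#' @export
fit_backbone <- function(backbone, X, y, warm_start = FALSE) {
  stopifnot(inherits(backbone, "octx_mlp"), is.matrix(X),
            nrow(X) == length(y))
  y <- match(y, four_classes)
  if (anyNA(y)) stop("labels must be in {P+, P-, N+, N-}")
  if (!warm_start || !backbone$fitted ||
      nrow(backbone$weights$W1) != ncol(X)) {
    backbone$weights <- mlp_init_weights(ncol(X), backbone$hidden,
                                         backbone$seed)
    backbone$adam <- list(m = rapply(backbone$weights, function(z) z * 0,
                                     how = "replace"),
                          v = rapply(backbone$weights, function(z) z * 0,
                                     how = "replace"),
                          t = 0)
    cen <- colMeans(X)
    sc <- apply(X, 2, stats::sd)
    sc[sc < 1e-8] <- 1
    backbone$center <- cen
    backbone$scale <- sc
  }
  Xs <- sweep(sweep(X, 2, backbone$center), 2, backbone$scale, "/")
  n <- nrow(Xs)
  Y <- matrix(0, n, 4L)
  Y[cbind(seq_len(n), y)] <- 1
  # inverse-frequency class weights so the 1:10 opposite-set ratio does
  # not swamp the primary class
  cls_n <- tabulate(y, 4L)
  cw <- ifelse(cls_n > 0, n / (sum(cls_n > 0) * pmax(cls_n, 1)), 0)
  wv <- cw[y]
  wv <- wv / sum(wv)
  w <- backbone$weights
  ad <- backbone$adam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (it in seq_len(backbone$epochs)) {
    f <- mlp_forward(w, Xs)
    dZ <- (f$P - Y) * wv
    g <- list()
    g$W3 <- t(f$A2) %*% dZ
    g$b3 <- colSums(dZ)
    dA2 <- dZ %*% t(w$W3) * (1 - f$A2^2)
    g$W2 <- t(f$A1) %*% dA2
    g$b2 <- colSums(dA2)
    dA1 <- dA2 %*% t(w$W2) * (1 - f$A1^2)
    g$W1 <- t(Xs) %*% dA1
    g$b1 <- colSums(dA1)
    ad$t <- ad$t + 1
    for (nm in names(w)) {
      ad$m[[nm]] <- b1 * ad$m[[nm]] + (1 - b1) * g[[nm]]
      ad$v[[nm]] <- b2 * ad$v[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- ad$m[[nm]] / (1 - b1^ad$t)
      vhat <- ad$v[[nm]] / (1 - b2^ad$t)
      w[[nm]] <- w[[nm]] - backbone$lr * mhat / (sqrt(vhat) + eps)
    }
  }
  backbone$weights <- w
  backbone$adam <- ad
  backbone$fitted <- TRUE
  backbone
}

#' Posterior over the four classes for each example row
#'
#' @param backbone a fitted `octx_mlp`.
#' @param X numeric matrix of examples (same columns as at fit time).
#' @return `n x 4` matrix with columns `P+, P-, N+, N-`, rows summing to 1.
#' @export
predict_posteriors <- function(backbone, X) {
  if (!inherits(backbone, "octx_mlp") || !backbone$fitted)
    stop("backbone is not fitted")
  Xs <- sweep(sweep(X, 2, backbone$center), 2, backbone$scale, "/")
  P <- mlp_forward(backbone$weights, Xs)$P
  colnames(P) <- four_classes
  P
}

#' Twin four-class design matrix from binary-labeled features
#'
#' Expands each feature row into its plus and minus branch rows
#' (branch indicator +1 / -1 appended as the last column; angle-averaged
#' GLCM features are mirror-invariant, so the indicator is what makes the
#' two branches distinguishable at the feature level) with the four-class
#' labels from [map_to_four_class()].
#'
#' @param features numeric matrix, one row per patch.
#' @param labels binary labels, 1 = positive/malignant.
#' @return list with `X` (`2n x (d+1)`), `y` (length `2n`).
#' @export
twin_design <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  lab <- ifelse(as.integer(labels) == 1L, "P", "N")
  X <- rbind(cbind(features, branch = 1),
             cbind(features, branch = -1))
  y <- c(paste0(lab, "+"), paste0(lab, "-"))
  list(X = X, y = y)
}

#' Fused twin prediction for binary-labeled features
#'
#' Runs both branches through the backbone and fuses the posteriors with
#' [fuse_twin_posteriors()].
#'
#' @param backbone a fitted `octx_mlp`.
#' @param features numeric matrix, one row per patch.
#' @return data.frame from [fuse_twin_matrix()] plus `pred` (0/1).
#' @export
predict_twin <- function(backbone, features) {
  theta <- predict_posteriors(backbone, cbind(features, branch = 1))
  psi <- predict_posteriors(backbone, cbind(features, branch = -1))
  out <- fuse_twin_matrix(theta, psi)
  out$pred <- as.integer(out$label == "P")
  out
}

#' Seed scorer: logistic patch score in `[0, 1]`
#'
#' Fits a binomial GLM of the (possibly noisy) seed labels on the patch
#' features; `score_patches()` then maps any feature matrix to lesion
#' scores. Higher = more lesion-like.
#'
#' @param features numeric matrix of the labeled seed subset.
#' @param labels binary labels for the seed subset.
#' @return an object of class `octx_scorer`.
#' @export
make_seed_scorer <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  df$.y <- as.integer(labels)
  model <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  structure(list(model = model, d = ncol(features), fitted = TRUE),
            class = "octx_scorer")
}

#' @rdname make_seed_scorer
#' @param scorer an `octx_scorer` (or any object with a `$fitted` flag and
#'   conforming predict method).
#' @export
score_patches <- function(scorer, features) {
  if (!inherits(scorer, "octx_scorer") || !isTRUE(scorer$fitted))
    stop("scorer is not fitted")
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  s <- suppressWarnings(
    as.numeric(stats::predict(scorer$model, newdata = df,
                              type = "response")))
  pmin(pmax(s, 0), 1)
}
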
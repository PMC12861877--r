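#' A (low, high) threshold pair
#'
#' @param t_low,t_high values in `[0, 1]` with `t_low < t_high`.
#' @return object of class `octx_threshold_pair`.
#' @export
threshold_pair <- function(t_low, t_high) {
  if (!(t_low >= 0 && t_high <= 1 && t_low < t_high))
    stop("need 0 <= t_low < t_high <= 1")
  structure(list(t_low = t_low, t_high = t_high),
            class = "octx_threshold_pair")
}

#' Partition scored patches by a double threshold
#'
#' Negative samples are the patches scoring at or below `t_low`, reliable
#' positives those at or above `t_high`, and the rest is uncertain. The
#' boundary inclusion (`<=` low, `>=` high) is fixed here.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param pair a [threshold_pair()].
#' @return object of class `octx_partition`: list of index vectors `RP`,
#'   `NS`, `U` (pairwise disjoint, jointly exhaustive).
#' @export
partition_by_thresholds <- function(scores, pair) {
  stopifnot(inherits(pair, "octx_threshold_pair"))
  ns <- which(scores <= pair$t_low)
  rp <- which(scores >= pair$t_high)
  u <- setdiff(seq_along(scores), c(ns, rp))
  structure(list(RP = rp, NS = ns, U = u), class = "octx_partition")
}

#' @export
print.octx_partition <- function(x, ...) {
  cat(sprintf("<octx_partition> RP: %d, NS: %d, uncertain: %d\n",
              length(x$RP), length(x$NS), length(x$U)))
  invisible(x)
}

#' Bundle scored data for the threshold search
#'
#' @param features numeric matrix (n x d) of patch features.
#' @param scores numeric scores in `[0, 1]`, one per patch.
#' @param labels noisy supervision labels (0/1) used to evaluate candidate
#'   partitions on the validation split.
#' @param train_idx,val_idx disjoint index vectors into the rows.
#' @return object of class `octx_fdtgs_data`.
#' @export
fdtgs_data <- function(features, scores, labels, train_idx, val_idx) {
  stopifnot(nrow(features) == length(scores),
            length(labels) == length(scores),
            length(intersect(train_idx, val_idx)) == 0)
  structure(list(features = features, scores = scores,
                 labels = as.integer(labels),
                 train_idx = train_idx, val_idx = val_idx),
            class = "octx_fdtgs_data")
}

#' Evaluate one threshold pair by training the backbone on its partition
#'
#' Applies the pair to the training-pool scores, trains the backbone with
#' the reliable positives as positives and the negative samples as
#' negatives (twin four-class design), and returns the fused-prediction F1
#' on the validation split. Deterministic given `seed`.
#'
#' @param pair a [threshold_pair()].
#' @param data an [fdtgs_data()] bundle.
#' @param backbone an `octx_mlp` configuration (refitted from scratch).
#' @param seed integer seed for the backbone initialization.
#' @return validation F1 (numeric scalar).
#' @export
evaluate_threshold_pair <- function(pair, data, backbone, seed = 1L) {
  stopifnot(inherits(data, "octx_fdtgs_data"))
  part <- partition_by_thresholds(data$scores[data$train_idx], pair)
  if (!length(part$RP) || !length(part$NS))
    stop("degenerate partition: empty ",
         if (!length(part$RP)) "RP" else "NS")
  rp <- data$train_idx[part$RP]
  ns <- data$train_idx[part$NS]
  idx <- c(rp, ns)
  des <- twin_design(data$features[idx, , drop = FALSE],
                     c(rep(1L, length(rp)), rep(0L, length(ns))))
  backbone$seed <- as.integer(seed)
  fit <- fit_backbone(backbone, des$X, des$y)
  pred <- predict_twin(fit, data$features[data$val_idx, , drop = FALSE])
  f1_score(pred$pred, data$labels[data$val_idx])
}

# F1 with the convention 0 when undefined.
f1_score <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Partition signature: how many scores fall at/below t_low and at/above
# t_high in the pool. Two pairs with equal signatures induce identical
# partitions, so their evaluations are shared through a memo table.
partition_key <- function(scores, pair) {
  paste(sum(scores <= pair$t_low), sum(scores >= pair$t_high), sep = "/")
}

#' Fast double-threshold grid search (FDT-GS)
#'
#' Per round, a coarse grid (step `coarse_step` over `t_low` in `[0, 0.5]`
#' and `t_high` in `[0.5, 1]`) is scanned, then the incumbent is refined on
#' a fine grid of step `fine_step` inside a `+/- fine_window` window by
#' alternating coordinate sweeps (low threshold, then high). A candidate
#' replaces the incumbent iff its reward `alpha * (F1 - F1_incumbent)` is
#' strictly positive. Evaluations of identical partitions are memoized and
#' seeded by the partition signature, so the search is deterministic given
#' `(data, seed)`; with `resample_rounds = TRUE` each round re-draws a
#' bootstrap training pool, making the per-round retrieved thresholds
#' scatter the way a per-round log shows.
#'
#' @param data an [fdtgs_data()] bundle.
#' @param backbone an `octx_mlp` configuration.
#' @param rounds number of search rounds (default 8).
#' @param init initial `(t_low, t_high)` pair, default `c(0.5, 0.8)`.
#' @param alpha reward scale applied to F1 differences (default 100).
#' @param coarse_step,fine_step,fine_window grid geometry (defaults 0.1,
#'   0.001, 0.05).
#' @param resample_rounds bootstrap the training pool per round.
#' @param seed integer seed.
#' @return list with `pair` (the incumbent [threshold_pair()]), `trace`
#'   (data.frame: round, performance, t_low, t_high — the per-round bests,
#'   with best-so-far performance non-decreasing in `best_f1`), and
#'   `evaluations` (count of backbone trainings).
#' @export
fdtgs_search <- function(data, backbone, rounds = 8L,
                         init = c(0.5, 0.8), alpha = 100,
                         coarse_step = 0.1, fine_step = 0.001,
                         fine_window = 0.05,
                         resample_rounds = TRUE, seed = 1L) {
  stopifnot(rounds >= 1, inherits(data, "octx_fdtgs_data"))
  if (!(init[1] < init[2])) stop("invalid initial pair: t_low >= t_high")
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L

  eval_pair <- function(pair, pool) {
    key <- partition_key(pool$scores[pool$train_idx], pair)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- tryCatch(
      evaluate_threshold_pair(pair, pool, backbone,
                              seed = sub_seed(seed, paste0("eval/", key))),
      error = function(e) -Inf)
    if (is.finite(val)) n_eval <<- n_eval + 1L
    memo[[key]] <- val
    val
  }

  best_pair <- NULL; best_f1 <- -Inf
  trace <- data.frame(round = integer(0), performance = numeric(0),
                      t_low = numeric(0), t_high = numeric(0),
                      best_f1 = numeric(0))
  lows <- seq(0, 0.5, by = coarse_step)
  highs <- seq(0.5, 1, by = coarse_step)

  for (r in seq_len(rounds)) {
    pool <- data
    if (resample_rounds && rounds > 1L && r > 1L) {
      pool$train_idx <- with_seed(
        sub_seed(seed, paste0("round/", r)),
        sample(data$train_idx, length(data$train_idx), replace = TRUE))
      memo <- new.env(parent = emptyenv())
    }
    r_pair <- threshold_pair(init[1], init[2])
    r_f1 <- eval_pair(r_pair, pool)
    # coarse stage
    for (lo in lows) for (hi in highs) {
      if (lo >= hi) next
      cand <- threshold_pair(lo, hi)
      f1 <- eval_pair(cand, pool)
      if (!is.finite(f1)) next
      if (!is.finite(r_f1) || alpha * (f1 - r_f1) > 0) {
        r_pair <- cand; r_f1 <- f1
      }
    }
    if (!is.finite(r_f1)) {
      if (r == rounds && !is.finite(best_f1))
        stop("no feasible threshold pair: every candidate was degenerate")
      next
    }
    # fine stage: alternating coordinate sweeps at fine_step resolution
    for (sweep_i in 1:2) {
      lo_grid <- seq(max(0, r_pair$t_low - fine_window),
                     min(r_pair$t_high - fine_step,
                         r_pair$t_low + fine_window), by = fine_step)
      for (lo in lo_grid) {
        cand <- threshold_pair(lo, r_pair$t_high)
        f1 <- eval_pair(cand, pool)
        if (is.finite(f1) && alpha * (f1 - r_f1) > 0) {
          r_pair <- cand; r_f1 <- f1
        }
      }
      hi_grid <- seq(max(r_pair$t_low + fine_step,
                         r_pair$t_high - fine_window),
                     min(1, r_pair$t_high + fine_window), by = fine_step)
      for (hi in hi_grid) {
        cand <- threshold_pair(r_pair$t_low, hi)
        f1 <- eval_pair(cand, pool)
        if (is.finite(f1) && alpha * (f1 - r_f1) > 0) {
          r_pair <- cand; r_f1 <- f1
        }
      }
    }
    # round result enters the log; the incumbent is updated on positive
    # reward, measured on the original (non-resampled) data
    inc_f1 <- if (resample_rounds && r > 1L) {
      memo_full <- partition_key(data$scores[data$train_idx], r_pair)
      tryCatch(
        evaluate_threshold_pair(r_pair, data, backbone,
                                seed = sub_seed(seed,
                                                paste0("eval/", memo_full))),
        error = function(e) -Inf)
    } else r_f1
    if (alpha * (inc_f1 - best_f1) > 0) {
      best_pair <- r_pair; best_f1 <- inc_f1
    }
    trace <- rbind(trace, data.frame(round = r, performance = r_f1,
                                     t_low = r_pair$t_low,
                                     t_high = r_pair$t_high,
                                     best_f1 = best_f1))
  }
  if (is.null(best_pair))
    stop("no feasible threshold pair: every candidate was degenerate")
  structure(list(pair = best_pair, trace = trace, evaluations = n_eval),
            class = "octx_fdtgs_result")
}

#' @export
print.octx_fdtgs_result <- function(x, ...) {
  cat(sprintf(
    "<octx_fdtgs_result> incumbent (%.4f, %.4f), %d rounds, %d evaluations\n",
    x$pair$t_low, x$pair$t_high, nrow(x$trace), x$evaluations))
  invisible(x)
}

#' Write an FDT-GS search log with an AVG row
#'
#' Mirrors a per-round hyperparameter log: one row per round with the best
#' performance and the retrieved thresholds, plus a final `AVG` row holding
#' the mean retrieved thresholds (performance left as `/`). All rounds are
#' included in the average.
#'
#' @param result an `octx_fdtgs_result`.
#' @param path CSV output path.
#' @return the written data.frame, invisibly.
#' @export
write_search_log <- function(result, path) {
  tr <- result$trace
  df <- data.frame(round = as.character(tr$round),
                   performance = format(tr$performance, digits = 4),
                   low_threshold = tr$t_low, high_threshold = tr$t_high,
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(round = "AVG", performance = "/",
                             low_threshold = mean(tr$t_low),
                             high_threshold = mean(tr$t_high)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
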
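#' Build the PL/NL training and validation sets at the 1:10 ratio
#'
#' The loop cleans one "primary" set (the positives in positive-only
#' learning, the negatives in negative-only learning); the opposite set is
#' drawn uniformly without replacement from the supervised opposite pool at
#' `ratio` times the primary size, separately for training and validation.
#' Field names follow the PL orientation: `P_*` is the primary (cleaned)
#' set, `N_*` the opposite set, whatever the direction.
#'
#' @param primary_train ids of the primary training instances
#'   (`P_t_ori`).
#' @param opposite_pool ids of the supervised opposite pool (e.g. the
#'   negative samples NS in PL).
#' @param primary_val ids of the primary validation instances (`P_v_ori`).
#' @param ratio opposite-to-primary multiplier (default 10).
#' @param direction `"PL"` or `"NL"` (bookkeeping only).
#' @param seed integer seed for the opposite-set draws.
#' @return object of class `octx_sets` with `P_t_ori`, `P_v_ori`,
#'   `N_t_ori`, `N_v_ori`, `Psi` (empty), and the effective sets `P_t`,
#'   `N_t`, `P_v`, `N_v`.
#' @export
build_pl_nl_sets <- function(primary_train, opposite_pool, primary_val,
                             ratio = 10L, direction = c("PL", "NL"),
                             seed = 1L) {
  direction <- match.arg(direction)
  need_t <- ratio * length(primary_train)
  need_v <- ratio * length(primary_val)
  if (!length(primary_train)) stop("empty primary training set")
  if (length(opposite_pool) < need_t)
    stop("insufficient opposite instances: ", need_t, " required for the ",
         "1:", ratio, " training ratio, ", length(opposite_pool),
         " available")
  picks <- with_seed(seed, {
    t_ids <- sample(opposite_pool, need_t)
    rest <- setdiff(opposite_pool, t_ids)
    if (length(rest) < need_v)
      stop("insufficient opposite instances: ", need_v,
           " required for the validation ratio, ", length(rest),
           " available after the training draw")
    v_ids <- if (need_v > 0) sample(rest, need_v) else integer(0)
    list(t = t_ids, v = v_ids)
  })
  structure(list(P_t_ori = primary_train, P_v_ori = primary_val,
                 N_t_ori = picks$t, N_v_ori = picks$v,
                 Psi = integer(0),
                 P_t = primary_train, N_t = picks$t,
                 P_v = primary_val, N_v = picks$v,
                 direction = direction),
            class = "octx_sets")
}

#' The retain/remove noise-filter policy
#'
#' A logistic model `pi(remove | S) = sigmoid(w0 + w . S)` over the state
#' `S` = standardized patch features concatenated with the current
#' backbone posterior for that patch. The intercept starts at
#' `qlogis(init_remove)` and all state weights at zero, so the initial
#' policy removes each instance with probability `init_remove` —
#' retain-leaning by default, since removing half of the primary set
#' before any evidence would wreck the training signal the reward
#' depends on.
#'
#' @param d_state state dimension (features + 4 posterior entries).
#' @param init_remove initial removal probability (default 0.1).
#' @return object of class `octx_policy`.
#' @export
policy_model <- function(d_state, init_remove = 0.1) {
  structure(list(w = c(stats::qlogis(init_remove), rep(0, d_state)),
                 d_state = as.integer(d_state)),
            class = "octx_policy")
}

#' @rdname policy_model
#' @param policy an `octx_policy`.
#' @param states matrix `n x d_state`.
#' @return numeric removal probabilities in `(0, 1)`.
#' @export
predict_remove_prob <- function(policy, states) {
  stopifnot(inherits(policy, "octx_policy"),
            ncol(states) == policy$d_state)
  as.numeric(stats::plogis(cbind(1, states) %*% policy$w))
}

# State matrix for a set of instance ids: standardized features plus the
# backbone's four-class posterior (plus branch).
policy_states <- function(ids, features, center, scale, backbone = NULL) {
  f <- sweep(sweep(features[ids, , drop = FALSE], 2, center), 2, scale, "/")
  if (!is.null(backbone) && backbone$fitted) {
    post <- predict_posteriors(backbone,
                               cbind(features[ids, , drop = FALSE],
                                     branch = 1))
  } else {
    post <- matrix(0.25, length(ids), 4L)
  }
  cbind(f, post)
}

#' One stochastic filtering pass over the primary training set
#'
#' Samples each primary training instance for removal with probability
#' `pi(remove | S)`; removed ids form `Psi`, the effective primary set is
#' `P_t = P_t_ori - Psi` and the removed instances are transferred to the
#' opposite set, `N_t = N_t_ori + Psi`. A floor guarantees at least
#' `floor_frac` of `P_t_ori` is always retained: when the draw would
#' remove more, the removal set is truncated to the highest removal
#' probabilities with a warning.
#'
#' @param policy an `octx_policy`.
#' @param sets an `octx_sets`.
#' @param states state matrix aligned with `sets$P_t_ori`.
#' @param seed integer seed for the removal draws.
#' @param floor_frac minimum retained fraction of `P_t_ori` (default 0.2).
#' @return list with `sets` (updated), `decisions` (data.frame: `id`,
#'   `action` 1 = remove, `prob`).
#' @export
policy_filter_epoch <- function(policy, sets, states, seed = 1L,
                                floor_frac = 0.2) {
  stopifnot(inherits(sets, "octx_sets"),
            nrow(states) == length(sets$P_t_ori))
  if (!length(sets$P_t_ori)) stop("empty primary training set")
  prob <- predict_remove_prob(policy, states)
  # clip the sampling probabilities away from 0/1 so the stochastic
  # filter never saturates and keeps exploring
  p_clip <- pmin(pmax(prob, 0.02), 0.98)
  sampled <- with_seed(seed, stats::runif(length(p_clip)) < p_clip)
  remove <- sampled
  max_remove <- length(sets$P_t_ori) -
    ceiling(floor_frac * length(sets$P_t_ori))
  if (sum(remove) > max_remove) {
    warning("removal floor reached: truncating ", sum(remove), " -> ",
            max_remove, " removals")
    drawn <- which(remove)
    keep <- drawn[order(prob[drawn], decreasing = TRUE)[seq_len(max_remove)]]
    remove <- seq_along(prob) %in% keep
  }
  psi <- sets$P_t_ori[remove]
  sets$Psi <- psi
  sets$P_t <- setdiff(sets$P_t_ori, psi)
  sets$N_t <- union(sets$N_t_ori, psi)
  # decisions carry the *sampled* actions: a floor-enforced retention is
  # an environment override, not a policy choice, and crediting it to
  # the policy inverts the learning signal
  list(sets = sets,
       decisions = data.frame(id = sets$P_t_ori,
                              action = as.integer(sampled),
                              prob = p_clip))
}

#' Train the backbone for one epoch and score it on the cleaned validation
#'
#' Fits the backbone (warm start) on the current effective sets with twin
#' four-class labels, then applies the current policy deterministically
#' (`pi(remove|S) > 0.5`) to transfer suspected-noise validation
#' instances from `P_v_ori` to `N_v`, and computes the F1 of the fused
#' predictions on the cleaned validation set, treating the primary class
#' as positive. At most `1 - val_floor_frac` of `P_v_ori` is ever
#' transferred: the validation set is the loop's measurement instrument,
#' so it is guarded more tightly than the training set.
#'
#' @param backbone an `octx_mlp`.
#' @param sets an `octx_sets` (after [policy_filter_epoch()]).
#' @param features full feature matrix indexed by the set ids.
#' @param primary_label 1 when the primary set is malignant (PL), 0 for NL.
#' @param policy the current `octx_policy` (or `NULL` to skip transfer).
#' @param center,scale feature standardization for the policy states.
#' @param val_floor_frac retention floor for the validation transfer
#'   (default 0.8).
#' @param warm_start continue the backbone from its current weights
#'   (`FALSE` refits from scratch, which makes the epoch's F1 a direct
#'   function of the epoch's cleaned sets — the sharper reward signal).
#' @return list with `backbone` (fitted), `f1`, `transferred` (ids moved
#'   out of `P_v_ori`).
#' @export
train_epoch <- function(backbone, sets, features, primary_label = 1L,
                        policy = NULL, center = NULL, scale = NULL,
                        val_floor_frac = 0.8, warm_start = TRUE) {
  stopifnot(inherits(sets, "octx_sets"))
  if (!length(sets$P_t) || !length(sets$N_t))
    stop("empty effective training set")
  idx <- c(sets$P_t, sets$N_t)
  lab <- c(rep(primary_label, length(sets$P_t)),
           rep(1L - primary_label, length(sets$N_t)))
  des <- twin_design(features[idx, , drop = FALSE], lab)
  backbone <- fit_backbone(backbone, des$X, des$y, warm_start = warm_start)

  p_v <- sets$P_v_ori
  transferred <- integer(0)
  if (!is.null(policy) && length(p_v)) {
    st <- policy_states(p_v, features, center, scale, backbone)
    prob <- predict_remove_prob(policy, st)
    out <- prob > 0.5
    max_remove <- length(p_v) - ceiling(val_floor_frac * length(p_v))
    if (sum(out) > max_remove) {
      keep_top <- order(prob, decreasing = TRUE)[seq_len(max_remove)]
      out <- seq_along(prob) %in% keep_top
    }
    transferred <- p_v[out]
  }
  val_p <- setdiff(p_v, transferred)
  val_n <- union(sets$N_v_ori, transferred)
  val_idx <- c(val_p, val_n)
  val_lab <- c(rep(1L, length(val_p)), rep(0L, length(val_n)))
  pred <- predict_twin(backbone, features[val_idx, , drop = FALSE])
  pred_primary <- if (primary_label == 1L) pred$pred else 1L - pred$pred
  f1 <- f1_score(pred_primary, val_lab)
  list(backbone = backbone, f1 = f1, transferred = transferred)
}

#' Reward trace bookkeeping
#'
#' Holds the per-epoch F1 history and the rewards
#' `R_i = alpha * (Fbar_i - Fbar_(i-1))` where `Fbar_i` is the mean of the
#' trailing `min(window, i)` F1 values — the smoothing that removes
#' epoch-to-epoch randomness from the signal.
#'
#' @param alpha reward scale (default 100: maps F1 differences to O(1)
#'   rewards).
#' @param window trailing-mean window (default 5 epochs).
#' @return object of class `octx_reward_trace`.
#' @export
reward_trace <- function(alpha = 100, window = 5L) {
  structure(list(f1 = numeric(0), fbar = numeric(0), rewards = numeric(0),
                 alpha = alpha, window = as.integer(window)),
            class = "octx_reward_trace")
}

#' @rdname reward_trace
#' @param trace an `octx_reward_trace`.
#' @param f1 the epoch's validation F1.
#' @export
record_f1 <- function(trace, f1) {
  trace$f1 <- c(trace$f1, f1)
  n <- length(trace$f1)
  k <- min(trace$window, n)
  trace$fbar <- c(trace$fbar, mean(trace$f1[(n - k + 1):n]))
  if (n >= 2)
    trace$rewards <- c(trace$rewards,
                       trace$alpha * (trace$fbar[n] - trace$fbar[n - 1]))
  trace
}

#' Latest reward from a trace
#'
#' @param trace an `octx_reward_trace` with at least 2 recorded epochs.
#' @return `R_i = alpha * (Fbar_i - Fbar_(i-1))`.
#' @export
compute_reward <- function(trace) {
  stopifnot(inherits(trace, "octx_reward_trace"))
  n <- length(trace$f1)
  if (n < 2) stop("need at least 2 recorded epochs")
  trace$alpha * (trace$fbar[n] - trace$fbar[n - 1])
}

#' Reward-weighted policy update (REINFORCE-style)
#'
#' One gradient step on the cross-entropy of the taken retain/remove
#' actions, scaled by the reward: actions taken under a positive reward
#' are reinforced, under a negative reward discouraged; a zero reward
#' leaves the policy untouched. The effective reward is clipped to
#' `[-2, 1]`: bounded so a single noisy epoch cannot saturate the
#' logits, and asymmetric because removing clean instances costs more
#' than removing noise gains — performance drops are punished harder
#' than equal-sized gains are rewarded, which keeps the filter
#' conservative.
#'
#' @param policy an `octx_policy`.
#' @param decisions data.frame from [policy_filter_epoch()].
#' @param states state matrix aligned with `decisions`.
#' @param reward scalar reward `R_i`.
#' @param lr learning rate (default 0.05).
#' @return the updated `octx_policy`.
#' @export
update_policy <- function(policy, decisions, states, reward, lr = 0.05) {
  stopifnot(inherits(policy, "octx_policy"),
            nrow(states) == nrow(decisions))
  if (reward == 0) return(policy)
  reward <- max(min(reward, 1), -2)
  X <- cbind(1, states)
  p <- decisions$prob
  grad <- colMeans((decisions$action - p) * X)
  # mild decay keeps the logits bounded, so a bad early reward cannot
  # freeze the policy in a saturated remove-everything state
  policy$w <- 0.99 * (policy$w + lr * reward * grad)
  policy
}

#' Configuration for the cross-learning loop
#'
#' @param epochs training epochs per loop.
#' @param alpha reward scale of the trace.
#' @param ratio opposite-to-primary set ratio.
#' @param window trailing-mean window for the reward.
#' @param policy_enabled run the retain/remove filter (disable for an
#'   ablation baseline).
#' @param policy_lr policy gradient step size.
#' @param warmup epochs of backbone burn-in before the filter activates
#'   (the policy needs informative posteriors in its state).
#' @param backbone_warm warm-start the backbone across epochs; the
#'   default `FALSE` refits per epoch so the reward tracks the current
#'   removal decisions rather than the training history.
#' @param floor_frac retention floor.
#' @param eta0 base backbone learning rate; per-channel rates are
#'   `eta0 * N_min / N_c` (multirate balancing).
#' @param backbone_hidden,backbone_epochs MLP shape and per-epoch steps.
#' @param val_frac fraction of the primary set held out when the caller
#'   does not supply a validation split.
#' @return a list of class `octx_cross_config`.
#' @export
cross_config <- function(epochs = 30L, alpha = 100, ratio = 10L,
                         window = 5L, policy_enabled = TRUE,
                         policy_lr = 0.3, warmup = 10L, floor_frac = 0.2,
                         backbone_warm = FALSE,
                         eta0 = 0.05, backbone_hidden = c(16L, 8L),
                         backbone_epochs = 40L, val_frac = 0.2) {
  structure(list(epochs = as.integer(epochs), alpha = alpha,
                 ratio = as.integer(ratio), window = as.integer(window),
                 policy_enabled = policy_enabled, policy_lr = policy_lr,
                 warmup = as.integer(warmup),
                 floor_frac = floor_frac, backbone_warm = backbone_warm,
                 eta0 = eta0,
                 backbone_hidden = backbone_hidden,
                 backbone_epochs = as.integer(backbone_epochs),
                 val_frac = val_frac),
            class = "octx_cross_config")
}

#' Run one PL or NL loop to completion
#'
#' @param features full feature matrix.
#' @param sets an `octx_sets` from [build_pl_nl_sets()].
#' @param config an [cross_config()].
#' @param primary_label 1 for PL, 0 for NL.
#' @param lr backbone learning rate for this channel.
#' @param seed integer seed.
#' @return list with `backbone`, `policy`, `trace`
#'   (`octx_reward_trace`), `sets` (final state), `psi_history` (list of
#'   per-epoch removed ids), `log` (data.frame: epoch, f1, fbar, reward,
#'   n_psi).
#' @export
run_pl_nl_loop <- function(features, sets, config, primary_label = 1L,
                           lr = NULL, seed = 1L) {
  stopifnot(inherits(config, "octx_cross_config"))
  pool <- c(sets$P_t_ori, sets$N_t_ori)
  center <- colMeans(features[pool, , drop = FALSE])
  scl <- apply(features[pool, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-8] <- 1
  policy <- policy_model(ncol(features) + 4L)
  backbone <- mlp_backbone(hidden = config$backbone_hidden,
                           epochs = config$backbone_epochs,
                           lr = if (is.null(lr)) config$eta0 else lr,
                           seed = sub_seed(seed, "backbone"))
  trace <- reward_trace(alpha = config$alpha, window = config$window)
  psi_history <- list()
  log <- data.frame()
  cur <- sets
  state_backbone <- NULL
  for (ep in seq_len(config$epochs)) {
    decisions <- NULL; states <- NULL
    filtering <- config$policy_enabled && ep > config$warmup
    if (filtering) {
      # the policy state uses the burn-in classifier's posterior, frozen
      # at the end of warmup: a posterior that tracks the epoch's own
      # transfers would merely confirm whatever the policy last did
      if (is.null(state_backbone)) state_backbone <- backbone
      states <- policy_states(cur$P_t_ori, features, center, scl,
                              state_backbone)
      flt <- suppressWarnings(
        policy_filter_epoch(policy, cur, states,
                            seed = sub_seed(seed, paste0("filter/", ep)),
                            floor_frac = config$floor_frac))
      cur <- flt$sets
      decisions <- flt$decisions
    }
    te <- train_epoch(backbone, cur, features, primary_label,
                      policy = if (filtering) policy else NULL,
                      center = center, scale = scl,
                      warm_start = config$backbone_warm)
    backbone <- te$backbone
    trace <- record_f1(trace, te$f1)
    reward <- if (length(trace$f1) >= 2) compute_reward(trace) else 0
    if (filtering && !is.null(decisions)) {
      policy <- update_policy(policy, decisions, states, reward,
                              lr = config$policy_lr)
    }
    psi_history[[ep]] <- cur$Psi
    log <- rbind(log, data.frame(epoch = ep, f1 = te$f1,
                                 fbar = trace$fbar[ep], reward = reward,
                                 n_psi = length(cur$Psi)))
  }
  list(backbone = backbone, policy = policy, trace = trace, sets = cur,
       state_backbone = state_backbone,
       psi_history = psi_history, log = log)
}

#' Run the full cross-learning over up to four channels
#'
#' Each channel carries its FDT-GS output (reliable positives RP and
#' negative samples NS within the training split) plus feature and label
#' vectors. Per channel a PL loop (cleaning the positives) and a mirrored
#' NL loop (cleaning the negatives; its primary set is truncated to
#' `floor(|RP| / ratio)` so the 1:10 ratio stays attainable) are run; the
#' backbone learning rate is scaled as `eta_c = eta0 * N_min / N_c`
#' (multirate balancing, so the largest channel trains with the smallest
#' rate). Final test metrics come from the branch-averaged posterior of
#' the PL and NL backbones.
#'
#' @param channels named list; each element is a list with `name`,
#'   `features`, `noisy_labels`, `true_labels`, `split` (factor
#'   train/test/val), `RP`, `NS` (ids within the training split).
#' @param config an [cross_config()].
#' @param seed integer seed.
#' @return named list per channel: `pl`, `nl` (loop results), `lr`,
#'   `metrics` (an `octx_metrics` on the test split vs true labels),
#'   `auc`, `predictions`.
#' @export
run_cross_learning <- function(channels, config = cross_config(),
                               seed = 1L) {
  stopifnot(length(channels) >= 1, length(channels) <= 4)
  sizes <- vapply(channels, function(ch) length(ch$true_labels), 0)
  n_min <- min(sizes)
  out <- list()
  for (ci in seq_along(channels)) {
    ch <- channels[[ci]]
    if (!length(ch$true_labels)) {
      warning("skipping empty channel ", ch$name)
      next
    }
    lr <- unname(config$eta0 * n_min / sizes[ci])
    cs <- sub_seed(seed, paste0("channel/", ch$name))
    val_ids <- which(ch$split == "val")
    val_pos <- val_ids[ch$noisy_labels[val_ids] == 1L]
    val_neg <- val_ids[ch$noisy_labels[val_ids] == 0L]

    # the supervised opposite pool for PL: negative samples plus the
    # validation-split negatives; the primary set is capped so the 1:10
    # draws stay feasible (about 1/5 of the capacity goes to validation)
    pl_pool <- c(ch$NS, val_neg)
    pv_n <- min(length(val_pos),
                max(1L, floor(length(pl_pool) / (5L * config$ratio))))
    pv <- with_seed(sub_seed(cs, "pl_val"),
                    sample(val_pos, pv_n))
    pt_max <- floor(length(pl_pool) / config$ratio) - pv_n
    if (pt_max < 1L) {
      warning("skipping channel ", ch$name,
              ": opposite pool too small for the 1:", config$ratio,
              " ratio")
      next
    }
    pt <- if (length(ch$RP) > pt_max)
      with_seed(sub_seed(cs, "pl_primary"), sample(ch$RP, pt_max))
    else ch$RP
    pl_sets <- build_pl_nl_sets(pt, pl_pool, pv,
                                ratio = config$ratio, direction = "PL",
                                seed = sub_seed(cs, "pl_sets"))
    pl <- run_pl_nl_loop(ch$features, pl_sets, config, primary_label = 1L,
                         lr = lr, seed = sub_seed(cs, "pl"))

    nl_pool <- c(ch$RP, val_pos)
    nv_n <- min(length(val_neg),
                max(1L, floor(length(nl_pool) / (5L * config$ratio))))
    nl_val <- with_seed(sub_seed(cs, "nl_val"),
                        sample(val_neg, nv_n))
    nt_max <- floor(length(nl_pool) / config$ratio) - nv_n
    nl_primary_n <- min(length(ch$NS), max(1L, nt_max))
    nl_primary <- with_seed(sub_seed(cs, "nl_primary"),
                            sample(ch$NS, nl_primary_n))
    nl <- tryCatch({
      nl_sets <- build_pl_nl_sets(nl_primary, nl_pool, nl_val,
                                  ratio = config$ratio, direction = "NL",
                                  seed = sub_seed(cs, "nl_sets"))
      run_pl_nl_loop(ch$features, nl_sets, config, primary_label = 0L,
                     lr = lr, seed = sub_seed(cs, "nl"))
    }, error = function(e) {
      warning("NL loop skipped for ", ch$name, ": ", conditionMessage(e))
      NULL
    })

    test_ids <- which(ch$split == "test")
    fx <- ch$features[test_ids, , drop = FALSE]
    theta <- predict_posteriors(pl$backbone, cbind(fx, branch = 1))
    psi <- predict_posteriors(pl$backbone, cbind(fx, branch = -1))
    if (!is.null(nl)) {
      theta <- (theta + predict_posteriors(nl$backbone,
                                           cbind(fx, branch = 1))) / 2
      psi <- (psi + predict_posteriors(nl$backbone,
                                       cbind(fx, branch = -1))) / 2
    }
    fused <- fuse_twin_matrix(theta, psi)
    fused$pred <- as.integer(fused$label == "P")
    truth <- ch$true_labels[test_ids]
    metrics <- confusion_metrics(fused$pred, truth)
    auc <- if (length(unique(truth)) == 2)
      roc_auc(fused$score, truth)$auc else NA_real_
    out[[ch$name]] <- list(pl = pl, nl = nl, lr = lr, metrics = metrics,
                           auc = auc, predictions = fused)
  }
  out
}
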
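#' Declarative configuration for a full pipeline run
#'
#' Bundles every tunable of the pipeline with defaults mirroring the
#' reference protocol: 50 px patches, 7:2:1 splits, 1:10 set ratio,
#' 8 search rounds, initial pair (0.5, 0.8), reward scale 100. All
#' randomness downstream is derived from the single `seed` via
#' [sub_seed()]. The configuration round-trips losslessly through JSON
#' (`save_run_config()` / `load_run_config()`).
#'
#' @param channels character vector of channel names to simulate.
#' @param scale quota down-scaling passed to [channel_spec()] (keep small:
#'   the full reference quotas are minutes of texture synthesis).
#' @param noise label-noise rate per channel.
#' @param patch_size,image_size geometry passed to [channel_spec()].
#' @param glcm_levels,glcm_distances GLCM settings.
#' @param split_ratios train/test/val ratios.
#' @param fdtgs_rounds,fdtgs_init,fdtgs_resample threshold-search settings.
#' @param epochs,alpha,ratio,policy_enabled,eta0 cross-learning settings.
#' @param backbone_epochs,backbone_hidden backbone settings.
#' @param seed run seed.
#' @param out_dir artifact directory.
#' @return object of class `octx_run_config`.
#' @export
run_config <- function(channels = c("GU", "GRS", "GPs", "GB"),
                       scale = 0.05, noise = 0,
                       patch_size = 50L, image_size = 250L,
                       glcm_levels = 32L, glcm_distances = c(1L, 2L),
                       split_ratios = c(0.7, 0.2, 0.1),
                       fdtgs_rounds = 8L, fdtgs_init = c(0.5, 0.8),
                       fdtgs_resample = TRUE,
                       epochs = 30L, alpha = 100, ratio = 10L,
                       policy_enabled = TRUE, eta0 = 0.05,
                       backbone_epochs = 20L, backbone_hidden = c(16L, 8L),
                       seed = 1L, out_dir = tempfile("octx_run_")) {
  if (!(fdtgs_init[1] < fdtgs_init[2]))
    stop("invalid threshold pair in config: t_low >= t_high")
  if (abs(sum(split_ratios) - 1) > 1e-9)
    stop("split ratios must sum to 1")
  if (!all(channels %in% c("GU", "GRS", "GPs", "GB")))
    stop("unknown channel name")
  structure(as.list(environment()), class = "octx_run_config")
}

#' @rdname run_config
#' @param config an `octx_run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

stage_msg <- function(...) message("[octx] ", ...)

#' Run the full pipeline: simulate, features, FDT-GS, train, evaluate
#'
#' Executes every stage in order for each configured channel, writes all
#' intermediate artifacts (manifest, feature table, search log, training
#' log, metrics table, ROC points) under `config$out_dir`, and returns —
#' and writes as JSON — a final report with per-channel metrics and macro
#' averages. The run is a pure function of `(config, seed)`; re-running
#' the same configuration yields a byte-identical report.
#'
#' @param config an [run_config()].
#' @return the report list, invisibly; JSON at
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "octx_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  channels <- list()
  t0 <- Sys.time()

  for (ch_name in config$channels) {
    stage_msg("simulate: ", ch_name)
    spec <- channel_spec(ch_name, scale = config$scale,
                         image_size = config$image_size,
                         patch_size = config$patch_size,
                         label_noise_rate = config$noise)
    ds <- build_channel_dataset(spec, sub_seed(seed, paste0("sim/", ch_name)),
                                ratios = config$split_ratios)
    utils::write.csv(dataset_manifest(ds),
                     file.path(config$out_dir,
                               paste0(ch_name, "_manifest.csv")),
                     row.names = FALSE)

    stage_msg("features: ", ch_name, " (", length(ds$patches), " patches)")
    feats <- patch_feature_matrix(ds$patches,
                                  distances = config$glcm_distances,
                                  levels = config$glcm_levels)
    ft <- data.frame(patch_id = seq_len(nrow(feats)), row = ds$row,
                     col = ds$col, feats)
    utils::write.csv(ft, file.path(config$out_dir,
                                   paste0(ch_name, "_features.csv")),
                     row.names = FALSE)

    stage_msg("fdtgs: ", ch_name)
    train_ids <- which(ds$split == "train")
    val_ids <- which(ds$split == "val")
    scorer <- make_seed_scorer(feats[train_ids, , drop = FALSE],
                               ds$noisy_labels[train_ids])
    scores <- score_patches(scorer, feats)
    fd <- fdtgs_data(feats, scores, ds$noisy_labels, train_ids, val_ids)
    backbone <- mlp_backbone(hidden = config$backbone_hidden,
                             epochs = config$backbone_epochs,
                             lr = config$eta0)
    sr <- fdtgs_search(fd, backbone, rounds = config$fdtgs_rounds,
                       init = config$fdtgs_init,
                       alpha = config$alpha,
                       resample_rounds = config$fdtgs_resample,
                       seed = sub_seed(seed, paste0("fdtgs/", ch_name)))
    write_search_log(sr, file.path(config$out_dir,
                                   paste0(ch_name, "_search_log.csv")))
    part <- partition_by_thresholds(scores[train_ids], sr$pair)

    channels[[ch_name]] <- list(
      name = ch_name, features = feats, noisy_labels = ds$noisy_labels,
      true_labels = ds$labels, split = ds$split,
      RP = train_ids[part$RP], NS = train_ids[part$NS],
      scores = scores, pair = sr$pair, search = sr, dataset = ds)
  }

  stage_msg("train: cross-learning over ", length(channels), " channel(s)")
  cc <- cross_config(epochs = config$epochs, alpha = config$alpha,
                     ratio = config$ratio,
                     policy_enabled = config$policy_enabled,
                     eta0 = config$eta0,
                     backbone_hidden = config$backbone_hidden,
                     backbone_epochs = config$backbone_epochs)
  results <- run_cross_learning(channels, cc,
                                seed = sub_seed(seed, "train"))

  stage_msg("evaluate")
  metric_rows <- list()
  for (ch_name in names(results)) {
    res <- results[[ch_name]]
    utils::write.csv(res$pl$log,
                     file.path(config$out_dir,
                               paste0(ch_name, "_training_log.csv")),
                     row.names = FALSE)
    truth <- channels[[ch_name]]$true_labels[
      channels[[ch_name]]$split == "test"]
    if (length(unique(truth)) == 2) {
      roc <- roc_auc(res$predictions$score, truth)
      utils::write.csv(roc$curve,
                       file.path(config$out_dir,
                                 paste0(ch_name, "_roc.csv")),
                       row.names = FALSE)
    }
    metric_rows[[ch_name]] <- cbind(channel = ch_name,
                                    as.data.frame(res$metrics),
                                    auc = res$auc)
  }
  if (!length(metric_rows))
    stop("train: no channel could be trained (opposite pools too small ",
         "for the 1:", config$ratio, " ratio at this scale)")
  metrics_df <- do.call(rbind, metric_rows)
  utils::write.csv(metrics_df, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  manifest_all <- do.call(rbind, lapply(channels, function(ch)
    dataset_manifest(ch$dataset)))
  report <- list(
    config = unclass(config)[setdiff(names(config), "out_dir")],
    dataset = dataset_summary(manifest_all),
    thresholds = lapply(channels, function(ch)
      c(t_low = ch$pair$t_low, t_high = ch$pair$t_high)),
    metrics = metrics_df,
    macro = list(
      accuracy = macro_average(100 * metrics_df$accuracy),
      f_measure = macro_average(100 * metrics_df$f_measure),
      auc = if (any(!is.na(metrics_df$auc)))
        macro_average(100 * metrics_df$auc[!is.na(metrics_df$auc)])
      else NA_real_))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  stage_msg(sprintf("done in %.1fs: %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    config$out_dir))
  invisible(report)
}
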
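# End-to-end pipeline: simulate -> preprocess -> select sensors -> train ->
# evaluate -> report, driven by one flat configuration whose keys mirror the
# model's hyperparameter table (learning_rate, dropout, ratio, seed, ...).

pipeline_defaults <- function() {
  list(
    seed = 512L,
    model = "relation",           # relation | siamese | proto
    n_way = 4L,
    k_shot = 1L,
    batch_num_per_class = 20L,    # queries per class per episode
    training_epochs = 1001L,
    testing_epochs = 50L,
    eval_every = 20L,
    learning_rate = NULL,         # per-model default when NULL
    dropout = 0.3,
    ratio = 16L,
    window_lo = 700L,
    window_hi = 1000L,
    # synthetic data
    n_classes_train = 6L,
    samples_per_class_train = 20L,
    samples_per_class_test = c(40L, 8L, 20L, 10L),
    n_points = 2400L,
    separation = 1.5,
    noise_sd = 0.05,
    stages = c("simulate", "select_sensors", "train", "evaluate", "report"))
}

#' Run the full few-shot e-nose pipeline
#'
#' Generates seeded synthetic meta-training and meta-testing bundles,
#' reports mutual-information sensor rankings, trains the requested model
#' episodically, aggregates the stable evaluation window, and writes a
#' report plus a run manifest that records every configuration value, seed
#' and output path needed to reproduce the run.
#'
#' @param config named list overriding the defaults, or the path of a YAML
#'   file with such overrides. Unknown keys are rejected.
#' @param out_dir directory for outputs (created if needed).
#' @param verbose print stage progress (default TRUE).
#' @return the run manifest, invisibly: a list with the full config, output
#'   paths, and the aggregated statistics.
#' @export
run_pipeline <- function(config = list(), out_dir = "enosefs_run",
                         verbose = TRUE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(config = cfg, outputs = list(),
                   package_version = as.character(utils::packageVersion("enosefs")))

  # simulate: class-disjoint meta-train / meta-test bundles from one seed
  say("[simulate] generating synthetic bundles (seed %d)", cfg$seed)
  sc_train <- synth_config(
    n_classes = cfg$n_classes_train,
    samples_per_class = cfg$samples_per_class_train,
    n_points = cfg$n_points, separation = cfg$separation,
    noise_sd = cfg$noise_sd, source = "meta_train",
    class_names = paste0("gas_", seq_len(cfg$n_classes_train)),
    seed = cfg$seed)
  sc_test <- synth_config(
    n_classes = length(cfg$samples_per_class_test),
    samples_per_class = cfg$samples_per_class_test,
    n_points = cfg$n_points, separation = cfg$separation,
    noise_sd = cfg$noise_sd, source = "meta_test",
    class_names = c("copd", "smokers", "control", "air")[
      seq_along(cfg$samples_per_class_test)],
    seed = cfg$seed + 1L)
  bundle_train <- generate_dataset(sc_train)
  bundle_test <- generate_dataset(sc_test)

  if ("select_sensors" %in% cfg$stages) {
    say("[select-sensors] ranking %d sensors by mutual information",
        ncol(bundle_train$samples[[1]]$matrix))
    sc <- sensor_scores(bundle_train)
    sc$rank <- match(sc$sensor_id, rank_sensors(sc, k = nrow(sc)))
    path <- file.path(out_dir, "sensor_scores.tsv")
    utils::write.table(sc, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs$sensor_scores <- path
  }

  result <- NULL
  if ("train" %in% cfg$stages) {
    say("[train] %s, %d-way %d-shot, %d epochs", cfg$model, cfg$n_way,
        cfg$k_shot, cfg$training_epochs)
    tc <- train_config(
      model_kind = cfg$model,
      spec = episode_spec(cfg$n_way, cfg$k_shot, cfg$batch_num_per_class),
      learning_rate = cfg$learning_rate, epochs = cfg$training_epochs,
      eval_every = cfg$eval_every, test_episodes = cfg$testing_epochs,
      seed = cfg$seed,
      metric_cfg = metric_config(se_ratio = cfg$ratio,
                                 dropout = cfg$dropout),
      embed_cfg = embedding_config(se_ratio = cfg$ratio))
    result <- train_few_shot(bundle_train, bundle_test, tc,
                             verbose = verbose)
    hpath <- file.path(out_dir, "history.tsv")
    utils::write.table(result$history, hpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cpath <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(result$model, cpath)
    manifest$outputs$history <- hpath
    manifest$outputs$checkpoint <- cpath
  }

  if ("evaluate" %in% cfg$stages && !is.null(result)) {
    lo <- min(cfg$window_lo, max(result$history$epoch))
    hi <- cfg$window_hi
    stats <- aggregate_window(result$history, lo, hi)
    manifest$statistics <- stats
    say("[evaluate] window [%d, %d]: accuracy %.3f (h %.3f), F1 %.3f (h %.3f)",
        lo, hi, stats$mean_accuracy, stats$h_accuracy, stats$mean_f1,
        stats$h_f1)
  }

  if ("report" %in% cfg$stages) {
    rpath <- file.path(out_dir, "report.txt")
    lines <- c(
      sprintf("enosefs pipeline report (seed %d)", cfg$seed),
      sprintf("model: %s, %d-way %d-shot, %d epochs", cfg$model, cfg$n_way,
              cfg$k_shot, cfg$training_epochs))
    if (!is.null(manifest$statistics))
      lines <- c(lines, sprintf(
        "mean_accuracy %.4f  h_accuracy %.4f  mean_F1 %.4f  h_F1 %.4f (%d records)",
        manifest$statistics$mean_accuracy, manifest$statistics$h_accuracy,
        manifest$statistics$mean_f1, manifest$statistics$h_f1,
        manifest$statistics$n_records))
    writeLines(lines, rpath)
    manifest$outputs$report <- rpath
  }

  mpath <- file.path(out_dir, "manifest.rds")
  saveRDS(manifest, mpath)
  manifest$outputs$manifest <- mpath
  invisible(manifest)
}
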
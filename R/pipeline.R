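#' Resolve a full pipeline configuration
#'
#' Fills defaults for every stage: k = 2, duplex tracks, 45 removed
#' positions, and the tuned [model_config()] (64 units, dropout 0.5, batch
#' 64, seed 75, embedding 768).
#'
#' @param ... Overrides: `k`, `track_mode`, `K_removed`, `val_fraction`,
#'   `test_fraction`, plus any [model_config()] field.
#' @return A `run_config` list with a `model` sub-config.
#' @export
run_config <- function(...) {
  over <- list(...)
  base <- list(k = 2L, track_mode = "duplex", K_removed = 45L,
               val_fraction = 0.1, test_fraction = 0.1)
  model_fields <- names(formals(model_config))
  base_over <- over[names(over) %in% names(base)]
  model_over <- over[names(over) %in% model_fields]
  unknown <- setdiff(names(over), c(names(base), model_fields))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(base, base_over)
  cfg$model <- do.call(model_config, model_over)
  structure(cfg, class = "run_config")
}

log_stage <- function(...) message("[seqpose] ", ...)

#' Run the full pipeline end to end
#'
#' Dictionary construction, encoding, chi-squared position removal,
#' two-head training, and held-out evaluation, with all artifacts written
#' to an output directory: `dictionary.tsv`, `score_table.tsv`,
#' `mask.json`, the model bundle (`model/`), per-layer `metrics.tsv`,
#' test-set predictions, and `run.json` capturing the resolved
#' configuration.
#'
#' @param dataset A labelled `benchmark_dataset`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return List with `model` (`spenhancer_model`), `metrics` (data.frame,
#'   one row per layer), `predictions` (test-set cascade calls), `splits`.
#' @export
run_pipeline <- function(dataset, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage("dataset: ", nrow(dataset$records), " records of ",
            dataset$expected_length, " bp")
  splits <- split_protocol(dataset, seed = config$model$seed,
                           test_fraction = config$test_fraction,
                           val_fraction = 0)
  train_ds <- splits$train; test_ds <- splits$test
  log_stage("split: ", nrow(train_ds$records), " train / ",
            nrow(test_ds$records), " test")

  tracks <- if (config$track_mode == "duplex") 2L else 1L
  n_cols <- tracks * (dataset$expected_length - config$k + 1L)
  if (config$K_removed >= n_cols) {
    stop("selection stage: K_removed (", config$K_removed,
         ") must be smaller than the feature count (", n_cols, ")",
         call. = FALSE)
  }

  dict <- build_dictionary(train_ds$records, config$k, config$track_mode)
  log_stage("dictionary: P = ", dict$size, " ", config$k, "-mers")
  write_dictionary(dict, file.path(out_dir, "dictionary.tsv"))

  det <- binary_view(train_ds, "detection")
  em_det <- encode_dataset(det$records, dict, config$track_mode,
                           labels = det$labels)
  log_stage("encoded: ", nrow(em_det$ids), " x ", ncol(em_det$ids))
  score <- remove_top_k(score_all_positions(em_det), config$K_removed)
  log_stage("selection: removed ", score$K, " of ", score$n_columns,
            " positions")
  write_score_table(score, file.path(out_dir, "score_table.tsv"))
  write_mask(score, file.path(out_dir, "mask.json"))

  heads <- list()
  metrics_rows <- list()
  for (layer in c("detection", "strength")) {
    view_tr <- binary_view(train_ds, layer)
    em_tr <- apply_mask(encode_dataset(view_tr$records, dict,
                                       config$track_mode,
                                       labels = view_tr$labels), score)
    idx <- split_indices(view_tr$labels, seed = config$model$seed,
                         test_fraction = 0,
                         val_fraction = config$val_fraction)
    net <- build_network(config$model, ncol(em_tr$ids), dict$size)
    log_stage("training ", layer, " head on ", length(idx$train),
              " samples (val ", length(idx$validation), ")")
    heads[[layer]] <- train_head(net, subset_encoded(em_tr, idx$train),
                                 subset_encoded(em_tr, idx$validation),
                                 config$model, role = layer)
    view_te <- binary_view(test_ds, layer)
    em_te <- apply_mask(encode_dataset(view_te$records, dict,
                                       config$track_mode,
                                       labels = view_te$labels), score)
    pr <- predict(heads[[layer]], em_te)
    m <- evaluate_predictions(view_te$labels, pr$call, pr$prob)
    log_stage(layer, " test: Acc = ", sprintf("%.4f", m$Acc),
              ", MCC = ", sprintf("%.4f", m$MCC))
    metrics_rows[[layer]] <- data.frame(layer = layer, Acc = m$Acc,
                                        Sn = m$Sn, Sp = m$Sp, MCC = m$MCC,
                                        AUC = m$AUC)
  }
  model <- structure(list(detection = heads$detection,
                          strength = heads$strength,
                          dictionary = dict, score_table = score,
                          mask = score$removed, k = dict$k,
                          track_mode = config$track_mode,
                          config = config$model),
                     class = "spenhancer_model")
  save_model(model, file.path(out_dir, "model"))
  metrics_df <- do.call(rbind, metrics_rows)
  rownames(metrics_df) <- NULL
  write_metrics_table(metrics_df, file.path(out_dir, "metrics.tsv"))
  predictions <- predict_two_layer(model, test_ds$records)
  write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
  run_manifest <- c(unclass(config)[setdiff(names(unclass(config)), "model")],
                    unclass(config$model),
                    list(package_version =
                           as.character(utils::packageVersion("seqpose"))))
  writeLines(jsonlite::toJSON(run_manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "run.json"))
  list(model = model, metrics = metrics_df, predictions = predictions,
       splits = splits)
}

#' Predict from a saved model bundle
#'
#' @param bundle_dir Directory written by [save_model()].
#' @param fasta_path Query FASTA file.
#' @param out_path Optional TSV output path.
#' @return Predictions data.frame (`id`, `prob_layer1`, `prob_layer2`,
#'   `category`).
#' @export
predict_bundle <- function(bundle_dir, fasta_path, out_path = NULL) {
  model <- load_model(bundle_dir)
  records <- read_fasta(fasta_path)
  predictions <- predict_two_layer(model, records)
  if (!is.null(out_path)) write_predictions(predictions, out_path)
  predictions
}
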